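#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Map characters to row indices of the scoring matrix; unknown characters
// fall back to `unknown_idx` (the matrix's 'X'/'N' column) so degenerate
// symbols score like an ambiguity code rather than crashing.
static std::vector<int> make_lookup(const std::string &alphabet, int unknown_idx) {
    std::vector<int> lut(256, unknown_idx);
    for (size_t i = 0; i < alphabet.size(); ++i)
        lut[(unsigned char)alphabet[i]] = (int)i;
    return lut;
}

// Affine-gap Smith-Waterman with traceback. Gap of length L costs
// gap_open + L * gap_extend (BLAST convention: open 11 / extend 1 means a
// single-residue gap costs 12). Reports the optimal local score, the number
// of identical aligned residues and the alignment length in columns
// (mismatches and gaps included), i.e. the quantities behind BLAST's pident.
static void sw_one(const std::string &a, const std::string &b,
                   const IntegerMatrix &mat, const std::vector<int> &lut,
                   int go, int ge,
                   int &best_score, int &n_match, int &aln_len) {
    const int m = (int)a.size(), n = (int)b.size();
    best_score = 0; n_match = 0; aln_len = 0;
    if (m == 0 || n == 0) return;

    const int NEG = -1000000000;
    std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
    std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
    std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
    // traceback codes for H: 0 stop, 1 diag, 2 from E (gap in a), 3 from F (gap in b)
    std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
    std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0); // 1 = extend
    std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);

    std::vector<int> ai(m), bi(n);
    for (int i = 0; i < m; ++i) ai[i] = lut[(unsigned char)a[i]];
    for (int j = 0; j < n; ++j) bi[j] = lut[(unsigned char)b[j]];

    int bi_best = 0, bj_best = 0;
    const size_t W = (size_t)(n + 1);
    for (int i = 1; i <= m; ++i) {
        const int *matrow = &mat((size_t)0, 0); // column-major access handled below
        (void)matrow;
        for (int j = 1; j <= n; ++j) {
            const size_t c = (size_t)i * W + j;
            const size_t up = c - W, left = c - 1, diag = c - W - 1;
            // E: gap in a (consume b)
            int e_open = H[left] - go - ge;
            int e_ext  = E[left] - ge;
            if (e_ext > e_open) { E[c] = e_ext; tbE[c] = 1; }
            else                { E[c] = e_open; tbE[c] = 0; }
            // F: gap in b (consume a)
            int f_open = H[up] - go - ge;
            int f_ext  = F[up] - ge;
            if (f_ext > f_open) { F[c] = f_ext; tbF[c] = 1; }
            else                { F[c] = f_open; tbF[c] = 0; }
            int sub = H[diag] + mat(ai[i - 1], bi[j - 1]);
            int h = 0; uint8_t t = 0;
            if (sub > h) { h = sub; t = 1; }
            if (E[c] > h) { h = E[c]; t = 2; }
            if (F[c] > h) { h = F[c]; t = 3; }
            H[c] = h; tbH[c] = t;
            if (h > best_score) { best_score = h; bi_best = i; bj_best = j; }
        }
    }
    if (best_score <= 0) { best_score = 0; return; }

    // traceback
    int i = bi_best, j = bj_best, state = 0; // 0=H, 1=E, 2=F
    while (i > 0 && j > 0) {
        const size_t c = (size_t)i * W + j;
        if (state == 0) {
            uint8_t t = tbH[c];
            if (t == 0) break;
            if (t == 1) {
                ++aln_len;
                if (a[i - 1] == b[j - 1]) ++n_match;
                --i; --j;
            } else if (t == 2) state = 1;
            else state = 2;
        } else if (state == 1) {
            ++aln_len;
            uint8_t t = tbE[c];
            --j;
            if (t == 0) state = 0;
        } else {
            ++aln_len;
            uint8_t t = tbF[c];
            --i;
            if (t == 0) state = 0;
        }
    }
}

// [[Rcpp::export]]
List cpp_sw_batch(CharacterVector a, CharacterVector b,
                  IntegerMatrix mat, std::string alphabet,
                  int gap_open, int gap_extend, int unknown_idx) {
    const int n = a.size();
    if (b.size() != n) stop("sequence vectors must have equal length");
    std::vector<int> lut = make_lookup(alphabet, unknown_idx);
    IntegerVector score(n), matches(n), alen(n);
    for (int i = 0; i < n; ++i) {
        int s, mt, al;
        sw_one(as<std::string>(a[i]), as<std::string>(b[i]), mat, lut,
               gap_open, gap_extend, s, mt, al);
        score[i] = s; matches[i] = mt; alen[i] = al;
    }
    return List::create(_["score"] = score, _["matches"] = matches,
                        _["aln_len"] = alen);
}

// One query aligned against many subjects (avoids re-copying the query).
// [[Rcpp::export]]
List cpp_sw_many(std::string query, CharacterVector subjects,
                 IntegerMatrix mat, std::string alphabet,
                 int gap_open, int gap_extend, int unknown_idx) {
    const int n = subjects.size();
    std::vector<int> lut = make_lookup(alphabet, unknown_idx);
    IntegerVector score(n), matches(n), alen(n);
    for (int i = 0; i < n; ++i) {
        int s, mt, al;
        sw_one(query, as<std::string>(subjects[i]), mat, lut,
               gap_open, gap_extend, s, mt, al);
        score[i] = s; matches[i] = mt; alen[i] = al;
    }
    return List::create(_["score"] = score, _["matches"] = matches,
                        _["aln_len"] = alen);
}

// Exact amino-acid k-mer seeding: report every (peptide, query) pair that
// shares at least one ungapped exact k-mer. K-mers containing 'X' or '*'
// never seed. Indices returned are 1-based.
// [[Rcpp::export]]
List cpp_seed_scan(CharacterVector peptides, CharacterVector queries, int k) {
    if (k < 2 || k > 12) stop("seed k must be in [2, 12]");
    const std::string alphabet = "ARNDCQEGHILKMFPSTWYV";
    std::vector<int> code(256, -1);
    for (size_t i = 0; i < alphabet.size(); ++i)
        code[(unsigned char)alphabet[i]] = (int)i;

    const int nq = queries.size();
    std::unordered_map<uint64_t, std::vector<int> > index;
    for (int q = 0; q < nq; ++q) {
        std::string s = as<std::string>(queries[q]);
        const int L = (int)s.size();
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < L; ++p) {
            int c = code[(unsigned char)s[p]];
            if (c < 0) { run = 0; key = 0; continue; }
            key = ((key << 5) | (uint64_t)c) & ((k < 12) ? ((1ULL << (5 * k)) - 1) : ~0ULL);
            if (++run >= k) {
                std::vector<int> &v = index[key];
                if (v.empty() || v.back() != q) v.push_back(q);
            }
        }
    }

    std::vector<int> out_pep, out_query;
    std::vector<char> seen(nq, 0);
    std::vector<int> touched;
    const int np = peptides.size();
    for (int p = 0; p < np; ++p) {
        std::string s = as<std::string>(peptides[p]);
        const int L = (int)s.size();
        if (L < k) continue;
        uint64_t key = 0; int run = 0;
        touched.clear();
        for (int i = 0; i < L; ++i) {
            int c = code[(unsigned char)s[i]];
            if (c < 0) { run = 0; key = 0; continue; }
            key = ((key << 5) | (uint64_t)c) & ((k < 12) ? ((1ULL << (5 * k)) - 1) : ~0ULL);
            if (++run >= k) {
                std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
                    index.find(key);
                if (it != index.end()) {
                    for (size_t u = 0; u < it->second.size(); ++u) {
                        int q = it->second[u];
                        if (!seen[q]) {
                            seen[q] = 1;
                            touched.push_back(q);
                            out_pep.push_back(p + 1);
                            out_query.push_back(q + 1);
                        }
                    }
                }
            }
        }
        for (size_t u = 0; u < touched.size(); ++u) seen[touched[u]] = 0;
    }
    return List::create(_["peptide"] = wrap(out_pep), _["query"] = wrap(out_query));
}

// First exact k-mer anchor of `frag` inside `genome`: returns 1-based
// (frag_pos, genome_pos) or (-1, -1). Fragment k-mers are probed every
// `step` bases so a few point mutations cannot mask every probe.
// [[Rcpp::export]]
IntegerVector cpp_anchor(std::string frag, std::string genome, int k, int step) {
    const int L = (int)frag.size();
    if (step < 1) step = 1;
    for (int p = 0; p + k <= L; p += step) {
        size_t pos = genome.find(frag.substr(p, k));
        if (pos != std::string::npos) {
            return IntegerVector::create(p + 1, (int)pos + 1);
        }
    }
    return IntegerVector::create(-1, -1);
}
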