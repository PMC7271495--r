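#' Translated-search parameters
#'
#' Scoring and statistics for the six-frame translated search. Defaults are
#' the standard gapped protein-search parameterization: BLOSUM62 with gap
#' open 11 / extend 1 and the corresponding Karlin-Altschul constants
#' lambda = 0.267 nats per score unit, K = 0.041. E-value cutoffs default
#' to 1e-4 for the target-marker (isoA) screen and 1e-6 for the
#' normalization-marker (recA) screen; candidate hits are verified against
#' a curated set and discarded below 50% amino-acid identity.
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped).
#' @param gap_open,gap_extend gap penalties (> 0); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @param evalue_cutoff_target,evalue_cutoff_norm E-value thresholds.
#' @param min_verify_identity percent identity below which a candidate hit
#'   is discarded at verification (strict `<`).
#' @param seed_k exact amino-acid k-mer length used to pre-select
#'   read/query pairs for alignment.
#' @return a `search_params` list.
#' @export
search_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041,
                          evalue_cutoff_target = 1e-4,
                          evalue_cutoff_norm = 1e-6,
                          min_verify_identity = 50,
                          seed_k = 5L) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0,
            evalue_cutoff_target > 0, evalue_cutoff_norm > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K,
                 evalue_cutoff_target = evalue_cutoff_target,
                 evalue_cutoff_norm = evalue_cutoff_norm,
                 min_verify_identity = min_verify_identity,
                 seed_k = as.integer(seed_k)),
            class = "search_params")
}

# Scoring matrix with '*' made prohibitively negative: local alignments can
# then never cross an in-frame stop codon, which is equivalent to splitting
# each frame at '*' and searching the segments independently.
#' @keywords internal
search_matrix <- function(params) {
  if (!identical(params$matrix, "BLOSUM62")) {
    stop("unsupported substitution matrix: ", params$matrix)
  }
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  stop_i <- which(colnames(mat) == "*")
  mat[stop_i, ] <- -10000L
  mat[, stop_i] <- -10000L
  storage.mode(mat) <- "integer"
  list(mat = mat, alphabet = paste(colnames(mat), collapse = ""),
       unknown_idx = which(colnames(mat) == "X") - 1L)
}

#' Six-frame translation of nucleotide reads
#'
#' Frames +1..+3 read the forward strand, -1..-3 the reverse complement.
#' Codons containing N (or any ambiguity) translate to `X`; stop codons are
#' emitted as `*`. Reads shorter than 3 nt yield empty frames. Together the
#' six frames cover every codon of the read and of its reverse complement
#' exactly once.
#'
#' @param reads character vector or `DNAStringSet` (alphabet ACGTN).
#' @return a `six_frame` object: list with `frames` (list of six character
#'   vectors named `"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`) and
#'   `read_len`.
#' @seealso [frame_to_read_coord()] for the peptide-to-read coordinate map.
#' @export
six_frame_translate <- function(reads) {
  dna <- if (inherits(reads, "DNAStringSet")) reads else
    Biostrings::DNAStringSet(toupper(reads))
  rc <- Biostrings::reverseComplement(dna)
  frames <- vector("list", 6L)
  names(frames) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (f in 1:3) {
    for (strand in c("+", "-")) {
      src <- if (strand == "+") dna else rc
      w <- pmax(Biostrings::width(src) - f + 1L, 0L)
      w3 <- w - (w %% 3L)
      sub <- Biostrings::subseq(src, start = pmin(f, Biostrings::width(src) + 1L),
                                width = w3)
      pep <- suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
      frames[[paste0(strand, f)]] <- as.character(pep)
    }
  }
  structure(list(frames = frames, read_len = Biostrings::width(dna)),
            class = "six_frame")
}

#' Map a peptide position back to read coordinates
#'
#' Returns the 0-based forward-strand coordinate of the first base of the
#' codon encoding peptide position `pep_pos` in the given frame.
#'
#' @param frame one of `"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`.
#' @param pep_pos 1-based position in the frame's peptide.
#' @param read_len read length in nt.
#' @return 0-based read coordinate of the codon start.
#' @export
frame_to_read_coord <- function(frame, pep_pos, read_len) {
  f <- as.integer(substr(frame, 2L, 2L))
  off <- (f - 1L) + 3L * (pep_pos - 1L)
  ifelse(substr(frame, 1L, 1L) == "+", off, read_len - off - 3L)
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman with affine gaps under the parameterization in `params`.
#' Identity is computed over aligned columns (gaps included), as in BLAST's
#' pident.
#'
#' @param query,subject amino-acid strings (vectors are aligned pairwise).
#' @param params a [search_params()].
#' @return data.frame with `raw_score`, `pct_identity`, `aln_len`.
#' @export
local_align <- function(query, subject, params = search_params()) {
  stopifnot(all(nzchar(query)), all(nzchar(subject)))
  sm <- search_matrix(params)
  r <- cpp_sw_batch(as.character(query), as.character(subject), sm$mat,
                    sm$alphabet, as.integer(params$gap_open),
                    as.integer(params$gap_extend), sm$unknown_idx)
  data.frame(raw_score = r$score,
             pct_identity = ifelse(r$aln_len > 0, 100 * r$matches / r$aln_len, 0),
             aln_len = r$aln_len)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments of score at least `S` between random sequences of total
#' lengths `m` and `n`. Strictly decreasing in the score and linear in
#' each search-space dimension.
#'
#' @param raw_score alignment raw score(s).
#' @param m query residues.
#' @param n searched residues (for a translated read search: the total
#'   number of residues in all six frames actually searched).
#' @param params a [search_params()].
#' @return E-value(s).
#' @export
estimate_evalue <- function(raw_score, m, n, params = search_params()) {
  stopifnot(m > 0, n > 0)
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' @keywords internal
read_seqs_ids <- function(reads) {
  if (inherits(reads, "read_set")) {
    list(seq = reads$seq, id = reads$id)
  } else if (inherits(reads, "DNAStringSet")) {
    list(seq = as.character(reads), id = names(reads))
  } else {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
    list(seq = unname(as.character(reads)), id = ids)
  }
}

#' Six-frame translated search of protein queries against reads
#'
#' Emulates a tBLASTn-style screen: every read is translated in six frames,
#' frames sharing an exact amino-acid k-mer with a query are aligned by
#' Smith-Waterman, scores are converted to Karlin-Altschul E-values against
#' the total translated search space, and hits with `evalue <= cutoff` are
#' reported -- at most one hit per (query, read) pair (best score; ties go
#' to the lowest frame index in the order +1, +2, +3, -1, -2, -3).
#'
#' @param queries a `protein_references` set (or named character vector).
#' @param reads a `read_set`, `DNAStringSet` or named character vector.
#' @param params a [search_params()].
#' @param cutoff E-value threshold (default: the target-marker cutoff).
#' @return an `alignment_hits` data.frame: `query_id`, `read_id`, `frame`,
#'   `raw_score`, `evalue`, `pct_identity`, `aln_len`, plus the translated
#'   read segment (`frame_peptide`) used downstream by [verify_hits()].
#' @export
search_translated <- function(queries, reads, params = search_params(),
                              cutoff = params$evalue_cutoff_target) {
  if (inherits(queries, "protein_references")) {
    qseq <- setNames(queries$sequence, queries$ref_id)
  } else {
    qseq <- queries
    if (is.null(names(qseq))) stop("queries must be named")
  }
  if (!length(qseq)) stop("queries non-empty required")

  empty <- data.frame(query_id = character(), read_id = character(),
                      frame = character(), raw_score = numeric(),
                      evalue = numeric(), pct_identity = numeric(),
                      aln_len = integer(), frame_peptide = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("alignment_hits", "data.frame")

  rd <- read_seqs_ids(reads)
  n_reads <- length(rd$seq)
  if (!n_reads) return(empty)

  sf <- six_frame_translate(rd$seq)
  frame_names <- names(sf$frames)
  peptides <- unlist(sf$frames, use.names = FALSE)     # 6 blocks of n_reads
  n_total <- sum(nchar(peptides))

  seeds <- cpp_seed_scan(peptides, unname(qseq), params$seed_k)
  if (!length(seeds$peptide)) return(empty)

  sm <- search_matrix(params)
  aln <- cpp_sw_batch(unname(qseq)[seeds$query], peptides[seeds$peptide],
                      sm$mat, sm$alphabet, as.integer(params$gap_open),
                      as.integer(params$gap_extend), sm$unknown_idx)

  frame_i <- ((seeds$peptide - 1L) %/% n_reads) + 1L    # 1..6
  read_i <- ((seeds$peptide - 1L) %% n_reads) + 1L
  m <- nchar(qseq)[seeds$query]
  ev <- estimate_evalue(aln$score, m, n_total, params)

  keep <- ev <= cutoff & aln$score > 0
  if (!any(keep)) return(empty)

  hits <- data.frame(query_id = names(qseq)[seeds$query][keep],
                     read_id = rd$id[read_i[keep]],
                     frame = frame_names[frame_i[keep]],
                     raw_score = aln$score[keep],
                     evalue = ev[keep],
                     pct_identity = 100 * aln$matches[keep] / aln$aln_len[keep],
                     aln_len = aln$aln_len[keep],
                     frame_peptide = peptides[seeds$peptide[keep]],
                     stringsAsFactors = FALSE)

  # one hit per (query, read): best score, ties -> lowest frame index
  fr_rank <- match(hits$frame, frame_names)
  ord <- order(hits$query_id, hits$read_id, -hits$raw_score, fr_rank)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("query_id", "read_id")]), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

#' Verify candidate hits against a curated protein set
#'
#' Emulates the manual BLASTx check of candidate marker reads: each hit's
#' translated read segment is aligned against every protein in the
#' verification set and the best percent identity is recorded. Hits below
#' `min_verify_identity` (strict `<`) are discarded; surviving hits are
#' deduplicated to one per read (best E-value; ties broken by
#' lexicographically smallest query id), giving the "unique hits" that are
#' counted downstream.
#'
#' @param hits an `alignment_hits` data.frame from [search_translated()].
#' @param verification_set a `protein_references` set (non-empty).
#' @param params a [search_params()].
#' @return a `verified_hits` list: `n_unique` (the unique verified hit
#'   count), `table` (all hits with `verify_identity` and `kept`), and
#'   `unique_hits` (the deduplicated table).
#' @export
verify_hits <- function(hits, verification_set, params = search_params()) {
  if (inherits(verification_set, "protein_references")) {
    vseq <- setNames(verification_set$sequence, verification_set$ref_id)
  } else {
    vseq <- verification_set
  }
  if (!length(vseq)) stop("verification impossible: empty verification set")

  if (!nrow(hits)) {
    return(structure(list(n_unique = 0L,
                          table = cbind(hits, verify_identity = numeric(0),
                                        kept = logical(0)),
                          unique_hits = hits),
                     class = "verified_hits"))
  }

  sm <- search_matrix(params)
  best_id <- rep(0, nrow(hits))
  for (v in vseq) {
    r <- cpp_sw_many(v, hits$frame_peptide, sm$mat, sm$alphabet,
                     as.integer(params$gap_open),
                     as.integer(params$gap_extend), sm$unknown_idx)
    pid <- ifelse(r$aln_len > 0, 100 * r$matches / r$aln_len, 0)
    best_id <- pmax(best_id, pid)
  }
  tab <- hits
  tab$verify_identity <- best_id
  tab$kept <- best_id >= params$min_verify_identity

  kept <- tab[tab$kept, , drop = FALSE]
  if (nrow(kept)) {
    ord <- order(kept$read_id, kept$evalue, kept$query_id)
    kept <- kept[ord, , drop = FALSE]
    kept <- kept[!duplicated(kept$read_id), , drop = FALSE]
    rownames(kept) <- NULL
  }
  structure(list(n_unique = nrow(kept), table = tab, unique_hits = kept),
            class = "verified_hits")
}

#' Count unique hits without identity verification
#'
#' Deduplicates hits to one per read (best E-value, ties by query id); used
#' for the normalization marker (recA), whose screen applies only the
#' E-value cutoff.
#'
#' @param hits an `alignment_hits` data.frame.
#' @return integer count of unique reads hit.
#' @export
count_unique_hits <- function(hits) {
  length(unique(hits$read_id))
}
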