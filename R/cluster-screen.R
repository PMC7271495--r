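#' Read gene annotations
#'
#' Annotations are a data.frame with columns `contig_id`, `gene_id`,
#' `start`, `end` (1-based inclusive), `strand` and `protein` (the
#' annotated translation). The TSV reader expects exactly those columns;
#' the GFF3 reader takes CDS features carrying a `translation` attribute.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gff3"`.
#' @return an annotations data.frame.
#' @export
read_annotations <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("contig_id", "gene_id", "start", "end", "strand", "protein")
    missing <- setdiff(need, names(ann))
    if (length(missing)) {
      stop("annotation TSV missing columns: ", paste(missing, collapse = ", "))
    }
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "CDS", TRUE)
    f <- f[keep]
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0(key, "=([^;]+)"), attrs))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    ann <- do.call(rbind, lapply(f, function(x) {
      data.frame(contig_id = x[1],
                 gene_id = attr_get(x[9], "ID"),
                 start = as.integer(x[4]), end = as.integer(x[5]),
                 strand = x[7],
                 protein = attr_get(x[9], "translation"),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ann) || anyNA(ann$protein)) {
      stop("GFF3 CDS features must carry ID and translation attributes")
    }
  }
  stopifnot(all(ann$start <= ann$end))
  ann
}

#' Assign iso-gene homologs to annotated proteins
#'
#' Each annotated protein is locally aligned (protein vs protein) against
#' every reference in the iso-pathway panel; the best-scoring reference
#' decides the gene assignment, and the hit's Karlin-Altschul E-value
#' decides the tier: `restrictive` below `1e-40`, `permissive` below
#' `1e-10` (every restrictive assignment is by construction also
#' permissive). Proteins passing neither tier are unassigned.
#'
#' @param annotations annotations data.frame (see [read_annotations()]).
#' @param references a `protein_references` set with `iso_gene` labels.
#' @param params a [search_params()].
#' @param permissive_cutoff,restrictive_cutoff E-value tier thresholds
#'   (strict `<`).
#' @return data.frame `gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `iso_gene`, `ref_id`, `raw_score`, `evalue`, `pct_identity`, `tier`.
#' @export
assign_homologs <- function(annotations, references, params = search_params(),
                            permissive_cutoff = 1e-10,
                            restrictive_cutoff = 1e-40) {
  if (!nrow(references)) stop("empty reference set")
  if (anyNA(references$iso_gene)) stop("references must carry iso_gene labels")
  sm <- search_matrix(params)
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    prot <- annotations$protein[i]
    r <- cpp_sw_many(prot, references$sequence, sm$mat, sm$alphabet,
                     as.integer(params$gap_open),
                     as.integer(params$gap_extend), sm$unknown_idx)
    ev <- estimate_evalue(r$score, nchar(references$sequence), nchar(prot),
                          params)
    b <- which.min(ev)
    if (ev[b] >= permissive_cutoff) next
    out[[i]] <- data.frame(
      gene_id = annotations$gene_id[i], contig_id = annotations$contig_id[i],
      start = annotations$start[i], end = annotations$end[i],
      strand = annotations$strand[i],
      iso_gene = references$iso_gene[b], ref_id = references$ref_id[b],
      raw_score = r$score[b], evalue = ev[b],
      pct_identity = if (r$aln_len[b] > 0) 100 * r$matches[b] / r$aln_len[b] else 0,
      tier = if (ev[b] < restrictive_cutoff) "restrictive" else "permissive",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      iso_gene = character(), ref_id = character(),
                      raw_score = numeric(), evalue = numeric(),
                      pct_identity = numeric(), tier = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

CORE_GENES <- c("isoA", "isoB", "isoC", "isoD", "isoE", "isoF")
EXTENDED_GENES <- c("isoG", "isoH", "isoI", "isoJ")
ACCESSORY_GENES <- c("aldH1", "aldH2", "gshB", "garB", "CoA-DSR")

#' Detect isoprene-degradation gene clusters
#'
#' Groups assigned iso genes per contig into clusters (consecutive genes
#' at most `max_gap` bp apart, strand-agnostic, in coordinate order) and
#' classifies each contig:
#' `complete` -- all six core genes (isoABCDEF) plus all four extended
#' genes (isoGHIJ) clustered; `putative_novel` -- the full core present
#' (any tier) with no isoGHIJ homolog recovered anywhere in the input,
#' the signature of a potentially novel pathway variant; `core_only` --
#' full core with an incomplete extended set; `partial` -- some but not
#' all core genes; `none` -- no assignment. Clusters are never bridged
#' across contigs; a cluster split over contigs shows up as two reports.
#'
#' @param assignments output of [assign_homologs()].
#' @param annotations the annotations the assignments refer to.
#' @param max_gap maximum intergenic distance (bp) within a cluster.
#' @return a `cluster_report` data.frame, one row per contig that carries
#'   at least one assignment (plus `none` rows for contigs without):
#'   `contig_id`, `genes` (ordered, comma-separated), `core_count`,
#'   `extended_count`, `accessory` (comma-separated), `max_gap_bp`,
#'   `n_clusters`, `classification`.
#' @export
detect_clusters <- function(assignments, annotations, max_gap = 5000) {
  contigs <- unique(annotations$contig_id)
  ext_anywhere <- any(assignments$iso_gene %in% EXTENDED_GENES)
  out <- vector("list", length(contigs))
  for (k in seq_along(contigs)) {
    cid <- contigs[k]
    a <- assignments[assignments$contig_id == cid, , drop = FALSE]
    if (!nrow(a)) {
      out[[k]] <- data.frame(contig_id = cid, genes = "", core_count = 0L,
                             extended_count = 0L, accessory = "",
                             max_gap_bp = NA_integer_, n_clusters = 0L,
                             classification = "none", stringsAsFactors = FALSE)
      next
    }
    a <- a[order(a$start), , drop = FALSE]
    gaps <- if (nrow(a) > 1) a$start[-1] - a$end[-nrow(a)] else integer()
    cluster_id <- cumsum(c(1L, as.integer(gaps > max_gap)))
    # best cluster = the one with the most distinct core genes, then most genes
    score <- vapply(split(seq_len(nrow(a)), cluster_id), function(idx) {
      length(intersect(a$iso_gene[idx], CORE_GENES)) * 1000 + length(idx)
    }, 0)
    best <- as.integer(names(score)[which.max(score)])
    cl <- a[cluster_id == best, , drop = FALSE]
    core <- length(intersect(cl$iso_gene, CORE_GENES))
    ext <- length(intersect(cl$iso_gene, EXTENDED_GENES))
    acc <- intersect(cl$iso_gene, ACCESSORY_GENES)
    classification <- if (core == 6 && ext == 4) "complete"
      else if (core == 6 && !ext_anywhere) "putative_novel"
      else if (core == 6) "core_only"
      else if (core > 0) "partial"
      else "none"
    cl_gaps <- if (nrow(cl) > 1) cl$start[-1] - cl$end[-nrow(cl)] else NA_integer_
    out[[k]] <- data.frame(
      contig_id = cid, genes = paste(a$iso_gene, collapse = ","),
      core_count = core, extended_count = ext,
      accessory = paste(acc, collapse = ","),
      max_gap_bp = if (all(is.na(cl_gaps))) NA_integer_ else max(cl_gaps),
      n_clusters = max(cluster_id),
      classification = classification, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("cluster_report", "data.frame")
  out
}

#' MAG quality gate
#'
#' Pass if completeness strictly exceeds `completeness_min` and
#' contamination is strictly below `contamination_max` -- both strict
#' inequalities, so a MAG at exactly 75% completeness or exactly 10%
#' contamination fails. The default gate (75 / 10) is the reporting gate;
#' reassembly pipelines often use the stricter `contamination_max = 5`.
#'
#' @param quality data.frame with columns `mag_id`, `completeness`,
#'   `contamination` (percent, 0-100).
#' @param completeness_min,contamination_max gate thresholds (percent).
#' @return the quality table with a logical `pass` column.
#' @export
mag_gate <- function(quality, completeness_min = 75, contamination_max = 10) {
  stopifnot(all(c("completeness", "contamination") %in% names(quality)),
            all(quality$completeness >= 0 & quality$completeness <= 100),
            all(quality$contamination >= 0 & quality$contamination <= 100))
  quality$pass <- quality$completeness > completeness_min &
                  quality$contamination < contamination_max
  quality
}

#' Fragment-based average nucleotide identity
#'
#' Genome A is cut into consecutive `fragment_len` pieces (the final
#' partial fragment is discarded). Each fragment is anchored in genome B
#' by an exact nucleotide k-mer seed (either strand) and locally aligned
#' to the anchored window; fragments aligning at >= 30% identity over
#' >= 70% of their length are retained, and ANI is the mean identity of
#' retained fragments. Fragments without a seed anywhere in genome B are
#' not retained (random unrelated sequence thus yields an undefined ANI).
#'
#' @param genome_a,genome_b character vectors of contig sequences (a
#'   single string is fine).
#' @param fragment_len fragment size in bp (default 1020, the classical
#'   fragment-based ANI recipe).
#' @param seed_k exact-match anchor length in nt.
#' @return an `ani_result` list: `ani` (percent, `NA` if undefined),
#'   `n_fragments_used`, `n_fragments_total`, and the per-fragment table.
#' @export
compute_ani <- function(genome_a, genome_b, fragment_len = 1020, seed_k = 14L) {
  stopifnot(length(genome_a) > 0, length(genome_b) > 0,
            all(nzchar(genome_a)), all(nzchar(genome_b)))
  # nucleotide scoring: +2 match / -3 mismatch, gap open 5 extend 2
  alpha <- c("A", "C", "G", "T", "N")
  mat <- matrix(-3L, 5, 5, dimnames = list(alpha, alpha))
  diag(mat) <- 2L
  mat["N", ] <- -1L; mat[, "N"] <- -1L

  frags <- unlist(lapply(genome_a, function(s) {
    n_full <- nchar(s) %/% fragment_len
    if (!n_full) return(character())
    starts <- (seq_len(n_full) - 1L) * fragment_len + 1L
    substring(s, starts, starts + fragment_len - 1L)
  }))
  n_total <- length(frags)
  if (!n_total) {
    warning("genome_a shorter than one fragment; ANI undefined")
    return(structure(list(ani = NA_real_, n_fragments_used = 0L,
                          n_fragments_total = 0L, fragments = NULL),
                     class = "ani_result"))
  }

  subj <- paste(toupper(genome_b), collapse = strrep("N", seed_k))
  subj_rc <- revcomp_chr(subj)
  pad <- 100L
  res <- data.frame(fragment = seq_len(n_total), identity = NA_real_,
                    coverage = NA_real_, retained = FALSE)
  for (i in seq_len(n_total)) {
    fr <- toupper(frags[i])
    anc <- cpp_anchor(fr, subj, seed_k, 32L)
    target <- subj
    if (anc[1] < 0) {
      anc <- cpp_anchor(fr, subj_rc, seed_k, 32L)
      target <- subj_rc
    }
    if (anc[1] < 0) next
    win_lo <- max(1L, anc[2] - anc[1] + 1L - pad)
    win_hi <- min(nchar(target), anc[2] + (fragment_len - anc[1]) + pad)
    window <- substr(target, win_lo, win_hi)
    r <- cpp_sw_batch(fr, window, mat, paste(alpha, collapse = ""),
                      5L, 2L, 4L)
    if (r$aln_len == 0) next
    res$identity[i] <- 100 * r$matches / r$aln_len
    res$coverage[i] <- 100 * r$aln_len / fragment_len
    res$retained[i] <- res$identity[i] >= 30 && res$coverage[i] >= 70
  }
  used <- which(res$retained)
  ani <- if (length(used)) mean(res$identity[used]) else NA_real_
  if (!length(used)) warning("no fragments retained; ANI undefined")
  structure(list(ani = ani, n_fragments_used = length(used),
                 n_fragments_total = n_total, fragments = res),
            class = "ani_result")
}
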