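#' Normalize marker hit counts across metagenomes
#'
#' Unique verified hit counts are made comparable across metagenomes and
#' genes by two multiplicative factors: depth scaling `N_min / N_i` (reads
#' in the smallest metagenome over reads in metagenome i) and length
#' scaling `L_min / L_gene` (shortest reference gene over the hit gene's
#' length, in residues). Scaled counts are then summed per metagenome and
#' role. With `length_norm = "global"` (default) `L_min` is taken across
#' both the target and the normalization sets, which makes the two totals
#' commensurable as genome-count proxies; `"per_set"` restricts `L_min`
#' to each role's own gene set.
#'
#' @param hits_by_gene data.frame with columns `metagenome_id`, `ref_id`,
#'   `role` (`"target"` or `"norm"`), `n_hits`.
#' @param stats data.frame with columns `metagenome_id`, `n_reads`
#'   (and optionally `mean_read_length`).
#' @param gene_lengths named vector: reference gene lengths in residues.
#' @param length_norm `"global"` or `"per_set"`.
#' @return data.frame `metagenome_id`, `role`, `raw_hits`, `scaled_hits`.
#' @export
normalize_hits <- function(hits_by_gene, stats, gene_lengths,
                           length_norm = c("global", "per_set")) {
  length_norm <- match.arg(length_norm)
  stopifnot(all(c("metagenome_id", "ref_id", "role", "n_hits") %in%
                names(hits_by_gene)),
            all(c("metagenome_id", "n_reads") %in% names(stats)),
            all(stats$n_reads > 0))
  missing_len <- setdiff(unique(hits_by_gene$ref_id), names(gene_lengths))
  if (length(missing_len)) {
    stop("missing gene length for: ", paste(missing_len, collapse = ", "))
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")

  n_min <- min(stats$n_reads)
  depth <- n_min / stats$n_reads[match(hits_by_gene$metagenome_id,
                                       stats$metagenome_id)]
  if (anyNA(depth)) stop("metagenome missing from stats")

  glen <- gene_lengths[hits_by_gene$ref_id]
  l_min <- if (length_norm == "global") {
    rep(min(gene_lengths[unique(hits_by_gene$ref_id)]), nrow(hits_by_gene))
  } else {
    vapply(hits_by_gene$role, function(r) {
      min(gene_lengths[unique(hits_by_gene$ref_id[hits_by_gene$role == r])])
    }, 0)
  }
  scaled <- hits_by_gene$n_hits * depth * (l_min / glen)

  agg <- stats::aggregate(cbind(raw_hits = hits_by_gene$n_hits,
                                scaled_hits = scaled),
                          by = list(metagenome_id = hits_by_gene$metagenome_id,
                                    role = hits_by_gene$role),
                          FUN = sum)
  agg[order(agg$metagenome_id, agg$role), , drop = FALSE]
}

#' Percentage of bacteria carrying the target marker
#'
#' `100 * scaled_target / scaled_norm`: with a strictly single-copy
#' normalization marker (recA), the scaled normalization total is a proxy
#' for the number of genomes sampled, so the ratio reads as "percent of
#' bacteria containing the marker gene".
#'
#' @param target_scaled,norm_scaled scaled hit totals (vectorized).
#' @return percent carriers; `NA` (with a warning) when both totals are 0.
#' @export
percent_marker_carriers <- function(target_scaled, norm_scaled) {
  stopifnot(all(norm_scaled >= 0), all(target_scaled >= 0))
  bad <- norm_scaled == 0 & target_scaled > 0
  if (any(bad)) {
    stop("degenerate normalization: zero normalization-marker hits with ",
         "nonzero target hits")
  }
  undef <- norm_scaled == 0 & target_scaled == 0
  if (any(undef)) {
    warning("percent carriers undefined (no hits of either marker); NA returned")
  }
  out <- ifelse(undef, NA_real_, 100 * target_scaled / norm_scaled)
  out[!undef & target_scaled == 0] <- 0
  out
}

#' Per-metagenome marker-abundance results
#'
#' Convenience wrapper combining [normalize_hits()] and
#' [percent_marker_carriers()] into one row per metagenome.
#'
#' @inheritParams normalize_hits
#' @return a `marker_abundance_result` data.frame: `metagenome_id`,
#'   `raw_target_hits`, `raw_norm_hits`, `scaled_target_hits`,
#'   `scaled_norm_hits`, `pct_carriers`.
#' @export
marker_abundance <- function(hits_by_gene, stats, gene_lengths,
                             length_norm = c("global", "per_set")) {
  sc <- normalize_hits(hits_by_gene, stats, gene_lengths, length_norm)
  ids <- unique(sc$metagenome_id)
  get <- function(id, role, col) {
    v <- sc[[col]][sc$metagenome_id == id & sc$role == role]
    if (length(v)) v else 0
  }
  out <- data.frame(
    metagenome_id = ids,
    raw_target_hits = vapply(ids, get, 0, role = "target", col = "raw_hits"),
    raw_norm_hits = vapply(ids, get, 0, role = "norm", col = "raw_hits"),
    scaled_target_hits = vapply(ids, get, 0, role = "target", col = "scaled_hits"),
    scaled_norm_hits = vapply(ids, get, 0, role = "norm", col = "scaled_hits"),
    stringsAsFactors = FALSE)
  out$pct_carriers <- percent_marker_carriers(out$scaled_target_hits,
                                              out$scaled_norm_hits)
  rownames(out) <- NULL
  class(out) <- c("marker_abundance_result", "data.frame")
  out
}

#' Pairwise habitat comparison of marker-carrier percentages
#'
#' For every pair of metagenomes, reports the fold-ratio of their
#' percent-carrier values with the larger/smaller convention and the
#' direction. Pairs with an undefined percentage are skipped with a
#' warning; a zero percentage yields an infinite fold flagged as
#' undefined rather than a numeric ratio.
#'
#' @param results a `marker_abundance_result` data.frame (>= 2 rows).
#' @return data.frame `metagenome_a`, `metagenome_b`, `pct_a`, `pct_b`,
#'   `fold` (larger / smaller), `higher`, `defined`.
#' @export
compare_habitats <- function(results) {
  if (nrow(results) < 2) stop("need at least two metagenomes to compare")
  pairs <- utils::combn(nrow(results), 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    pa <- results$pct_carriers[i]; pb <- results$pct_carriers[j]
    if (is.na(pa) || is.na(pb)) {
      warning("skipping pair with undefined percent carriers: ",
              results$metagenome_id[i], " vs ", results$metagenome_id[j])
      next
    }
    fold <- max(pa, pb) / min(pa, pb)
    out[[k]] <- data.frame(
      metagenome_a = results$metagenome_id[i],
      metagenome_b = results$metagenome_id[j],
      pct_a = pa, pct_b = pb, fold = fold,
      higher = if (pa >= pb) results$metagenome_id[i] else results$metagenome_id[j],
      defined = is.finite(fold),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(metagenome_a = character(), metagenome_b = character(),
                      pct_a = numeric(), pct_b = numeric(), fold = numeric(),
                      higher = character(), defined = logical())
  }
  rownames(out) <- NULL
  out
}
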