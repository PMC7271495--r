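#' Enrichment-calling parameters
#'
#' Numeric thresholds behind the labeled / not-confirmed / unlabeled
#' decision. The defaults reproduce the qualitative logic used when
#' reading SIP fold-changes: heavy/light ratios of ~19-90x are treated as
#' decisive labeling, while a modest ratio (e.g. 2.2x) that is matched by
#' the 12C control is not confirmed. A pseudocount of 1e-4 on relative
#' abundances (about one read in a 10^4-read sample) keeps ratios finite.
#'
#' @param min_fold_13C minimum heavy/light fold-change in the 13C
#'   incubation for a labeled call.
#' @param min_control_ratio minimum `fc_13C / fc_12C` when a 12C control
#'   is available.
#' @param pseudocount relative-abundance floor added to numerator and
#'   denominator.
#' @return an `enrichment_params` list.
#' @export
enrichment_params <- function(min_fold_13C = 5, min_control_ratio = 2,
                              pseudocount = 1e-4) {
  stopifnot(min_fold_13C > 0, min_control_ratio > 0, pseudocount > 0)
  structure(list(min_fold_13C = min_fold_13C,
                 min_control_ratio = min_control_ratio,
                 pseudocount = pseudocount),
            class = "enrichment_params")
}

#' @keywords internal
as_profile <- function(x) {
  df <- as.data.frame(x)
  if (!"density" %in% names(df) && "mean_density" %in% names(df)) {
    df$density <- df$mean_density
  }
  stopifnot(all(c("density", "dna_amount") %in% names(df)),
            all(df$dna_amount >= 0))
  if (any(duplicated(df$density))) stop("densities must be strictly monotonic")
  df[order(df$density), c("density", "dna_amount")]
}

#' @keywords internal
smooth3 <- function(x) {
  if (length(x) < 3) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  s[1] <- x[1]; s[length(x)] <- x[length(x)]
  s
}

#' Identify heavy and light gradient fractions
#'
#' Reproduces the "plot DNA abundance vs fraction density" step of a SIP
#' experiment. The light window is the contiguous band around the 12C
#' control profile's DNA peak (points at >= 50% of the peak signal after
#' 3-point moving-average smoothing -- the full-width-half-maximum band,
#' as when light fractions are picked at the 12C peak). The heavy window is centred on the
#' labeled profile's excess-DNA peak at higher density (peak = local
#' maximum of the smoothed excess over the control, on normalized shapes;
#' ties go to the denser peak) and spans the contiguous excess band around
#' it (>= 5% of the peak excess), extended to the dense end of the
#' gradient -- heavy fractions are pooled, as when combining fractions for
#' sequencing. If no excess peak resolves -- e.g. no labeling occurred --
#' the heavy window falls back to a fixed +0.03 to +0.04 g/ml offset from
#' the light peak, with a warning.
#'
#' @param labeled_profile,control_profile data.frames with columns
#'   `density` (or `mean_density`) and `dna_amount`, >= 6 points each; the
#'   `profile` element of a [simulate_gradient()] result works directly.
#' @return a `fraction_window` list: `heavy` and `light` density ranges
#'   `c(lo, hi)`, the peak densities, the point indices each window covers
#'   in the corresponding input profile (in the input's row order), and a
#'   `fallback` flag.
#' @export
identify_fractions <- function(labeled_profile, control_profile) {
  lab_in <- as.data.frame(labeled_profile)
  ctl_in <- as.data.frame(control_profile)
  lab <- as_profile(labeled_profile)
  ctl <- as_profile(control_profile)
  if (nrow(lab) < 6 || nrow(ctl) < 6) stop("need >= 6 points per profile")

  spacing <- stats::median(diff(lab$density))
  half <- spacing / 2

  ctl_s <- smooth3(ctl$dna_amount)
  peak_i <- which(ctl_s == max(ctl_s))
  light_i <- max(peak_i)                          # tie -> denser
  light_peak <- ctl$density[light_i]
  run <- contiguous_run(ctl_s >= 0.50 * ctl_s[light_i], light_i)
  light <- c(ctl$density[run[1]] - half, ctl$density[run[2]] + half)

  # excess of the labeled profile over the control, on normalized shapes
  ctl_at <- stats::approx(ctl$density, ctl$dna_amount / sum(ctl$dna_amount),
                          xout = lab$density, rule = 2)$y
  excess <- smooth3(lab$dna_amount / sum(lab$dna_amount) - ctl_at)

  n <- length(excess)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) excess[i - 1] else -Inf
    right <- if (i < n) excess[i + 1] else -Inf
    excess[i] > 0 && excess[i] >= left && excess[i] >= right
  }, TRUE)
  # a resolvable peak must carry a material mass excess (0.5% of total DNA)
  cand <- which(is_peak & lab$density > light_peak & excess > 0.005)

  fallback <- FALSE
  if (length(cand)) {
    best <- cand[excess[cand] == max(excess[cand])]
    heavy_i <- max(best)                          # tie -> denser
    heavy_peak <- lab$density[heavy_i]
    hrun <- contiguous_run(excess >= 0.05 * excess[heavy_i], heavy_i)
    heavy <- c(lab$density[hrun[1]] - half,
               max(lab$density) + half)           # pool to the dense end
  } else {
    fallback <- TRUE
    warning("no resolvable heavy peak; falling back to fixed offset window")
    heavy <- light_peak + c(0.03, 0.04)
    heavy_peak <- mean(heavy)
  }
  if (heavy[1] <= light[2]) {                     # enforce non-overlap
    mid <- (heavy_peak + light_peak) / 2
    light[2] <- min(light[2], mid)
    heavy[1] <- max(heavy[1], mid + 1e-9)
  }

  df_dens <- function(df) {
    if ("density" %in% names(df)) df$density else df$mean_density
  }
  in_window <- function(df, w) which(df_dens(df) >= w[1] & df_dens(df) <= w[2])
  structure(list(heavy = heavy, light = light,
                 heavy_peak = heavy_peak, light_peak = light_peak,
                 heavy_idx = in_window(lab_in, heavy),
                 light_idx = in_window(ctl_in, light),
                 fallback = fallback),
            class = "fraction_window")
}

# largest run of TRUE containing index i
#' @keywords internal
contiguous_run <- function(ok, i) {
  lo <- i
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i
  while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  c(lo, hi)
}

#' Pooled community composition of a density window
#'
#' Mass-weighted pooling of the per-fraction compositions whose mean
#' density falls inside the window -- the in-silico equivalent of
#' combining the DNA of the fractions spanning a heavy or light peak.
#'
#' @param fractions a `sip_fractions` object from [simulate_gradient()].
#' @param window numeric `c(lo, hi)` density range (g/ml), e.g. the
#'   `heavy` or `light` element of a [identify_fractions()] result.
#' @return named relative-abundance vector summing to 1.
#' @export
window_composition <- function(fractions, window) {
  stopifnot(inherits(fractions, "sip_fractions"), length(window) == 2)
  sel <- fractions$profile$mean_density >= window[1] &
         fractions$profile$mean_density <= window[2]
  if (!any(sel)) stop("window covers no fractions")
  mass <- colSums(fractions$taxon_mass[sel, , drop = FALSE])
  if (sum(mass) == 0) stop("window contains no DNA")
  mass / sum(mass)
}

#' Heavy/light fold-enrichment per taxon
#'
#' `fc = (RA_heavy + pseudocount) / (RA_light + pseudocount)` for the 13C
#' incubation, and analogously for the 12C control when both control
#' columns are present.
#'
#' @param table taxa x samples matrix (or data.frame) of relative
#'   abundances; column names drawn from `T0`, `13C_H`, `13C_L`, `13C_UF`,
#'   `12C_H`, `12C_L`. Columns must each sum to 1 (tolerance 1e-6).
#' @param params an [enrichment_params()].
#' @return an `enrichment_records` data.frame: `taxon`, `fc_13C`,
#'   `fc_12C` (NA when no control), plus the RA columns used.
#' @export
fold_enrichment <- function(table, params = enrichment_params()) {
  tab <- as.matrix(table)
  need <- c("13C_H", "13C_L")
  missing <- setdiff(need, colnames(tab))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  if (any(tab < 0)) stop("relative abundances must be >= 0")
  sums <- colSums(tab)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("sample columns must sum to 1: ",
         paste(colnames(tab)[abs(sums - 1) > 1e-6], collapse = ", "))
  }
  pc <- params$pseudocount
  fc13 <- (tab[, "13C_H"] + pc) / (tab[, "13C_L"] + pc)
  has12 <- all(c("12C_H", "12C_L") %in% colnames(tab))
  fc12 <- if (has12) (tab[, "12C_H"] + pc) / (tab[, "12C_L"] + pc) else
    rep(NA_real_, nrow(tab))
  out <- data.frame(taxon = rownames(tab), fc_13C = unname(fc13),
                    fc_12C = unname(fc12),
                    ra_13C_H = unname(tab[, "13C_H"]),
                    ra_13C_L = unname(tab[, "13C_L"]),
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Call labeled taxa from fold-enrichment records
#'
#' A taxon is `labeled` when its 13C heavy/light fold-change reaches
#' `min_fold_13C` and, where a 12C control exists, the 13C fold-change
#' exceeds the control fold-change by at least `min_control_ratio` -- a
#' taxon whose heavy/light ratio is matched in the 12C control (the
#' *Rhizobium* pattern) is `not_confirmed`, not labeled. Everything below
#' the fold threshold is `unlabeled`. Unfractionated relative abundance,
#' when supplied, is carried along as supporting evidence only; it never
#' changes a call.
#'
#' @param records an `enrichment_records` data.frame from
#'   [fold_enrichment()].
#' @param params an [enrichment_params()].
#' @param ra_unfractionated optional named vector of unfractionated RAs.
#' @return the records with `call` (and `ra_unfractionated`) added.
#' @export
call_labeled <- function(records, params = enrichment_params(),
                         ra_unfractionated = NULL) {
  stopifnot(all(c("taxon", "fc_13C", "fc_12C") %in% names(records)))
  fold_ok <- records$fc_13C >= params$min_fold_13C
  ctrl_ok <- is.na(records$fc_12C) |
    (records$fc_13C / records$fc_12C >= params$min_control_ratio)
  records$call <- ifelse(fold_ok & ctrl_ok, "labeled",
                  ifelse(fold_ok, "not_confirmed", "unlabeled"))
  records$ra_unfractionated <- if (!is.null(ra_unfractionated)) {
    unname(ra_unfractionated[records$taxon])
  } else NA_real_
  records
}
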