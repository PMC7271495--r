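#' Isopycnic gradient model
#'
#' Linear buoyant-density model for CsCl gradients: a genome's mean density
#' is `intercept + slope * GC + full_label_shift * label_atom_fraction`.
#' The defaults are the classical CsCl relation (1.660 g/ml intercept,
#' 0.098 g/ml per GC unit) and a 0.036 g/ml shift for fully 13C-labelled
#' DNA; 12 fractions span 1.690-1.760 g/ml, typical of SIP practice.
#'
#' @param base_density_intercept g/ml at GC = 0, unlabelled.
#' @param gc_density_slope g/ml per GC unit.
#' @param full_label_shift g/ml added at 13C atom fraction 1 (> 0).
#' @param fraction_edges strictly increasing density bounds (g/ml);
#'   `length(fraction_edges) - 1` fractions.
#' @param density_noise_sd within-taxon density spread (g/ml), the SD of
#'   the Gaussian band each taxon's DNA forms in the gradient.
#' @return a `sip_gradient_model` list.
#' @export
sip_gradient_model <- function(base_density_intercept = 1.660,
                               gc_density_slope = 0.098,
                               full_label_shift = 0.036,
                               fraction_edges = seq(1.690, 1.760, length.out = 13),
                               density_noise_sd = 0.005) {
  if (any(diff(fraction_edges) <= 0)) {
    stop("fraction_edges must be strictly increasing")
  }
  if (full_label_shift <= 0) stop("full_label_shift must be > 0")
  if (density_noise_sd <= 0) stop("density_noise_sd must be > 0")
  structure(list(base_density_intercept = base_density_intercept,
                 gc_density_slope = gc_density_slope,
                 full_label_shift = full_label_shift,
                 fraction_edges = fraction_edges,
                 density_noise_sd = density_noise_sd),
            class = "sip_gradient_model")
}

#' Mean buoyant density of a genome
#'
#' Direct evaluation of the gradient model's linear form.
#'
#' @param gc GC fraction.
#' @param label_atom_fraction 13C atom fraction.
#' @param model a [sip_gradient_model()].
#' @return density in g/ml.
#' @export
buoyant_density <- function(gc, label_atom_fraction = 0,
                            model = sip_gradient_model()) {
  model$base_density_intercept + model$gc_density_slope * gc +
    model$full_label_shift * label_atom_fraction
}

#' Simulate gradient fractionation of a community
#'
#' Each taxon's DNA mass (proportional to its relative abundance) forms a
#' Gaussian band centred at its [buoyant_density()] with SD
#' `density_noise_sd`; the band is integrated over the fraction bins
#' (outermost bins absorb the tails, so total mass is conserved). Fractions
#' are returned heaviest-first (fraction 1 = densest), the order in which
#' SIP fractions are usually collected from the bottom of the tube.
#'
#' @param genomes list of [genome_model()]s (GC and label state are used).
#' @param community named abundance vector; total DNA mass is 1.
#' @param model a [sip_gradient_model()].
#' @param seed kept for API symmetry with the other simulators; the default
#'   band-integration allocation is deterministic.
#' @return a `sip_fractions` object: list with `profile` (data.frame
#'   fraction_index, mean_density, dna_amount), `composition` (fractions x
#'   taxa matrix of relative abundances) and `taxon_mass` (fractions x taxa
#'   mass matrix).
#' @export
simulate_gradient <- function(genomes, community, model = sip_gradient_model(),
                              seed = NULL) {
  stopifnot(inherits(model, "sip_gradient_model"))
  if (!length(community) || all(community == 0)) stop("all-zero community")
  if (!all(names(community) %in% names(genomes))) {
    stop("community and genomes must share taxon ids")
  }
  if (!is.null(seed)) set.seed(seed)

  ids <- names(community)
  gc <- vapply(genomes[ids], `[[`, 0, "gc")
  lab <- vapply(genomes[ids], `[[`, 0, "label_atom_fraction")
  mu <- buoyant_density(gc, lab, model)

  edges <- sort(model$fraction_edges)
  nf <- length(edges) - 1L
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  lo[1L] <- -Inf          # outermost bins absorb the Gaussian tails
  hi[nf] <- Inf

  mass <- matrix(0, nrow = nf, ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (k in seq_along(ids)) {
    p <- pnorm(hi, mu[k], model$density_noise_sd) -
         pnorm(lo, mu[k], model$density_noise_sd)
    mass[, k] <- community[k] * p
  }

  # heaviest first
  ord <- nf:1
  mass <- mass[ord, , drop = FALSE]
  mid <- (sort(model$fraction_edges)[-1L] +
          sort(model$fraction_edges)[-(nf + 1L)]) / 2
  mid <- mid[ord]

  dna <- rowSums(mass)
  comp <- mass
  nz <- dna > 0
  comp[nz, ] <- mass[nz, , drop = FALSE] / dna[nz]

  structure(list(profile = data.frame(fraction_index = seq_len(nf),
                                      mean_density = mid, dna_amount = dna),
                 composition = comp, taxon_mass = mass,
                 model = model),
            class = "sip_fractions")
}

#' Write a gradient simulation as TSV
#'
#' Columns: fraction_index, mean_density, dna_amount, then one relative-
#' abundance column per taxon.
#'
#' @param fractions a `sip_fractions` object.
#' @param path output path.
#' @param ... passed to [write_tables()].
#' @export
write_fractions_tsv <- function(fractions, path, ...) {
  df <- cbind(fractions$profile, as.data.frame(fractions$composition))
  write_tables(df, path, ...)
}
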