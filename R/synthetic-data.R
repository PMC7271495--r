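#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Reverse-translate a protein at a target GC content
#'
#' Synonymous codons (bacterial/plastid code, translation table 11) are
#' sampled with probability proportional to
#' `gc^nGC * (1-gc)^(3-nGC)`, so the emitted coding sequence tracks the
#' host genome's GC content as closely as the amino-acid sequence allows.
#' Uses the current RNG stream.
#'
#' @param protein amino-acid string (no stops).
#' @param gc target GC fraction in (0, 1).
#' @return a nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, gc) {
  stopifnot(gc > 0, gc < 1)
  code <- Biostrings::GENETIC_CODE
  aa <- strsplit(protein, "")[[1L]]
  if (any(aa == "*")) stop("protein contains stop codons")
  codons <- character(length(aa))
  for (res in unique(aa)) {
    cand <- names(code)[code == res]
    if (!length(cand)) stop("no codon for residue: ", res)
    ngc <- vapply(strsplit(cand, ""), function(s) sum(s %in% c("G", "C")), 0L)
    w <- gc^ngc * (1 - gc)^(3 - ngc)
    idx <- which(aa == res)
    codons[idx] <- sample(cand, length(idx), replace = TRUE, prob = w)
  }
  paste(codons, collapse = "")
}

#' @keywords internal
random_background <- function(length, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Construct a genome model
#'
#' A `genome_model` carries the taxon id, genome length and GC, the planted
#' marker genes (name, protein, copies per genome), the 13C label state
#' (atom fraction of carbon that is 13C), the emitted nucleotide sequence
#' and a truth table of marker coordinates. Genomes carry exactly one recA
#' copy by default: the single-copy assumption behind recA normalization.
#'
#' @param taxon_id character scalar.
#' @param length genome length in bp (>= 10000).
#' @param gc GC fraction in \[0, 1\].
#' @param markers data.frame with columns `gene_name`, `protein_seq`,
#'   `copies_per_genome`.
#' @param label_atom_fraction 13C atom fraction in \[0, 1\].
#' @return a `genome_model` (sequence emitted lazily by
#'   [emit_genome_sequence()]).
#' @export
genome_model <- function(taxon_id, length, gc, markers, label_atom_fraction = 0) {
  stopifnot(length >= 10000, gc >= 0, gc <= 1,
            label_atom_fraction >= 0, label_atom_fraction <= 1)
  stopifnot(all(c("gene_name", "protein_seq", "copies_per_genome") %in% names(markers)))
  structure(list(taxon_id = taxon_id, length = as.integer(length), gc = gc,
                 markers = markers, label_atom_fraction = label_atom_fraction,
                 sequence = NULL, marker_truth = NULL),
            class = "genome_model")
}

#' Emit the nucleotide sequence of a genome model
#'
#' Background is i.i.d. nucleotides at the genome GC; each marker gene with
#' `copies_per_genome > 0` is reverse-translated at the genome GC and
#' inserted at a random non-overlapping position on a random strand.
#' Markers with zero copies leave no trace in the sequence. Uses the
#' current RNG stream.
#'
#' @param model a [genome_model()].
#' @return the model with `$sequence` and `$marker_truth`
#'   (gene_name, start, end, strand; 1-based inclusive) filled in.
#' @export
emit_genome_sequence <- function(model) {
  mk <- model$markers[model$markers$copies_per_genome > 0, , drop = FALSE]
  gene_nt_list <- lapply(seq_len(nrow(mk)), function(i) {
    reverse_translate(mk$protein_seq[i], model$gc)
  })
  # codon constraints cap how closely a gene can track extreme GC targets;
  # compensate in the background so the whole genome lands on target
  gene_len <- sum(nchar(unlist(c(gene_nt_list, list(character())))) *
                  mk$copies_per_genome)
  gene_gc <- sum(vapply(seq_len(nrow(mk)), function(i) {
    nchar(gsub("[^GC]", "", gene_nt_list[[i]])) * mk$copies_per_genome[i]
  }, 0))
  bg_len <- model$length - gene_len
  bg_gc <- if (bg_len > 0) {
    min(max((model$gc * model$length - gene_gc) / bg_len, 0.01), 0.99)
  } else model$gc
  seq <- random_background(model$length, bg_gc)
  truth <- list()
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(mk))) {
    gene_nt <- gene_nt_list[[i]]
    for (copy in seq_len(mk$copies_per_genome[i])) {
      glen <- nchar(gene_nt)
      if (glen > model$length) stop("marker gene longer than genome")
      for (try in 1:200) {
        start <- sample.int(model$length - glen + 1L, 1L)
        end <- start + glen - 1L
        ok <- !nrow(occupied) ||
          all(end < occupied[, 1] | start > occupied[, 2])
        if (ok) break
        if (try == 200) stop("could not place marker genes without overlap")
      }
      occupied <- rbind(occupied, c(start, end))
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") gene_nt else revcomp_chr(gene_nt)
      substr(seq, start, end) <- ins
      truth[[length(truth) + 1L]] <-
        data.frame(gene_name = mk$gene_name[i], start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
    }
  }
  model$sequence <- seq
  model$marker_truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_name = character(), start = integer(), end = integer(),
               strand = character())
  model
}

#' Generate a synthetic community with planted marker genes
#'
#' Builds `n_taxa` genomes, of which exactly
#' `round(n_taxa * carrier_fraction)` carry a single isoA-like marker gene;
#' every genome carries exactly one recA-like copy. Taxa named in
#' `labeled_taxa` are fully 13C-labelled (atom fraction 1), emulating
#' active substrate assimilation during a DNA-SIP incubation. Relative
#' abundances are drawn from a symmetric Dirichlet(1) by default.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param carrier_fraction fraction of genomes carrying isoA, in \[0, 1\].
#' @param labeled_taxa character vector of taxon ids to label (subset of
#'   the generated ids `taxon001`, `taxon002`, ...).
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param abundance_dist `"dirichlet"` (symmetric, concentration 1),
#'   `"lognormal"` (meanlog 0, sdlog 1, normalized) or `"equal"`.
#' @param genome_length genome length in bp (all taxa).
#' @param gc_range range from which per-taxon GC is drawn uniformly.
#' @param target_protein,norm_protein marker proteins to plant; default the
#'   package's synthetic IsoA-like and RecA-like references.
#' @return list with `genomes` (list of [genome_model()] with sequences
#'   emitted), `community` (named abundance vector summing to 1), and
#'   `carriers` (taxon ids carrying isoA).
#' @export
generate_community <- function(n_taxa, carrier_fraction, labeled_taxa = character(),
                               seed = 1L,
                               abundance_dist = c("dirichlet", "lognormal", "equal"),
                               genome_length = 20000L,
                               gc_range = c(0.35, 0.65),
                               target_protein = iso_reference_proteins("target_marker"),
                               norm_protein = iso_reference_proteins("normalization_marker")) {
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1)
  abundance_dist <- match.arg(abundance_dist)
  set.seed(seed)

  ids <- sprintf("taxon%03d", seq_len(n_taxa))
  if (!all(labeled_taxa %in% ids)) {
    stop("labeled_taxa must be a subset of generated taxon ids")
  }
  n_carriers <- round(n_taxa * carrier_fraction)
  carriers <- if (n_carriers > 0) sort(sample(ids, n_carriers)) else character()

  ab <- switch(abundance_dist,
    dirichlet = { x <- rexp(n_taxa); x / sum(x) },
    lognormal = { x <- rlnorm(n_taxa); x / sum(x) },
    equal = rep(1 / n_taxa, n_taxa))
  names(ab) <- ids

  gcs <- runif(n_taxa, gc_range[1], gc_range[2])
  genomes <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    markers <- data.frame(
      gene_name = c("isoA", "recA"),
      protein_seq = c(target_protein$sequence[1], norm_protein$sequence[1]),
      copies_per_genome = c(if (ids[i] %in% carriers) 1L else 0L, 1L),
      stringsAsFactors = FALSE)
    gm <- genome_model(ids[i], genome_length, gcs[i], markers,
                       label_atom_fraction = if (ids[i] %in% labeled_taxa) 1 else 0)
    genomes[[i]] <- emit_genome_sequence(gm)
  }
  names(genomes) <- ids
  list(genomes = genomes, community = ab, carriers = carriers)
}

#' Write community genomes as FASTA
#' @param genomes list of emitted [genome_model()]s.
#' @param path output FASTA path.
#' @export
write_genomes_fasta <- function(genomes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "taxon_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
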