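# Shared fixtures, built once per test run.

# A compact community for read-level tests: 10 taxa, 2 isoA carriers.
small_sim <- generate_community(10, 0.2, seed = 11, abundance_dist = "equal",
                                genome_length = 12000)

# Full carrier-percentage pipeline at configurable scale; returns the
# marker-abundance row plus the pieces for truth comparisons.
run_carrier_pipeline <- function(n_taxa, carrier_fraction, n_reads, seed,
                                 genome_length = 12000, read_length = 150,
                                 sub_error_rate = 0.005) {
  sim <- generate_community(n_taxa, carrier_fraction, seed = seed,
                            abundance_dist = "equal",
                            genome_length = genome_length)
  cfg <- read_sim_config(n_reads = n_reads, read_length = read_length,
                         sub_error_rate = sub_error_rate, seed = seed + 1)
  reads <- simulate_reads(sim$genomes, sim$community, cfg)
  params <- search_params()
  tgt <- iso_reference_proteins("target_marker")
  nrm <- iso_reference_proteins("normalization_marker")
  hits_t <- search_translated(tgt, reads, params,
                              cutoff = params$evalue_cutoff_target)
  ver <- verify_hits(hits_t, iso_reference_proteins("verification_set"), params)
  hits_n <- search_translated(nrm, reads, params,
                              cutoff = params$evalue_cutoff_norm)
  hbg <- data.frame(metagenome_id = "mg", ref_id = c(tgt$ref_id, nrm$ref_id),
                    role = c("target", "norm"),
                    n_hits = c(ver$n_unique, count_unique_hits(hits_n)))
  st <- data.frame(metagenome_id = "mg", n_reads = n_reads)
  glen <- setNames(c(tgt$length, nrm$length), c(tgt$ref_id, nrm$ref_id))
  list(ab = marker_abundance(hbg, st, glen), sim = sim, reads = reads,
       n_target = ver$n_unique, n_norm = count_unique_hits(hits_n))
}

# 13C + 12C gradient pair -> abundance table -> labeled calls.
run_sip_experiment <- function(n_taxa, labeled_taxa, seed,
                               genome_length = 12000, label_13C = TRUE) {
  sim <- generate_community(n_taxa, 0, labeled_taxa = if (label_13C)
    labeled_taxa else character(), seed = seed, abundance_dist = "equal",
    genome_length = genome_length)
  model <- sip_gradient_model()
  f13 <- simulate_gradient(sim$genomes, sim$community, model)
  g12 <- lapply(sim$genomes, function(g) { g$label_atom_fraction <- 0; g })
  f12 <- simulate_gradient(g12, sim$community, model)
  w <- suppressWarnings(identify_fractions(f13$profile, f12$profile))
  tab <- cbind(`13C_H` = window_composition(f13, w$heavy),
               `13C_L` = window_composition(f13, w$light),
               `12C_H` = window_composition(f12, w$heavy),
               `12C_L` = window_composition(f12, w$light))
  rec <- call_labeled(fold_enrichment(tab), enrichment_params())
  list(records = rec, window = w, sim = sim, f13 = f13, f12 = f12)
}

# Minimal hit-table row for white-box verification tests.
mk_hit <- function(read_id, query_id, pep, evalue = 1e-10) {
  h <- data.frame(query_id = query_id, read_id = read_id, frame = "+1",
                  raw_score = 100, evalue = evalue, pct_identity = 100,
                  aln_len = nchar(pep), frame_peptide = pep,
                  stringsAsFactors = FALSE)
  class(h) <- c("alignment_hits", "data.frame")
  h
}
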