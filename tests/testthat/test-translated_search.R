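test_that("six-frame translation follows the standard code", {
  sf <- six_frame_translate(c("ATGAAA", "TTTCAT", "ATGNAA"))
  expect_identical(sf$frames[["+1"]][1], "MK")
  expect_identical(sf$frames[["-1"]][2], "MK")   # revcomp of ATGAAA
  expect_identical(sf$frames[["+1"]][3], "MX")   # N-containing codon

  # shorter than one codon: empty frames, no error
  short <- six_frame_translate("AT")
  expect_true(all(vapply(short$frames, function(f) f == "", TRUE)))
})

test_that("six frames cover every codon of read and reverse complement once", {
  set.seed(101)
  for (L in c(3, 4, 5, 10, 17, 50)) {
    read <- rand_dna(L)
    sf <- six_frame_translate(read)
    for (fr in names(sf$frames)) {
      expect_identical(sf$frames[[fr]][1], oracle_translate_frame(read, fr),
                       info = paste("frame", fr, "len", L))
    }
    total <- sum(nchar(unlist(sf$frames)))
    expect_identical(total, as.integer(2 * sum((L - 0:2) %/% 3)))
  }
})

test_that("peptide coordinates map back to the encoding codon", {
  set.seed(102)
  read <- rand_dna(31)
  sf <- six_frame_translate(read)
  for (fr in names(sf$frames)) {
    pep <- sf$frames[[fr]][1]
    for (p in seq_len(nchar(pep))) {
      c0 <- frame_to_read_coord(fr, p, 31)
      codon <- substr(read, c0 + 1, c0 + 3)
      if (startsWith(fr, "-")) codon <- oracle_revcomp(codon)
      expect_identical(unname(Biostrings::GENETIC_CODE[codon]),
                       substr(pep, p, p))
    }
  }
})

test_that("local alignment reproduces published matrix scores", {
  r <- local_align("MA", "MA")
  expect_identical(r$raw_score, 9L)        # M->M 5 + A->A 4
  expect_identical(r$pct_identity, 100)
  p <- rand_pep(25)
  self <- local_align(p, p)
  expect_identical(self$pct_identity, 100)
  expect_identical(self$aln_len, 25L)
})

test_that("local alignment equals the exhaustive DP oracle on small instances", {
  set.seed(103)
  for (i in 1:60) {
    a <- rand_pep(sample(1:30, 1))
    b <- rand_pep(sample(1:30, 1))
    expect_identical(local_align(a, b)$raw_score,
                     as.integer(oracle_sw_score(a, b)),
                     info = paste(a, b))
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  p <- search_params()
  expect_equal(estimate_evalue(0, 100, 1000, p), p$K * 100 * 1000)
  expect_equal(estimate_evalue(50, 100, 2000, p),
               2 * estimate_evalue(50, 100, 1000, p))
  # direct evaluation, independently written out
  expect_equal(estimate_evalue(100, 1000, 1000, p),
               0.041 * 1000 * 1000 * exp(-0.267 * 100))
  expect_true(estimate_evalue(101, 10, 10, p) < estimate_evalue(100, 10, 10, p))
})

test_that("a planted in-frame marker substring is found with full identity", {
  isoA <- iso_reference_proteins("target_marker")$sequence[1]
  set.seed(104)
  frag <- substr(isoA, 100, 146)            # 47 residues
  read <- reverse_translate(frag, 0.5)      # 141 nt, frame +1
  hits <- search_translated(iso_reference_proteins("target_marker"),
                            c(r1 = read))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$frame, "+1")
  expect_identical(hits$pct_identity, 100)
  expect_lte(hits$evalue, 1e-4)

  # the same read under two ids gives two hits with identical scores
  h2 <- search_translated(iso_reference_proteins("target_marker"),
                          c(a = read, b = read))
  expect_identical(nrow(h2), 2L)
  expect_identical(h2$raw_score[1], h2$raw_score[2])

  # empty read set -> empty hit list
  h0 <- search_translated(iso_reference_proteins("target_marker"), character())
  expect_identical(nrow(h0), 0L)
})

test_that("random reads produce no hits at the default cutoff", {
  set.seed(105)
  n <- 100000
  reads <- vapply(seq_len(n), function(i) rand_dna(150), "")
  names(reads) <- sprintf("r%06d", seq_len(n))
  hits <- search_translated(iso_reference_proteins("target_marker"), reads)
  expect_identical(nrow(hits), 0L)
})

test_that("recall of error-free reads overlapping >= 45 codons is >= 0.99", {
  sim <- generate_community(5, 0.2, seed = 21, abundance_dist = "equal",
                            genome_length = 12000)
  cfg <- read_sim_config(n_reads = 20000, read_length = 150,
                         sub_error_rate = 0, seed = 22)
  rs <- simulate_reads(sim$genomes, sim$community, cfg)
  carrier <- sim$carriers[1]
  g <- sim$genomes[[carrier]]
  iso <- g$marker_truth[g$marker_truth$gene_name == "isoA", ][1, ]
  tr <- rs$truth
  ov <- pmin(iso$end, tr$start + 149) - pmax(iso$start, tr$start) + 1
  target_reads <- tr$read_id[tr$taxon_id == carrier & ov >= 137]
  expect_gt(length(target_reads), 50)
  hits <- search_translated(iso_reference_proteins("target_marker"), rs)
  recall <- mean(target_reads %in% hits$read_id)
  expect_gte(recall, 0.99)
})

test_that("verification enforces the strict 50% identity boundary", {
  params <- search_params()
  # all-positive columns, so the local alignment spans the full length:
  # 499/1000 identical columns = 49.9% -> discarded; 500/1000 retained
  ref <- strrep("I", 1000)
  pep_499 <- paste0(strrep("I", 499), strrep("V", 501))
  pep_500 <- paste0(strrep("I", 500), strrep("V", 500))
  vset <- protein_references("ref", ref, "verification_set")
  v1 <- verify_hits(mk_hit("r1", "q", pep_499), vset, params)
  expect_equal(v1$table$verify_identity, 49.9)
  expect_identical(v1$n_unique, 0L)
  v2 <- verify_hits(mk_hit("r1", "q", pep_500), vset, params)
  expect_equal(v2$table$verify_identity, 50)
  expect_identical(v2$n_unique, 1L)
})

test_that("one read hitting two queries is counted once", {
  pep <- substr(iso_reference_proteins("target_marker")$sequence[1], 1, 47)
  hits <- rbind(mk_hit("r1", "qA", pep, 1e-12), mk_hit("r1", "qB", pep, 1e-10))
  class(hits) <- c("alignment_hits", "data.frame")
  v <- verify_hits(hits, iso_reference_proteins("verification_set"))
  expect_identical(v$n_unique, 1L)
  expect_identical(v$unique_hits$query_id, "qA")   # best e-value wins
})

test_that("cross-marker reads fail verification", {
  recA_pep <- substr(iso_reference_proteins("normalization_marker")$sequence[1],
                     50, 96)
  # independent identity oracle: Biostrings local alignment
  vset <- iso_reference_proteins("verification_set")
  oracle_best <- max(vapply(vset$sequence, function(v) {
    pa <- Biostrings::pairwiseAlignment(recA_pep, v, type = "local",
                                        substitutionMatrix = blosum62,
                                        gapOpening = 11, gapExtension = 1)
    Biostrings::pid(pa, "PID1")
  }, 0))
  expect_lt(oracle_best, 50)
  v <- verify_hits(mk_hit("r1", "q", recA_pep), vset)
  expect_identical(v$n_unique, 0L)
  expect_lt(v$table$verify_identity, 50)
})

test_that("verification requires a non-empty verification set", {
  expect_error(verify_hits(mk_hit("r1", "q", "MKL"), character()),
               "verification impossible")
})
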