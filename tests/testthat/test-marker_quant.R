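two_mg_hits <- function(hits1, hits2 = 0) {
  data.frame(metagenome_id = c("mg1", "mg2"), ref_id = "isoA",
             role = "target", n_hits = c(hits1, hits2))
}

test_that("depth scaling uses the smallest metagenome's read count", {
  stats <- data.frame(metagenome_id = c("mg1", "mg2"),
                      n_reads = c(2e6, 1e6))
  sc <- normalize_hits(two_mg_hits(20, 0), stats, c(isoA = 500))
  expect_equal(sc$scaled_hits[sc$metagenome_id == "mg1"], 10)
})

test_that("length scaling weights by the shortest reference gene", {
  hits <- data.frame(metagenome_id = "mg1", ref_id = c("g1500", "g1000"),
                     role = "target", n_hits = c(30, 10))
  stats <- data.frame(metagenome_id = "mg1", n_reads = 1e6)
  sc <- normalize_hits(hits, stats, c(g1500 = 1500, g1000 = 1000))
  expect_equal(sc$scaled_hits, 30 * (1000 / 1500) + 10)
})

test_that("a single metagenome with one minimal-length gene is unscaled", {
  sc <- normalize_hits(two_mg_hits(7)[1, ],
                       data.frame(metagenome_id = "mg1", n_reads = 5e5),
                       c(isoA = 497))
  expect_equal(sc$scaled_hits, 7)
  expect_error(normalize_hits(two_mg_hits(7)[1, ],
                              data.frame(metagenome_id = "mg1", n_reads = 5e5),
                              c(other = 100)),
               "missing gene length")
})

test_that("depth and length scalings commute", {
  hits <- data.frame(metagenome_id = rep(c("a", "b"), each = 2),
                     ref_id = rep(c("x", "y"), 2), role = "target",
                     n_hits = c(12, 5, 40, 9))
  stats <- data.frame(metagenome_id = c("a", "b"), n_reads = c(3e6, 1e6))
  glen <- c(x = 400, y = 250)
  sc <- normalize_hits(hits, stats, glen)
  # manual: length first, then depth (reverse order of the implementation's
  # algebra) must give the same totals
  lf <- min(glen) / glen[hits$ref_id]
  df <- min(stats$n_reads) / stats$n_reads[match(hits$metagenome_id,
                                                 stats$metagenome_id)]
  manual <- tapply((hits$n_hits * lf) * df, hits$metagenome_id, sum)
  expect_equal(sc$scaled_hits, as.vector(manual[sc$metagenome_id]))
})

test_that("percent carriers handles zero and degenerate denominators", {
  expect_equal(percent_marker_carriers(10, 1000), 1)
  expect_equal(percent_marker_carriers(0, 1000), 0)
  expect_error(percent_marker_carriers(1, 0), "degenerate")
  expect_warning(p <- percent_marker_carriers(0, 0), "undefined")
  expect_true(is.na(p))
})

test_that("habitat comparison reports larger/smaller fold with direction", {
  res <- data.frame(metagenome_id = c("soil", "leaf"),
                    pct_carriers = c(1.0, 0.2))
  class(res) <- c("marker_abundance_result", "data.frame")
  cmp <- compare_habitats(res)
  expect_equal(cmp$fold, 5)
  expect_identical(cmp$higher, "soil")

  res$pct_carriers <- c(0.4, 0.4)
  expect_equal(compare_habitats(res)$fold, 1)

  res$pct_carriers <- c(0.4, 0)
  cmp0 <- compare_habitats(res)
  expect_false(cmp0$defined)
  expect_identical(cmp0$fold, Inf)

  res$pct_carriers <- c(0.4, NA)
  expect_warning(cmpNA <- compare_habitats(res), "skipping")
  expect_identical(nrow(cmpNA), 0L)
  expect_error(compare_habitats(res[1, ]), "at least two")
})

test_that("the pipeline estimate tracks the seeded carrier percentage", {
  r <- run_carrier_pipeline(n_taxa = 20, carrier_fraction = 0.05,
                            n_reads = 30000, seed = 31)
  truth <- 5
  tol <- 3 * truth / sqrt(r$n_target)   # binomial SDs of the hit count
  expect_lt(abs(r$ab$pct_carriers - truth), tol)
})

test_that("downsampling reads by half moves the estimate < 3 binomial SDs", {
  full <- run_carrier_pipeline(n_taxa = 20, carrier_fraction = 0.05,
                               n_reads = 30000, seed = 33)
  set.seed(34)
  keep <- sort(sample(30000, 15000))
  half_reads <- structure(list(id = full$reads$id[keep],
                               seq = full$reads$seq[keep],
                               qual = full$reads$qual[keep],
                               truth = full$reads$truth[keep, ]),
                          class = "read_set")
  params <- search_params()
  tgt <- iso_reference_proteins("target_marker")
  nrm <- iso_reference_proteins("normalization_marker")
  ver <- verify_hits(search_translated(tgt, half_reads, params),
                     iso_reference_proteins("verification_set"), params)
  hn <- search_translated(nrm, half_reads, params,
                          cutoff = params$evalue_cutoff_norm)
  hbg <- data.frame(metagenome_id = "mg", ref_id = c(tgt$ref_id, nrm$ref_id),
                    role = c("target", "norm"),
                    n_hits = c(ver$n_unique, count_unique_hits(hn)))
  ab_half <- marker_abundance(hbg,
                              data.frame(metagenome_id = "mg", n_reads = 15000),
                              setNames(c(tgt$length, nrm$length),
                                       c(tgt$ref_id, nrm$ref_id)))
  tol <- 3 * full$ab$pct_carriers / sqrt(min(ver$n_unique, full$n_target))
  expect_lt(abs(ab_half$pct_carriers - full$ab$pct_carriers), tol)
})

test_that("mean estimates recover seeded carrier fractions within 25%", {
  for (cf in c(0.01, 0.05)) {
    est <- vapply(1:6, function(s) {
      run_carrier_pipeline(n_taxa = 100, carrier_fraction = cf,
                           n_reads = 20000, seed = 400 + s)$ab$pct_carriers
    }, 0)
    truth <- 100 * cf
    expect_lt(abs(mean(est) - truth) / truth, 0.25)
  }
})
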