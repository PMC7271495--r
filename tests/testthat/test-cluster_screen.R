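cluster_refs <- iso_reference_proteins("cluster")

# annotations laid out as a contiguous gene cluster on one contig
make_annotations <- function(genes, contig = "c1", gap = 100, start = 1000,
                             strand = NULL) {
  refs <- cluster_refs[match(genes, cluster_refs$iso_gene), ]
  n <- nrow(refs)
  lens <- 3 * nchar(refs$sequence)
  starts <- start + cumsum(c(0, (lens + gap)[-n]))
  data.frame(contig_id = contig,
             gene_id = paste0(contig, "_", seq_len(n)),
             start = starts, end = starts + lens - 1,
             strand = if (is.null(strand)) rep(c("+", "-"), length.out = n)
                      else strand,
             protein = refs$sequence, stringsAsFactors = FALSE)
}

test_that("identical proteins get restrictive-tier assignments", {
  ann <- make_annotations(c("isoA", "recA"))
  asg <- assign_homologs(ann, cluster_refs)
  expect_identical(nrow(asg), 2L)
  expect_true(all(asg$tier == "restrictive"))
  expect_identical(asg$iso_gene, c("isoA", "recA"))
  expect_true(all(asg$evalue < 1e-40))
  expect_error(assign_homologs(ann, cluster_refs[0, ]), "empty")
})

test_that("a moderately diverged protein lands in the permissive tier only", {
  set.seed(51)
  base <- cluster_refs$sequence[cluster_refs$iso_gene == "isoC"]  # 120 aa
  div <- mutate_seq(base, round(0.6 * nchar(base)), AA20)
  ann <- data.frame(contig_id = "c1", gene_id = "g1", start = 1,
                    end = 3 * nchar(div), strand = "+", protein = div,
                    stringsAsFactors = FALSE)
  # oracle-derived expectation for the tier
  o_score <- oracle_sw_score(div, base)
  o_ev <- 0.041 * nchar(base) * nchar(div) * exp(-0.267 * o_score)
  expect_true(o_ev < 1e-10 && o_ev >= 1e-40)
  asg <- assign_homologs(ann, cluster_refs)
  expect_identical(asg$tier, "permissive")
  expect_identical(asg$iso_gene, "isoC")
  expect_equal(asg$evalue, o_ev, tolerance = 1e-6)
})

test_that("unrelated proteins are not assigned", {
  set.seed(52)
  ann <- data.frame(contig_id = "c1", gene_id = "g1", start = 1, end = 360,
                    strand = "+", protein = rand_pep(120),
                    stringsAsFactors = FALSE)
  expect_identical(nrow(assign_homologs(ann, cluster_refs)), 0L)
})

test_that("assignment tiers nest: restrictive implies permissive", {
  set.seed(53)
  muts <- c(0, 0.1, 0.3, 0.5, 0.7)
  base <- cluster_refs$sequence[cluster_refs$iso_gene == "isoE"]
  ann <- data.frame(contig_id = "c1",
                    gene_id = paste0("g", seq_along(muts)),
                    start = 1 + 2000 * seq_along(muts),
                    end = 2000 * seq_along(muts) + 3 * nchar(base),
                    strand = "+",
                    protein = vapply(muts, function(m) {
                      mutate_seq(base, round(m * nchar(base)), AA20)
                    }, ""), stringsAsFactors = FALSE)
  asg <- assign_homologs(ann, cluster_refs)
  expect_true(all(asg$evalue < 1e-10))
  expect_true(all(asg$evalue[asg$tier == "restrictive"] < 1e-40))
  expect_true(all(asg$evalue[asg$tier == "permissive"] >= 1e-40))
})

test_that("a full colocated cluster classifies as complete", {
  genes <- c("isoA", "isoB", "isoC", "isoD", "isoE", "isoF",
             "isoG", "isoH", "isoI", "isoJ", "aldH1")
  ann <- make_annotations(genes)
  rep <- detect_clusters(assign_homologs(ann, cluster_refs), ann)
  expect_identical(rep$classification, "complete")
  expect_identical(rep$core_count, 6L)
  expect_identical(rep$extended_count, 4L)
  expect_identical(rep$accessory, "aldH1")
})

test_that("a core-only cluster with no isoGHIJ anywhere is putative_novel", {
  ann <- make_annotations(c("isoA", "isoB", "isoC", "isoD", "isoE", "isoF"))
  rep <- detect_clusters(assign_homologs(ann, cluster_refs), ann)
  expect_identical(rep$classification, "putative_novel")
  expect_identical(rep$extended_count, 0L)
})

test_that("contigs without assignments classify as none", {
  ann <- data.frame(contig_id = "empty", gene_id = "g1", start = 1, end = 300,
                    strand = "+", protein = strrep("G", 100),
                    stringsAsFactors = FALSE)
  rep <- detect_clusters(assign_homologs(ann, cluster_refs), ann)
  expect_identical(rep$classification, "none")
})

test_that("cluster genes are reported in coordinate order, strand-agnostic", {
  ann <- make_annotations(c("isoC", "isoA", "isoB"),
                          strand = c("-", "+", "-"))
  ann <- ann[c(3, 1, 2), ]   # shuffle row order
  rep <- detect_clusters(assign_homologs(ann, cluster_refs), ann)
  expect_identical(rep$genes, "isoC,isoA,isoB")   # by start coordinate
  expect_identical(rep$classification, "partial")
})

test_that("genes separated beyond max_gap split into clusters", {
  ann <- make_annotations(c("isoA", "isoB", "isoC", "isoD", "isoE", "isoF"))
  ann$start[4:6] <- ann$start[4:6] + 50000
  ann$end[4:6] <- ann$end[4:6] + 50000
  rep <- detect_clusters(assign_homologs(ann, cluster_refs), ann,
                         max_gap = 5000)
  expect_identical(rep$n_clusters, 2L)
  expect_identical(rep$core_count, 3L)           # best cluster only
  expect_identical(rep$classification, "partial")
})

test_that("MAG gates apply strict inequalities at the printed thresholds", {
  q <- data.frame(mag_id = c("a", "b", "c", "d"),
                  completeness = c(97.6, 75.0, 80, 98.4),
                  contamination = c(2.5, 2.0, 10.0, 1.1))
  g <- mag_gate(q)
  expect_identical(g$pass, c(TRUE, FALSE, FALSE, TRUE))
  # reassembly variant of the gate
  g5 <- mag_gate(data.frame(mag_id = "e", completeness = 90,
                            contamination = 7), contamination_max = 5)
  expect_false(g5$pass)
})

test_that("self-ANI is exactly 100% with all fragments used", {
  set.seed(54)
  g <- rand_dna(5100)
  r <- compute_ani(g, g)
  expect_identical(r$ani, 100)
  expect_identical(r$n_fragments_used, 5L)
  expect_identical(r$n_fragments_total, 5L)
})

test_that("a single substitution gives fragment identity 1019/1020", {
  set.seed(55)
  g <- rand_dna(3060)
  mut <- g
  cur <- substr(mut, 500, 500)
  substr(mut, 500, 500) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  r <- compute_ani(mut, g)
  expect_equal(r$fragments$identity[1], 100 * 1019 / 1020, tolerance = 1e-9)
  expect_identical(r$fragments$identity[2], 100)
})

test_that("unrelated sequences yield an undefined ANI", {
  set.seed(56)
  a <- rand_dna(3060)
  b <- rand_dna(3060)
  expect_warning(r <- compute_ani(a, b), "no fragments retained")
  expect_true(is.na(r$ani))
  expect_identical(r$n_fragments_used, 0L)
})

test_that("ANI is strand-insensitive and near-symmetric under divergence", {
  set.seed(57)
  a <- rand_dna(10200)
  expect_identical(compute_ani(a, oracle_revcomp(a))$ani, 100)
  b <- mutate_seq(a, round(0.03 * nchar(a)), c("A", "C", "G", "T"))
  ab <- compute_ani(a, b)$ani
  ba <- compute_ani(b, a)$ani
  expect_lt(abs(ab - ba), 1)
  expect_gt(ab, 90)
})
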