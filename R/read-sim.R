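#' Read-simulation configuration
#'
#' Defaults emulate short post-QC Illumina shotgun reads (143 bp, the mean
#' length after quality filtering in typical NovaSeq soil/leaf metagenome
#' runs) with a low residual substitution error rate.
#'
#' @param n_reads number of reads to simulate (> 0).
#' @param read_length read length in bp.
#' @param sub_error_rate per-base substitution probability in \[0, 0.25).
#' @param quality_model `"constant"` (every base at `quality_q`) or
#'   `"two_state"` (each base at `quality_q` with probability 0.9, else
#'   `quality_low`).
#' @param quality_q,quality_low Phred scores used by the quality model.
#' @param seed integer seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(n_reads, read_length = 143L, sub_error_rate = 0.005,
                            quality_model = c("constant", "two_state"),
                            quality_q = 30L, quality_low = 10L, seed = 1L) {
  if (n_reads <= 0) stop("n_reads must be > 0")
  if (sub_error_rate < 0 || sub_error_rate >= 0.25) {
    stop("sub_error_rate must be in [0, 0.25)")
  }
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 sub_error_rate = sub_error_rate,
                 quality_model = match.arg(quality_model),
                 quality_q = as.integer(quality_q),
                 quality_low = as.integer(quality_low),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate shotgun reads from a community
#'
#' Reads are drawn from genomes with probability proportional to
#' `abundance * genome_length` (deeper-sequenced taxa contribute more DNA),
#' from a uniform start position and a random strand, then substitution
#' errors are applied at `sub_error_rate`. Per-read provenance (source
#' taxon, 1-based start on the forward strand, strand, error count) is
#' retained in a truth table for validation; it is not part of any emitted
#' FASTQ.
#'
#' @param genomes list of emitted [genome_model()]s.
#' @param community named abundance vector (same taxon ids as `genomes`).
#' @param cfg a [read_sim_config()].
#' @return a `read_set`: list with `id`, `seq`, `qual` (parallel character
#'   vectors) and `truth` (data.frame).
#' @export
simulate_reads <- function(genomes, community, cfg) {
  if (!length(community) || all(community == 0)) stop("empty community")
  if (!setequal(names(community), names(genomes))) {
    stop("community and genomes must share taxon ids")
  }
  stopifnot(inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)

  ids <- names(community)
  glen <- vapply(genomes[ids], `[[`, 0L, "length")
  rl <- cfg$read_length
  if (any(glen < rl)) stop("read_length exceeds a genome length")
  w <- community * glen
  n <- cfg$n_reads

  taxon_i <- sample.int(length(ids), n, replace = TRUE, prob = w)
  start <- floor(runif(n) * (glen[taxon_i] - rl + 1)) + 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)

  gseq <- vapply(genomes[ids], `[[`, "", "sequence")
  seqs <- substring(gseq[taxon_i], start, start + rl - 1L)
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- revcomp_chr(seqs[minus])

  n_err <- rbinom(n, rl, cfg$sub_error_rate)
  to_mut <- which(n_err > 0)
  nucs <- c("A", "C", "G", "T")
  for (i in to_mut) {
    pos <- sample.int(rl, n_err[i])
    s <- seqs[i]
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(nucs, cur), 1L)
    }
    seqs[i] <- s
  }

  qual <- if (cfg$quality_model == "constant") {
    rep(strrep(intToUtf8(33L + cfg$quality_q), rl), n)
  } else {
    qs <- matrix(ifelse(runif(n * rl) < 0.9, cfg$quality_q, cfg$quality_low),
                 nrow = n)
    apply(qs, 1L, function(q) intToUtf8(33L + q, multiple = FALSE))
  }

  read_id <- sprintf("read%07d", seq_len(n))
  truth <- data.frame(read_id = read_id, taxon_id = ids[taxon_i],
                      start = start, strand = strand, n_errors = n_err,
                      stringsAsFactors = FALSE)
  structure(list(id = read_id, seq = unname(seqs), qual = qual, truth = truth),
            class = "read_set")
}
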