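# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

rand_pep <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive affine-gap Smith-Waterman, plain R matrices. Gap of length L
# costs go + L * ge (same convention as the implementation under test).
oracle_sw_score <- function(a, b, go = 11, ge = 1, mat = blosum62) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Codon-by-codon translation oracle (N-containing codons -> X).
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}
oracle_translate_frame <- function(read, frame) {
  s <- if (startsWith(frame, "-")) oracle_revcomp(read) else read
  f <- as.integer(substr(frame, 2, 2))
  s <- substring(s, f)
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  starts <- 3 * (seq_len(n) - 1) + 1
  codons <- substring(s, starts, starts + 2)
  aa <- ifelse(grepl("N", codons), "X",
               unname(Biostrings::GENETIC_CODE[codons]))
  paste(aa, collapse = "")
}

# Mutate a fraction of positions (to a different symbol) in a sequence.
mutate_seq <- function(seq, n_mut, alphabet) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), n_mut)
  for (p in pos) s[p] <- sample(setdiff(alphabet, s[p]), 1)
  paste(s, collapse = "")
}
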