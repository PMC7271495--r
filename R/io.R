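#' Quality-filter parameters for amplicon reads
#'
#' Defaults follow common amplicon practice: truncate to 275 nt and
#' discard reads whose expected error exceeds 2.
#'
#' @param truncate_len truncation length in bases (> 0).
#' @param max_expected_error maximum allowed expected error (> 0).
#' @return a `quality_filter_params` list.
#' @export
quality_filter_params <- function(truncate_len = 275L, max_expected_error = 2) {
  stopifnot(truncate_len > 0, max_expected_error > 0)
  structure(list(truncate_len = as.integer(truncate_len),
                 max_expected_error = max_expected_error),
            class = "quality_filter_params")
}

#' @keywords internal
phred_from_qual <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Expected-error read filter
#'
#' Each read is truncated to `truncate_len` bases (reads shorter than that
#' are discarded), its expected error `EE = sum(10^(-Q/10))` is computed
#' over the retained bases, and reads with `EE > max_expected_error`
#' (strict: EE exactly at the threshold is retained) are discarded.
#'
#' @param reads a `read_set` (with qualities) or a list with `id`, `seq`,
#'   `qual` character vectors.
#' @param params a [quality_filter_params()].
#' @return list with `retained` (id, seq, qual, expected_error) and
#'   `discarded` (id, reason, expected_error).
#' @export
expected_error_filter <- function(reads, params = quality_filter_params()) {
  if (is.null(reads$qual)) stop("reads must carry qualities")
  stopifnot(length(reads$qual) == length(reads$seq))
  n <- length(reads$seq)
  ids <- if (!is.null(reads$id)) reads$id else sprintf("read%07d", seq_len(n))
  L <- params$truncate_len

  too_short <- nchar(reads$seq) < L
  seq_t <- substr(reads$seq, 1L, L)
  qual_t <- substr(reads$qual, 1L, L)
  ee <- vapply(phred_from_qual(qual_t), function(q) sum(10^(-q / 10)), 0)
  ee[too_short] <- NA_real_
  high_ee <- !too_short & ee > params$max_expected_error

  keep <- !too_short & !high_ee
  discard_reason <- ifelse(too_short, "shorter_than_truncate_len",
                    ifelse(high_ee, "expected_error_above_max", NA))
  list(retained = data.frame(id = ids[keep], seq = seq_t[keep],
                             qual = qual_t[keep], expected_error = ee[keep],
                             stringsAsFactors = FALSE),
       discarded = data.frame(id = ids[!keep],
                              reason = discard_reason[!keep],
                              expected_error = ee[!keep],
                              stringsAsFactors = FALSE))
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTA (wrapped lines are concatenated) is read via Biostrings; FASTQ is
#' read as strict 4-line records (Sanger/Phred+33) with validation that
#' names each malformed record and its line number.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return list with `id`, `seq` and (FASTQ only) `qual`.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    return(list(id = sub("\\s.*$", "", names(x)),
                seq = unname(as.character(x)), qual = NULL))
  }
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  i <- seq(1, length(lines), by = 4)
  hdr <- lines[i]
  seqs <- lines[i + 1]
  plus <- lines[i + 2]
  qual <- lines[i + 3]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", (bad[1] - 1) * 4 + 1, ": ",
         hdr[bad[1]])
  }
  mism <- which(nchar(seqs) != nchar(qual))
  if (length(mism)) {
    stop("quality length mismatch for record '", sub("^@", "", hdr[mism[1]]),
         "' at line ", (mism[1] - 1) * 4 + 1)
  }
  list(id = sub("\\s.*$", "", sub("^@", "", hdr)), seq = seqs, qual = qual)
}

#' Write sequences as FASTA or FASTQ
#'
#' @param x list with `id`, `seq` and, for FASTQ, `qual`; a `read_set`
#'   works directly.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param width FASTA line width.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq"), width = 70L) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fastq") {
    if (is.null(x$qual)) stop("FASTQ output requires qualities")
    writeLines(paste0("@", x$id, "\n", x$seq, "\n+\n", x$qual), con)
  } else {
    wrapped <- vapply(x$seq, function(s) {
      starts <- seq(1, nchar(s), by = width)
      paste(substring(s, starts, pmin(starts + width - 1, nchar(s))),
            collapse = "\n")
    }, "", USE.NAMES = FALSE)
    writeLines(paste0(">", x$id, "\n", wrapped), con)
  }
  invisible(path)
}

#' Write a results table as TSV with a provenance comment
#'
#' The first line is a `#`-prefixed comment recording the package version
#' and any parameters passed (e.g. the seed), followed by a header row and
#' tab-separated data.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list echoed into the comment line.
#' @return `path`, invisibly.
#' @export
write_tables <- function(df, path, params = list()) {
  meta <- c(version = as.character(packageVersion("isosip")),
            vapply(params, function(p) paste(format(p), collapse = ","), ""))
  comment <- paste0("# isosip ",
                    paste(names(meta), unname(meta), sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a TSV written by [write_tables()]
#' @param path input path.
#' @return data.frame (the provenance comment is skipped).
#' @export
read_tables <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
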