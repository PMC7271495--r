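#' Protein reference sets
#'
#' A reference set is a plain `data.frame` with columns `ref_id`,
#' `sequence`, `role` and `length` (residues). Roles follow the search
#' workflow: `target_marker` (queries for the isoA screen),
#' `verification_set` (curated proteins the candidate hits must resemble),
#' `normalization_marker` (recA queries) and `cluster` (isoprene-pathway
#' proteins used for gene-cluster screening).
#'
#' @param ref_id character vector of identifiers.
#' @param sequence character vector of amino-acid sequences
#'   (alphabet: the 20 standard residues plus `X`).
#' @param role one of `"target_marker"`, `"verification_set"`,
#'   `"normalization_marker"`, `"cluster"`; recycled.
#' @param iso_gene optional gene labels (e.g. `"isoA"`, `"recA"`) used by
#'   the cluster screen.
#' @return a `protein_references` data.frame.
#' @export
protein_references <- function(ref_id, sequence, role, iso_gene = NA_character_) {
  stopifnot(length(ref_id) == length(sequence), length(sequence) > 0)
  sequence <- toupper(sequence)
  bad <- grepl("[^ARNDCQEGHILKMFPSTWYVX*]", sequence)
  if (any(bad)) {
    stop("invalid amino-acid characters in reference(s): ",
         paste(ref_id[bad], collapse = ", "))
  }
  if (any(!nzchar(sequence))) stop("empty reference sequence")
  role <- match.arg(role, c("target_marker", "verification_set",
                            "normalization_marker", "cluster"),
                    several.ok = FALSE)
  out <- data.frame(ref_id = as.character(ref_id), sequence = sequence,
                    role = role, iso_gene = iso_gene,
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("protein_references", "data.frame")
  out
}

#' Built-in synthetic reference proteins
#'
#' Loads the package's synthetic stand-ins for the IsoA / RecA /
#' isoprene-pathway reference proteins (`inst/extdata/synthetic_iso_refs.faa`).
#' These are fixed random sequences with realistic lengths (IsoA-like 497
#' residues, RecA-like 353 residues, pathway proteins 103-500 residues) --
#' they carry no biological signal and exist so the pipeline can be
#' exercised end-to-end on synthetic communities that plant the very same
#' sequences. Substitute real curated FASTA sets via [read_protein_fasta()]
#' for analyses of real data.
#'
#' @param role which subset to return: `"target_marker"` (IsoA-like),
#'   `"verification_set"` (IsoA-like plus two diverged variants),
#'   `"normalization_marker"` (RecA-like), or `"cluster"` (the full
#'   isoABCDEFGHIJ + accessory panel).
#' @return a `protein_references` data.frame.
#' @export
iso_reference_proteins <- function(role = c("target_marker", "verification_set",
                                            "normalization_marker", "cluster")) {
  role <- match.arg(role)
  path <- system.file("extdata", "synthetic_iso_refs.faa", package = "isosip")
  refs <- read_protein_fasta(path, role = "cluster")
  pick <- switch(role,
    target_marker = "IsoA_syn",
    verification_set = c("IsoA_syn", "IsoA_syn_v95", "IsoA_syn_v85"),
    normalization_marker = "RecA_syn",
    cluster = setdiff(refs$ref_id, c("IsoA_syn_v95", "IsoA_syn_v85")))
  out <- refs[match(pick, refs$ref_id), , drop = FALSE]
  out$role <- role
  rownames(out) <- NULL
  class(out) <- c("protein_references", "data.frame")
  out
}

#' Read a protein FASTA into a reference set
#'
#' Headers of the form `>id|gene` carry the iso-gene label used by the
#' cluster screen; a plain `>id` header leaves it `NA`.
#'
#' @param path FASTA file of protein sequences.
#' @param role role assigned to every record (see [protein_references()]).
#' @return a `protein_references` data.frame.
#' @export
read_protein_fasta <- function(path, role = "target_marker") {
  aas <- Biostrings::readAAStringSet(path)
  ids <- names(aas)
  parts <- strsplit(ids, "|", fixed = TRUE)
  ref_id <- vapply(parts, `[`, "", 1L)
  iso_gene <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
  protein_references(ref_id, as.character(aas), role, iso_gene)
}
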