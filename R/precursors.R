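#' Read proneuropeptide precursor sequences from FASTA
#'
#' Headers follow `>ACCESSION SYMBOL description`. Residues are normalised
#' to uppercase. Duplicate symbols are rejected: the symbol is the key
#' peptides are mapped against.
#'
#' @param path FASTA file of precursor amino-acid sequences.
#' @return Tibble with columns `accession`, `symbol`, `sequence`.
#' @export
read_precursors <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("FASTA file is empty: %s", path))
  headers <- names(aa)
  fields <- strsplit(trimws(headers), "\\s+")
  accession <- vapply(fields, `[`, "", 1)
  symbol <- vapply(fields, function(f) if (length(f) >= 2) f[2] else f[1], "")
  dup <- symbol[duplicated(symbol)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate precursor symbol(s): %s", paste(unique(dup), collapse = ", ")))
  }
  sequence <- toupper(as.character(aa))
  if (any(!nzchar(sequence))) abort("FASTA contains an empty sequence")
  tibble::tibble(accession = accession, symbol = symbol, sequence = unname(sequence))
}

#' Write precursor records to FASTA
#'
#' @param precursors Tibble with `accession`, `symbol`, `sequence` (an
#'   optional `description` column is appended to the header).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_precursors <- function(precursors, path) {
  stopifnot(all(c("accession", "symbol", "sequence") %in% names(precursors)))
  desc <- if ("description" %in% names(precursors)) {
    precursors$description
  } else {
    rep("", nrow(precursors))
  }
  hdr <- trimws(paste(precursors$accession, precursors$symbol, desc))
  aa <- Biostrings::AAStringSet(precursors$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
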