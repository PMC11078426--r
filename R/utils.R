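#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Validate a protein sequence
#'
#' Accepts the 20 canonical residues, optionally `X` for unknown residues
#' (common in metagenomic gene calls). Ambiguity codes B/Z/J and U/O are
#' rejected so scoring stays well defined.
#'
#' @param seq Character scalar, one protein sequence.
#' @param allow_x Allow `X`? Default `TRUE`.
#' @param arg Name used in error messages.
#' @return The validated sequence, uppercased, invisibly usable.
#' @keywords internal
check_protein <- function(seq, allow_x = TRUE, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single character string.", arg))
  }
  seq <- toupper(seq)
  if (nchar(seq) == 0L) {
    abort(sprintf("`%s` is empty: protein sequences must have >= 1 residue.", arg))
  }
  ok <- AA20
  if (allow_x) ok <- c(ok, "X")
  letters_seen <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters_seen, ok)
  if (length(bad) > 0L) {
    abort(sprintf(
      "`%s` contains unsupported residue code(s): %s%s",
      arg, paste(bad, collapse = ", "),
      if (!allow_x) " (X not allowed here)" else ""
    ))
  }
  seq
}

#' Read a protein FASTA file as a named character vector
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#'   Record ids are the whitespace-delimited first token of each header.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path, width = 70L) {
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
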