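#' Optimal pairwise protein alignment
#'
#' `smith_waterman()` computes the optimal affine-gap local alignment and
#' `needleman_wunsch()` the optimal affine-gap global alignment of two
#' protein sequences, via [Biostrings::pairwiseAlignment()] with the
#' substitution matrix and penalties of a [scoring_scheme()].
#'
#' A local alignment whose best score is not positive is returned as the
#' empty alignment (score 0, zero columns). Coordinates are 1-based and
#' inclusive on the ungapped inputs; the gap character is `-`.
#'
#' @param a,b Protein sequences (single strings, 20 canonical residues
#'   plus `X`).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `pairwise_alignment`: a list with fields
#'   `mode` (`"local"` or `"global"`), `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `score`, `identities`, `columns`, and
#'   `a_span`, `b_span` (integer length-2 start/end vectors).
#' @examples
#' aln <- smith_waterman("ACDE", "ACDE")
#' aln$score        # 24 under BLOSUM62
#' percent_identity(aln)
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  pairwise_align(a, b, scheme, mode = "local")
}

#' @rdname smith_waterman
#' @export
needleman_wunsch <- function(a, b, scheme = scoring_scheme()) {
  pairwise_align(a, b, scheme, mode = "global")
}

pairwise_align <- function(a, b, scheme, mode) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  a <- check_protein(a, arg = "a")
  b <- check_protein(b, arg = "b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = mode
  )
  sc <- Biostrings::score(pa)
  if (mode == "local" && sc <= 0) {
    return(new_pairwise_alignment(
      mode, "", "", 0, a_span = integer(0), b_span = integer(0)
    ))
  }
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  a_span <- c(Biostrings::start(Biostrings::pattern(pa)),
              Biostrings::end(Biostrings::pattern(pa)))
  b_span <- c(Biostrings::start(Biostrings::subject(pa)),
              Biostrings::end(Biostrings::subject(pa)))
  new_pairwise_alignment(mode, ga, gb, sc, a_span, b_span)
}

new_pairwise_alignment <- function(mode, aligned_a, aligned_b, score,
                                   a_span, b_span) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  ids <- sum(ca == cb & ca != "-")
  structure(
    list(mode = mode, aligned_a = aligned_a, aligned_b = aligned_b,
         score = score, identities = ids, columns = length(ca),
         a_span = as.integer(a_span), b_span = as.integer(b_span)),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s, score %.0f, %d/%d identities\n",
              x$mode, x$score, x$identities, x$columns))
  if (x$columns > 0) cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identical aligned residue pairs divided by the total number of
#' alignment columns (gap columns included), times 100. This is the
#' Clustal-style identity convention; to use the shorter-sequence
#' denominator instead, divide `identities` by the ungapped length
#' yourself.
#'
#' @param aln A `pairwise_alignment`.
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$columns < 1) abort("Empty alignment: percent identity undefined.")
  100 * aln$identities / aln$columns
}

#' All-vs-all local alignment hit table
#'
#' Aligns every query against every subject with [smith_waterman()] and
#' reports score, percent identity and Karlin-Altschul E-value in a
#' BLAST-tabular-spirit tibble. The database size `n` used for E-values
#' is the total residue count of the subject set.
#'
#' @param subjects,queries Named character vectors of protein sequences.
#' @param scheme A [scoring_scheme()].
#' @return A tibble with columns `query_id`, `subject_id`, `score`,
#'   `identity_pct`, `evalue`, `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
align_hits <- function(subjects, queries, scheme = scoring_scheme()) {
  if (length(queries) == 0L) abort("Query set is empty.")
  if (is.null(names(queries)) || is.null(names(subjects)) && length(subjects)) {
    abort("`subjects` and `queries` must be named.")
  }
  n_db <- sum(nchar(subjects))
  rows <- purrr::map(names(queries), function(qid) {
    q <- queries[[qid]]
    purrr::map(names(subjects), function(sid) {
      aln <- smith_waterman(q, subjects[[sid]], scheme)
      tibble(
        query_id = qid, subject_id = sid, score = aln$score,
        identity_pct = if (aln$columns > 0) percent_identity(aln) else 0,
        evalue = evalue(aln$score, nchar(q), n_db, scheme),
        q_start = aln$a_span[1] %||% NA_integer_,
        q_end = aln$a_span[2] %||% NA_integer_,
        s_start = aln$b_span[1] %||% NA_integer_,
        s_end = aln$b_span[2] %||% NA_integer_
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
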