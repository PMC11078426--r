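#' BLOSUM62 with neutral X
#'
#' Copy of the classic BLOSUM62 substitution matrix restricted to the 20
#' canonical residues plus `X`, with every score against `X` set to 0 so
#' unknown residues from metagenomic gene calls neither reward nor punish
#' an alignment.
#'
#' @return A 21 x 21 integer matrix.
#' @export
blosum62_x0 <- function() {
  m <- get_blosum62()
  keep <- c(AA20, "X")
  m <- m[keep, keep]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Alignment scoring scheme
#'
#' Bundles a substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw local-alignment scores
#' into E-values. A gap of length L costs `gap_open + L * gap_extend`.
#' Defaults are the standard gapped protein-search constants
#' (BLOSUM62, open 11 / extend 1, lambda 0.267, K 0.041).
#'
#' @param matrix_name Name of the substitution matrix. Currently
#'   `"BLOSUM62"` (with X scored 0; see [blosum62_x0()]).
#' @param gap_open Positive gap-opening penalty.
#' @param gap_extend Positive per-residue gap-extension penalty;
#'   must not exceed `gap_open`.
#' @param lambda Karlin-Altschul lambda, in nats per score unit (> 0).
#' @param k Karlin-Altschul K (> 0).
#' @return An object of class `scoring_scheme`.
#' @examples
#' s <- scoring_scheme()
#' s$gap_open
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, k = 0.041) {
  if (!identical(matrix_name, "BLOSUM62")) {
    abort("Only the BLOSUM62 substitution matrix is shipped.")
  }
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (is.na(gap_open) || is.na(gap_extend) || gap_extend <= 0L ||
      gap_open < gap_extend) {
    abort("Gap penalties must satisfy gap_open >= gap_extend > 0.")
  }
  if (!is.numeric(lambda) || lambda <= 0) abort("`lambda` must be > 0.")
  if (!is.numeric(k) || k <= 0) abort("`k` must be > 0.")
  mat <- blosum62_x0()
  if (!isTRUE(all.equal(mat[AA20, AA20], t(mat[AA20, AA20])))) {
    abort("Substitution matrix must be symmetric over the canonical residues.")
  }
  structure(
    list(matrix_name = matrix_name, matrix = mat,
         gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, k = k),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> %s, gap open %d / extend %d, lambda %.3f, K %.3f\n",
    x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$k
  ))
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' Expected number of local alignments scoring at least `score` between a
#' query of length `m` and a database of `n` residues:
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score Raw alignment score(s), >= 0. Vectorised.
#' @param m Query length in residues (>= 1).
#' @param n Database length in residues (>= 1).
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return Numeric vector of expected hit counts.
#' @examples
#' evalue(0, 100, 100, scoring_scheme(k = 0.041))  # 410
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (any(score < 0)) abort("`score` must be >= 0.")
  if (m < 1 || n < 1) abort("`m` and `n` must be >= 1.")
  scheme$k * m * n * exp(-scheme$lambda * score)
}
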