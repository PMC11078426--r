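# Average (not monoisotopic) residue masses in Da, ExPASy convention.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Protein molecular weight
#'
#' Sum of average-isotopic residue masses plus one water, reported in
#' kDa. Ambiguous residues (X) are disallowed: an unknown residue has no
#' defined mass.
#'
#' @param seq Protein sequence over the 20 canonical residues.
#' @return Molecular weight in kDa.
#' @examples
#' molecular_weight("G")  # 0.07507 kDa
#' @export
molecular_weight <- function(seq) {
  seq <- check_protein(seq, allow_x = FALSE)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  (sum(AA_AVG_MASS[res]) + WATER_MASS) / 1000
}

#' pKa tables for isoelectric-point calculation
#'
#' `"bjellqvist"` (default) is the set used by the ExPASy Compute pI
#' tool: side chains D 4.05, E 4.45, H 5.98, C 9.0, Y 10.0, K 10.0,
#' R 12.0; C-terminus 3.55; N-terminus 7.5 with residue-specific values
#' for A/M/S/P/T/V/E/G. `"emboss"` is the EMBOSS iep set.
#'
#' @param name `"bjellqvist"` or `"emboss"`.
#' @return A list with `cterm`, `nterm` (named vector with `default`),
#'   and `side` (named vector over ionizable residues).
#' @export
pka_set <- function(name = c("bjellqvist", "emboss")) {
  name <- match.arg(name)
  switch(name,
    bjellqvist = list(
      cterm = 3.55,
      nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, G = 7.50, default = 7.50),
      side = c(D = 4.05, E = 4.45, H = 5.98, C = 9.00, Y = 10.00,
               K = 10.00, R = 12.00)
    ),
    emboss = list(
      cterm = 3.60,
      nterm = c(default = 8.60),
      side = c(D = 3.90, E = 4.10, H = 6.50, C = 8.50, Y = 10.10,
               K = 10.80, R = 12.50)
    )
  )
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y negative; H, K, R positive).
#'
#' @param seq Protein sequence.
#' @param ph pH value(s); vectorised.
#' @param pka A [pka_set()].
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(seq, ph, pka = pka_set()) {
  seq <- check_protein(seq, allow_x = FALSE)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- table(factor(res, levels = AA20))
  nterm_pk <- pka$nterm[res[1]]
  if (is.na(nterm_pk)) nterm_pk <- pka$nterm[["default"]]
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - ph))
  charge <- pos_frac(nterm_pk) + neg_frac(pka$cterm)
  for (r in c("H", "K", "R")) charge <- charge + counts[[r]] * pos_frac(pka$side[[r]])
  for (r in c("D", "E", "C", "Y")) charge <- charge + counts[[r]] * neg_frac(pka$side[[r]])
  unname(charge)
}

#' Protein isoelectric point
#'
#' pH at which the net charge crosses zero. Net charge is strictly
#' decreasing in pH, so the root is unique; it is found by bisection on
#' \[0, 14\] to better than 0.01 pH and reported to two decimals.
#'
#' @inheritParams net_charge
#' @return pI in pH units, rounded to 0.01.
#' @export
isoelectric_point <- function(seq, pka = pka_set()) {
  seq <- check_protein(seq, allow_x = FALSE)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pka) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 2)
}

#' Dipeptide thermostability index and Tm class
#'
#' `tm_index()` is a simple composition-based thermostability surrogate:
#' the mean, over all overlapping dipeptides, of a packaged coefficient
#' table. Each dipeptide coefficient is
#' `50 + 15 * (x in S) + 15 * (y in S) + 5 * (x in S & y in S)` where
#' `S = {I,V,Y,W,R,E,L}`, the residue set enriched in thermophile
#' proteomes. The index therefore depends only on dipeptide composition
#' and sits on a Celsius-like scale. `tm_class()` maps the index through
#' two thresholds into the bins `<55`, `55-65`, `>65`; when `split_at`
#' is given, per-domain bins are computed on the two subsequences.
#'
#' This is an explicit surrogate predictor, not a reimplementation of
#' any published melting-temperature tool; treat the bins as a coarse,
#' configurable stability ranking.
#'
#' @param seq Protein sequence (>= 2 residues for the index).
#' @param coefficients Dipeptide coefficient table, a named numeric
#'   vector over 400 dipeptides; default [tm_coefficients()].
#' @return `tm_index()`: numeric index. `tm_class()`: tibble with
#'   `tm_index_whole`, `tm_bin_whole` and, with `split_at`, the
#'   N-/C-part indexes and bins.
#' @export
tm_index <- function(seq, coefficients = tm_coefficients()) {
  seq <- check_protein(seq, allow_x = FALSE)
  n <- nchar(seq)
  if (n < 2) abort("`tm_index()` needs at least 2 residues.")
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  dipep <- paste0(res[-n], res[-1])
  mean(coefficients[dipep])
}

#' @rdname tm_index
#' @export
tm_coefficients <- function() {
  s <- c("I", "V", "Y", "W", "R", "E", "L")
  grid <- expand.grid(x = AA20, y = AA20, stringsAsFactors = FALSE)
  val <- 50 + 15 * (grid$x %in% s) + 15 * (grid$y %in% s) +
    5 * (grid$x %in% s & grid$y %in% s)
  stats::setNames(val, paste0(grid$x, grid$y))
}

#' @rdname tm_index
#' @param thresholds Two increasing cut points (default `c(55, 65)`).
#' @param split_at Optional 1-based position starting the C-terminal
#'   domain, for per-domain bins.
#' @export
tm_class <- function(seq, thresholds = c(55, 65), split_at = NULL,
                     coefficients = tm_coefficients()) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    abort("`thresholds` must be two increasing cut points.")
  }
  bin <- function(idx) {
    dplyr::case_when(
      idx < thresholds[1] ~ sprintf("<%g", thresholds[1]),
      idx <= thresholds[2] ~ sprintf("%g-%g", thresholds[1], thresholds[2]),
      TRUE ~ sprintf(">%g", thresholds[2])
    )
  }
  whole <- tm_index(seq, coefficients)
  out <- tibble(tm_index_whole = whole, tm_bin_whole = bin(whole))
  if (!is.null(split_at)) {
    split_at <- as.integer(split_at)
    n_part <- substr(seq, 1, split_at - 1L)
    c_part <- substr(seq, split_at, nchar(seq))
    idx_n <- tm_index(n_part, coefficients)
    idx_c <- tm_index(c_part, coefficients)
    out <- dplyr::mutate(out,
      tm_index_n = idx_n, tm_bin_n = bin(idx_n),
      tm_index_c = idx_c, tm_bin_c = bin(idx_c)
    )
  }
  out
}

#' Physical-property table for a sequence set
#'
#' Length, molecular weight (kDa), isoelectric point, and Tm-class bins
#' (whole protein and, when `split_at` is given, per domain) for each
#' sequence -- the columns of a classic protein-characterisation table.
#'
#' @param seqs Named character vector of protein sequences.
#' @param split_at Optional domain split position (per-domain Tm bins).
#' @param pka A [pka_set()].
#' @param thresholds Tm-class thresholds, see [tm_class()].
#' @return A tibble with one row per sequence: `seq_id`, `length`,
#'   `mw_kda`, `pi`, and the `tm_*` columns.
#' @export
physchem_table <- function(seqs, split_at = NULL, pka = pka_set(),
                           thresholds = c(55, 65)) {
  if (length(seqs) == 0) {
    return(tibble(seq_id = character(0), length = integer(0),
                  mw_kda = numeric(0), pi = numeric(0)))
  }
  if (is.null(names(seqs))) abort("`seqs` must be named.")
  purrr::imap_dfr(seqs, function(s, id) {
    dplyr::bind_cols(
      tibble(seq_id = id, length = nchar(s),
             mw_kda = molecular_weight(s),
             pi = isoelectric_point(s, pka)),
      tm_class(s, thresholds, split_at)
    )
  })
}
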