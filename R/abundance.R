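#' Transcripts/fragments per million (TPM)
#'
#' Length-normalized proportional abundance:
#' `tpm_i = 1e6 * (c_i / l_i) / sum_j(c_j / l_j)`. Within a sample the
#' values sum to one million, making them comparable across samples.
#'
#' @param counts Nonnegative per-gene counts (reals allowed -- coverage
#'   estimators often return fractions), not all zero.
#' @param lengths Positive per-gene lengths, same order and unit
#'   (bp or aa) for every gene.
#' @return Numeric vector of TPM values summing to 1e6.
#' @examples
#' tpm(c(10, 10), c(100, 200))  # c(666666.67, 333333.33)
#' @export
tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    abort("`counts` and `lengths` must have the same length.")
  }
  if (any(lengths <= 0)) abort("`lengths` must be positive.")
  if (any(counts < 0)) abort("`counts` must be nonnegative.")
  rates <- counts / lengths
  tot <- sum(rates)
  if (tot == 0) abort("All counts are zero: TPM is an undefined proportion.")
  1e6 * rates / tot
}

#' TPM-normalize a counts table
#'
#' Takes a tidy counts table (one row per gene, one column per sample)
#' and replaces each sample column with its TPM values. Duplicate
#' samples from one site stay separate columns, as in a genes-by-sample
#' abundance figure.
#'
#' @param counts_tbl Data frame with columns `gene_id`, `length`, then
#'   one numeric column per sample.
#' @param length_unit Declared unit of `length` (`"bp"` or `"aa"`);
#'   purely a consistency declaration -- TPM is invariant to the unit as
#'   long as it is the same for all genes.
#' @return A tibble of the same shape with TPM values.
#' @export
tpm_table <- function(counts_tbl, length_unit = c("bp", "aa")) {
  length_unit <- match.arg(length_unit)
  counts_tbl <- as_tibble(counts_tbl)
  if (!all(c("gene_id", "length") %in% names(counts_tbl))) {
    abort("`counts_tbl` needs `gene_id` and `length` columns.")
  }
  sample_cols <- setdiff(names(counts_tbl), c("gene_id", "length"))
  if (length(sample_cols) == 0) abort("No sample columns found.")
  out <- counts_tbl
  for (s in sample_cols) {
    out[[s]] <- tpm(counts_tbl[[s]], counts_tbl$length)
  }
  attr(out, "length_unit") <- length_unit
  out
}

#' KEGG-orthology presence/absence inventory
#'
#' Collapses a MAG -> gene -> KO annotation table into a logical
#' presence/absence matrix in tidy form: one row per KO, one logical
#' column per MAG, `TRUE` iff the MAG carries at least one gene with
#' that KO (duplicates are idempotent).
#'
#' @param annotations Data frame with columns `mag_id`, `gene_id`,
#'   `ko_id`. KO ids must match `K` + 5 digits (e.g. `K03575`).
#' @param ko_list Optional character vector of KO ids fixing the row
#'   set/order (absent KOs get all-`FALSE` rows); defaults to the KOs
#'   seen in `annotations`.
#' @param metadata Optional per-MAG passthrough table (e.g. completeness
#'   and contamination scores) with a `mag_id` column; attached as
#'   `attr(, "metadata")`.
#' @return A tibble: `ko_id` plus one logical column per MAG.
#' @export
ko_presence <- function(annotations, ko_list = NULL, metadata = NULL) {
  annotations <- as_tibble(annotations)
  if (!all(c("mag_id", "gene_id", "ko_id") %in% names(annotations))) {
    abort("`annotations` needs `mag_id`, `gene_id`, `ko_id` columns.")
  }
  check_ko <- function(k) {
    bad <- k[!grepl("^K[0-9]{5}$", k)]
    if (length(bad) > 0) {
      abort(sprintf("Malformed KO id(s): %s", paste(unique(bad), collapse = ", ")))
    }
  }
  check_ko(annotations$ko_id)
  if (is.null(ko_list)) {
    ko_list <- sort(unique(annotations$ko_id))
  } else {
    check_ko(ko_list)
  }
  mags <- sort(unique(annotations$mag_id))
  out <- tibble(ko_id = ko_list)
  for (m in mags) {
    seen <- unique(annotations$ko_id[annotations$mag_id == m])
    out[[m]] <- out$ko_id %in% seen
  }
  if (!is.null(metadata)) attr(out, "metadata") <- as_tibble(metadata)
  out
}
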