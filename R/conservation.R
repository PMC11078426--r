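#' Per-column conservation profile (sequence-logo data)
#'
#' Computes, for each column of a gapped alignment, the residue
#' frequencies over non-gap characters and the information content
#' `IC = log2(20) + sum(p * log2(p))` in bits -- the quantity a protein
#' sequence logo stacks. All-gap columns have undefined IC, reported as
#' `NA`.
#'
#' @param aligned Character vector (>= 2) of equal-length gapped
#'   sequences, e.g. from [reference_alignment()].
#' @return A tibble of class `muty_conservation` with columns
#'   `position`, one frequency column per canonical residue, `n_seqs`
#'   (non-gap count) and `ic_bits`.
#' @examples
#' conservation_profile(c("CS", "CT"))
#' @export
conservation_profile <- function(aligned) {
  if (length(aligned) < 2) abort("Need >= 2 aligned sequences.")
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1) abort("Aligned sequences must share one length.")
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  ncol_ <- ncol(mat)
  rows <- purrr::map(seq_len(ncol_), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    counts <- table(factor(col, levels = AA20))
    n <- sum(counts)
    freqs <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, 20)
    ic <- if (n > 0) {
      p <- freqs[freqs > 0]
      log2(20) + sum(p * log2(p))
    } else NA_real_
    c(stats::setNames(freqs, AA20), n_seqs = n, ic_bits = ic)
  })
  out <- as_tibble(do.call(rbind, rows))
  out <- dplyr::mutate(out, position = seq_len(ncol_), .before = 1)
  class(out) <- c("muty_conservation", class(out))
  out
}

#' Logo-style plot of a conservation profile
#'
#' Stacked per-column bars whose total height is the column information
#' content and whose segments are residues scaled by frequency -- the
#' data view a sequence logo renders.
#'
#' @param object A `muty_conservation` tibble.
#' @param positions Optional integer vector restricting plotted columns
#'   (e.g. motif anchor positions).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot muty_conservation
#' @export
autoplot.muty_conservation <- function(object, positions = NULL, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(AA20), names_to = "residue",
                        values_to = "freq") |>
    dplyr::filter(.data$freq > 0, !is.na(.data$ic_bits)) |>
    dplyr::mutate(height = .data$freq * .data$ic_bits)
  if (!is.null(positions)) {
    long <- dplyr::filter(long, .data$position %in% positions)
  }
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$position), y = .data$height, fill = .data$residue
  )) +
    ggplot2::geom_col(width = 0.85, colour = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = "reference position", y = "information (bits)",
                  fill = "residue") +
    ggplot2::theme_minimal()
}
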