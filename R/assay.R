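#' Rifampicin-resistance frequency of one culture
#'
#' Spontaneous Rif-resistant mutants per 1e8 viable cells:
#' `freq = (rif_cfu / rif_dilution) / (viable_cfu / viable_dilution) * 1e8`.
#' Selective and permissive plates receive the same plated volume, so
#' volumes cancel.
#'
#' @param rif_cfu Colony count on the selective (rifampicin) plate.
#' @param rif_dilution Dilution of the selective plate (1 = undiluted,
#'   0.1 = ten-fold diluted). Vectorised.
#' @param viable_cfu Colony count on the permissive plate (>= 1).
#' @param viable_dilution Dilution of the permissive plate (default 1e-7).
#' @return Mutants per 1e8 viable cells.
#' @examples
#' rifr_frequency(50, 1, 100)  # 5
#' @export
rifr_frequency <- function(rif_cfu, rif_dilution = 1, viable_cfu,
                           viable_dilution = 1e-7) {
  if (any(viable_cfu < 1)) {
    abort("`viable_cfu` must be >= 1: frequency is undefined without viable counts.")
  }
  if (any(rif_cfu < 0)) abort("`rif_cfu` must be nonnegative.")
  if (any(rif_dilution <= 0) || any(viable_dilution <= 0)) {
    abort("Dilutions must be positive.")
  }
  (rif_cfu / rif_dilution) / (viable_cfu / viable_dilution) * 1e8
}

#' Pick the countable selective plate per culture
#'
#' When a culture was plated both undiluted and at 0.1 dilution, keep
#' the plate whose colony count falls in the countable 30-300 range;
#' if neither (or both) qualifies, keep the undiluted plate.
#'
#' @param plates Data frame with columns `group_id`, `culture_id`,
#'   `rif_cfu`, `rif_dilution`, `viable_cfu` (one row per plate).
#' @return One row per culture.
#' @export
choose_plate <- function(plates) {
  plates <- as_tibble(plates)
  plates |>
    dplyr::group_by(.data$group_id, .data$culture_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 1) return(d)
      countable <- d$rif_cfu >= 30 & d$rif_cfu <= 300
      undiluted <- which.max(d$rif_dilution)
      pick <- if (sum(countable) == 1) which(countable) else undiluted
      d[pick, , drop = FALSE]
    }) |>
    dplyr::ungroup()
}

#' Per-culture frequencies for an assay table
#'
#' Applies [choose_plate()] then [rifr_frequency()] to a plate-count
#' table.
#'
#' @inheritParams choose_plate
#' @param viable_dilution Permissive-plate dilution (default 1e-7).
#' @return A tibble: `group_id`, `culture_id`, `frequency`.
#' @export
assay_frequencies <- function(plates, viable_dilution = 1e-7) {
  chosen <- choose_plate(plates)
  dplyr::transmute(
    chosen, .data$group_id, .data$culture_id,
    frequency = rifr_frequency(.data$rif_cfu, .data$rif_dilution,
                               .data$viable_cfu, viable_dilution)
  )
}

#' Median with bootstrap confidence interval
#'
#' Sample median plus a confidence interval from `n_boot` resampled
#' medians. The default percentile interval takes the empirical
#' `(1-level)/2` and `1-(1-level)/2` quantiles of the bootstrap
#' distribution; `"basic"` reflects them around the sample median. Same
#' seed, same interval, bit for bit.
#'
#' @param x Numeric vector of per-culture frequencies (>= 3 values).
#' @param n_boot Number of bootstrap resamples (>= 1000; default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @param type `"percentile"` (default) or `"basic"`.
#' @return An object of class `rifr_boot`: list with `median`, `ci_low`,
#'   `ci_high`, `n`, `n_boot`, `level`, `type`, `seed` and the vector of
#'   resampled medians `boot_medians`.
#' @export
median_ci <- function(x, n_boot = 10000L, level = 0.95, seed = 1L,
                      type = c("percentile", "basic")) {
  type <- match.arg(type)
  x <- as.numeric(x)
  if (length(x) < 3) abort("Need >= 3 values for a bootstrap median CI.")
  if (n_boot < 1000) abort("`n_boot` must be >= 1000.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  n <- length(x)
  med <- stats::median(x)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  vals <- matrix(x[idx], nrow = n_boot)
  meds <- apply(vals, 1, stats::median)
  alpha <- (1 - level) / 2
  q <- unname(stats::quantile(meds, c(alpha, 1 - alpha), type = 7))
  ci <- switch(type,
    percentile = q,
    basic = c(2 * med - q[2], 2 * med - q[1])
  )
  structure(
    list(median = med, ci_low = ci[1], ci_high = ci[2], n = n,
         n_boot = as.integer(n_boot), level = level, type = type,
         seed = as.integer(seed), boot_medians = meds),
    class = "rifr_boot"
  )
}

#' @export
print.rifr_boot <- function(x, ...) {
  cat(sprintf(
    "<rifr_boot> median %.3g, %g%% CI [%.3g, %.3g] (%s, %d resamples, n = %d)\n",
    x$median, 100 * x$level, x$ci_low, x$ci_high, x$type, x$n_boot, x$n
  ))
  invisible(x)
}

#' @method tidy rifr_boot
#' @export
tidy.rifr_boot <- function(x, ...) {
  tibble(median = x$median, ci_low = x$ci_low, ci_high = x$ci_high,
         n = x$n, level = x$level, type = x$type)
}

#' @method glance rifr_boot
#' @export
glance.rifr_boot <- function(x, ...) {
  tibble(n = x$n, n_boot = x$n_boot, level = x$level, type = x$type,
         seed = x$seed)
}

#' Group medians, CI-overlap significance and fold changes
#'
#' Summarises per-culture Rif-resistance frequencies into group medians
#' with bootstrap confidence intervals, then compares groups: two groups
#' differ significantly iff their CIs do not overlap, and each group's
#' fold change is its median divided by the reference-group median
#' (typically the positive-control MutY group).
#'
#' @param freqs Data frame with columns `group_id`, `culture_id`,
#'   `frequency` (see [assay_frequencies()]).
#' @param reference Reference group id for fold changes.
#' @param null_group Group id of the no-enzyme control for
#'   `significant_vs_null` (default `"null"`; set `NULL` to skip).
#' @param n_boot,level,seed,type Passed to [median_ci()]; each group is
#'   resampled with seed `seed + rank of group`.
#' @return A tibble of class `rifr_comparison`: `group_id`, `n`,
#'   `median`, `ci_low`, `ci_high`, `fold_change`,
#'   `significant_vs_null`, `significant_vs_reference`.
#' @export
compare_groups <- function(freqs, reference, null_group = "null",
                           n_boot = 10000L, level = 0.95, seed = 1L,
                           type = c("percentile", "basic")) {
  type <- match.arg(type)
  freqs <- as_tibble(freqs)
  if (!all(c("group_id", "frequency") %in% names(freqs))) {
    abort("`freqs` needs `group_id` and `frequency` columns.")
  }
  groups <- unique(freqs$group_id)
  if (!reference %in% groups) abort(sprintf("Reference group '%s' missing.", reference))
  summaries <- purrr::imap_dfr(
    stats::setNames(groups, groups),
    function(g, nm) {
      b <- median_ci(freqs$frequency[freqs$group_id == g],
                     n_boot = n_boot, level = level,
                     seed = seed + match(g, groups), type = type)
      tibble(group_id = g, n = b$n, median = b$median,
             ci_low = b$ci_low, ci_high = b$ci_high)
    }
  )
  ref_med <- summaries$median[summaries$group_id == reference]
  if (ref_med <= 0) abort("Reference group median must be > 0 for fold changes.")
  disjoint <- function(lo1, hi1, lo2, hi2) lo1 > hi2 | hi1 < lo2
  ref_row <- summaries[summaries$group_id == reference, ]
  out <- summaries |>
    dplyr::mutate(
      fold_change = .data$median / ref_med,
      significant_vs_reference = disjoint(.data$ci_low, .data$ci_high,
                                          ref_row$ci_low, ref_row$ci_high)
    )
  if (!is.null(null_group) && null_group %in% groups) {
    null_row <- summaries[summaries$group_id == null_group, ]
    out$significant_vs_null <- disjoint(out$ci_low, out$ci_high,
                                        null_row$ci_low, null_row$ci_high)
  } else {
    out$significant_vs_null <- NA
  }
  class(out) <- c("rifr_comparison", class(out))
  attr(out, "reference") <- reference
  attr(out, "null_group") <- null_group
  out
}

#' @method glance rifr_comparison
#' @export
glance.rifr_comparison <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    reference = attr(x, "reference"),
    n_significant_vs_null = sum(x$significant_vs_null, na.rm = TRUE),
    n_significant_vs_reference = sum(x$significant_vs_reference, na.rm = TRUE)
  )
}

#' Bar plot of group medians with bootstrap CIs
#'
#' Median Rif-resistance frequency per group with 95% CI error bars --
#' the standard presentation for a mutation-suppression assay.
#'
#' @param object A `rifr_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rifr_comparison
#' @export
autoplot.rifr_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$group_id, levels = .data$group_id), y = .data$median
  )) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = expression("Rif"^R ~ "per" ~ 10^8 ~ "viable"),
                  caption = "error bars: bootstrap 95% CI") +
    ggplot2::theme_minimal()
}
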