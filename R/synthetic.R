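#' Configuration for the synthetic candidate-pool generator
#'
#' Defaults emulate a desk-scale version of a metagenomic mining pool:
#' true homologs at 55-90% identity to the reference, decoys that break
#' exactly one chemical motif, decoys truncated before the domain split
#' (missing the whole OG-recognition part), and unrelated background
#' proteins.
#'
#' @param seed Integer seed; same seed, byte-identical outputs.
#' @param n_positive,n_decoy_motif,n_decoy_truncated,n_background
#'   Class counts (>= 0).
#' @param identity_range Target global identity range for positives and
#'   decoys, a length-2 vector inside (0.3, 1\].
#' @param anchor_sub_rate Probability that a planted positive draws an
#'   anchor residue from the allowed set instead of keeping the
#'   reference residue (emulates motif diversity).
#' @param background_length Length range for background proteins.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_positive = 5L, n_decoy_motif = 5L,
                         n_decoy_truncated = 0L, n_background = 10L,
                         identity_range = c(0.55, 0.9),
                         anchor_sub_rate = 0.3,
                         background_length = c(300L, 420L)) {
  counts <- c(n_positive, n_decoy_motif, n_decoy_truncated, n_background)
  if (any(counts < 0)) abort("Class counts must be >= 0.")
  if (length(identity_range) != 2 || identity_range[1] > identity_range[2] ||
      identity_range[1] <= 0.3 || identity_range[2] > 1) {
    abort("`identity_range` must be increasing and inside (0.3, 1].")
  }
  structure(
    list(seed = as.integer(seed), n_positive = as.integer(n_positive),
         n_decoy_motif = as.integer(n_decoy_motif),
         n_decoy_truncated = as.integer(n_decoy_truncated),
         n_background = as.integer(n_background),
         identity_range = identity_range,
         anchor_sub_rate = anchor_sub_rate,
         background_length = as.integer(background_length)),
    class = "synth_config"
  )
}

with_seed_ <- function(seed, code) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a candidate pool with known ground truth
#'
#' Positives are reference mutants: enough non-anchor positions are
#' substituted to hit a drawn target identity, and anchor residues are
#' (at a configured rate) redrawn *within* their allowed sets, so every
#' positive satisfies the full catalog by construction. Motif decoys are
#' built the same way, then one constrained anchor of one named motif is
#' substituted with a disallowed residue. Truncated decoys end before
#' the domain split. Background proteins are uniform-random sequences.
#' Substitution-only mutagenesis keeps candidates reference-length, so
#' realized global identity equals the fraction of unchanged positions.
#'
#' @param cfg A [synth_config()].
#' @param ref A [muty_reference()].
#' @return A list with `sequences` (named character vector) and `truth`
#'   (tibble: `record_id`, `class`, `broken_motif`, `target_identity`).
#' @export
generate_candidates <- function(cfg = synth_config(), ref = default_reference()) {
  stopifnot(inherits(cfg, "synth_config"), inherits(ref, "muty_reference"))
  with_seed_(cfg$seed, {
    ref_res <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
    len <- length(ref_res)
    anchors <- ref$anchors
    anchor_pos <- unique(anchors$position)
    constrained <- constrained_positions(ref)
    mutable <- setdiff(seq_len(len), anchor_pos)

    draw_homolog <- function() {
      target <- stats::runif(1, cfg$identity_range[1], cfg$identity_range[2])
      res <- ref_res
      # anchor substitutions within allowed sets
      for (i in seq_len(nrow(anchors))) {
        if (stats::runif(1) < cfg$anchor_sub_rate) {
          res[anchors$position[i]] <- sample(anchors$allowed[[i]], 1)
        }
      }
      d <- sum(res != ref_res)
      k <- max(0L, round((1 - target) * len) - d)
      if (k > length(mutable)) {
        abort("identity_range incompatible with motif constraints: too few mutable positions.")
      }
      idx <- sample(mutable, k)
      res[idx] <- vapply(res[idx], function(r) sample(setdiff(AA20, r), 1), "")
      list(res = res, target = target)
    }

    seqs <- character(0)
    truth <- list()
    add <- function(id, seq, class, broken = NA_character_, target = NA_real_) {
      seqs[[id]] <<- seq
      truth[[id]] <<- tibble(record_id = id, class = class,
                             broken_motif = broken, target_identity = target)
    }

    for (i in seq_len(cfg$n_positive)) {
      h <- draw_homolog()
      add(sprintf("pos_%03d", i), paste(h$res, collapse = ""), "positive",
          target = h$target)
    }

    motif_names <- unique(anchors$motif[anchors$position %in% constrained])
    for (i in seq_len(cfg$n_decoy_motif)) {
      h <- draw_homolog()
      m <- motif_names[(i - 1L) %% length(motif_names) + 1L]
      rows <- which(anchors$motif == m & anchors$position %in% constrained)
      row <- if (length(rows) == 1) rows else rows[sample.int(length(rows), 1)]
      pos <- anchors$position[row]
      disallowed <- setdiff(AA20, union(anchors$allowed[[row]], ref_res[pos]))
      h$res[pos] <- sample(disallowed, 1)
      add(sprintf("decoy_motif_%03d", i), paste(h$res, collapse = ""),
          "decoy_motif", broken = m, target = h$target)
    }

    for (i in seq_len(cfg$n_decoy_truncated)) {
      h <- draw_homolog()
      add(sprintf("decoy_trunc_%03d", i),
          paste(h$res[seq_len(ref$split_before - 1L)], collapse = ""),
          "decoy_truncated", target = h$target)
    }

    for (i in seq_len(cfg$n_background)) {
      n <- sample(seq(cfg$background_length[1], cfg$background_length[2]), 1)
      add(sprintf("bg_%03d", i),
          paste(sample(AA20, n, replace = TRUE), collapse = ""), "background")
    }

    list(sequences = seqs, truth = dplyr::bind_rows(truth))
  })
}

#' Generate a genes-by-samples counts table with known proportions
#'
#' Emulates per-gene metagenomic coverage across sites sampled in
#' duplicate: each site draws true gene proportions (Dirichlet via
#' normalized gammas), and each sample's counts are Poisson around
#' `length * depth * proportion`. Truth proportions are returned for
#' round-trip tests against [tpm_table()].
#'
#' @param seed Integer seed.
#' @param genes Tibble with `gene_id` and `length` (bp); defaults to the
#'   five base-excision-repair genes tracked by the pipeline.
#' @param n_sites Number of sites.
#' @param replicates Samples per site.
#' @param depth Expected reads per bp at proportion 1 (> 0).
#' @param concentration Dirichlet concentration for site proportions.
#' @return List with `counts` (tibble: `gene_id`, `length`, one column
#'   per sample `site<i>_r<j>`) and `truth` (tibble: `site`, `gene_id`,
#'   `proportion`).
#' @export
generate_counts <- function(seed = 1L,
                            genes = tibble(
                              gene_id = c("mutT", "mutM", "mutY", "xthA", "nfo"),
                              length = c(393L, 810L, 1053L, 807L, 858L)
                            ),
                            n_sites = 5L, replicates = 2L, depth = 0.5,
                            concentration = 5) {
  if (depth <= 0) abort("`depth` must be positive.")
  genes <- as_tibble(genes)
  with_seed_(seed, {
    counts <- genes
    truth <- list()
    for (s in seq_len(n_sites)) {
      g <- stats::rgamma(nrow(genes), shape = concentration)
      prop <- g / sum(g)
      truth[[s]] <- tibble(site = sprintf("site%d", s),
                           gene_id = genes$gene_id, proportion = prop)
      for (r in seq_len(replicates)) {
        counts[[sprintf("site%d_r%d", s, r)]] <-
          stats::rpois(nrow(genes), genes$length * depth * prop)
      }
    }
    list(counts = counts, truth = dplyr::bind_rows(truth))
  })
}

#' Generate mutation-suppression assay plate counts
#'
#' Per-culture true frequencies are lognormal around each group's median
#' (`freq = median * exp(sigma * Z)`), and plate counts are
#' back-computed through the dilution model with Poisson noise: a
#' permissive plate at `viable_dilution`, and selective plates both
#' undiluted and at 0.1 dilution. Group defaults emulate a
#' mutator-strain assay: a high-frequency no-enzyme control (median 101
#' per 1e8 viable), a suppressing reference enzyme (12), plus a strong,
#' an equivalent and a partial suppressor.
#'
#' @param seed Integer seed.
#' @param groups Tibble with `group_id` and `true_median` (> 0).
#' @param n_cultures Cultures per group.
#' @param sigma Lognormal dispersion of per-culture frequencies
#'   (0 = every culture at the group median, Poisson noise aside).
#' @param viable_density Viable cells per mL of washed culture.
#' @param plated_volume Plated volume in mL.
#' @param viable_dilution Permissive-plate dilution.
#' @param poisson_noise Apply Poisson counting noise (default `TRUE`;
#'   `FALSE` gives deterministic expected counts, useful for exact
#'   round-trip checks).
#' @return List with `plates` (tibble: `group_id`, `culture_id`,
#'   `rif_cfu`, `rif_dilution`, `viable_cfu`, `viable_dilution`,
#'   `plated_volume`; two selective-plate rows per culture) and `truth`
#'   (tibble: `group_id`, `culture_id`, `true_frequency`).
#' @export
generate_assay <- function(seed = 1L,
                           groups = tibble(
                             group_id = c("null", "EcMutY", "MsMutY",
                                          "RbMutY", "TtMutY"),
                             true_median = c(101, 12, 6, 12, 48)
                           ),
                           n_cultures = 24L, sigma = 0.5,
                           viable_density = 2e9, plated_volume = 0.1,
                           viable_dilution = 1e-7, poisson_noise = TRUE) {
  groups <- as_tibble(groups)
  if (any(groups$true_median <= 0)) abort("Group medians must be positive.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  with_seed_(seed, {
    plates <- list()
    truth <- list()
    count <- function(mu) if (poisson_noise) stats::rpois(1, mu) else round(mu)
    for (g in seq_len(nrow(groups))) {
      gid <- groups$group_id[g]
      for (cu in seq_len(n_cultures)) {
        freq <- groups$true_median[g] * exp(sigma * stats::rnorm(1))
        cid <- sprintf("%s_c%02d", gid, cu)
        truth[[cid]] <- tibble(group_id = gid, culture_id = cid,
                               true_frequency = freq)
        viable_cfu <- count(viable_density * viable_dilution * plated_volume)
        mutant_per_ml <- freq / 1e8 * viable_density
        for (dil in c(1, 0.1)) {
          plates[[paste(cid, dil)]] <- tibble(
            group_id = gid, culture_id = cid,
            rif_cfu = count(mutant_per_ml * plated_volume * dil),
            rif_dilution = dil,
            viable_cfu = viable_cfu,
            viable_dilution = viable_dilution,
            plated_volume = plated_volume
          )
        }
      }
    }
    list(plates = dplyr::bind_rows(plates), truth = dplyr::bind_rows(truth))
  })
}
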