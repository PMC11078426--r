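#' Mine a protein set for authenticated MutY homologs
#'
#' Runs the full funnel: (1) prefilter -- every protein is locally
#' aligned against each query and kept iff its best hit has percent
#' identity >= `min_identity` *and* E-value <= `max_evalue` (both
#' criteria must hold; the best hit per subject is the one with lowest
#' E-value, ties broken by higher score then query id); (2) each
#' survivor is mapped onto the reference by two-part global alignment;
#' (3) authenticated against the chemical-motif catalog; (4) physical
#' properties are computed for the authenticated set. Stage counts are
#' returned in a run manifest and are non-increasing along the funnel.
#'
#' @param proteins Named character vector of predicted proteins, or a
#'   FASTA path.
#' @param queries Named character vector of query sequences, or a FASTA
#'   path. Defaults to the packaged reference plus a second synthetic
#'   query.
#' @param ref A [muty_reference()].
#' @param min_identity Percent-identity cutoff (default 30).
#' @param max_evalue E-value cutoff (default 1e-5).
#' @param policy An [auth_policy()].
#' @param scheme A [scoring_scheme()].
#' @param out_dir Optional directory; when given, writes
#'   `hits.tsv`, `screen.tsv`, `physchem.tsv`, `manifest.json`.
#' @return An object of class `muty_mining`: list with `hits` (best hit
#'   per passing subject), `screen` (the [authenticate_all()] tibble),
#'   `physchem`, and `manifest` (funnel counts, thresholds, versions).
#' @export
run_mining <- function(proteins, queries = NULL, ref = default_reference(),
                       min_identity = 30, max_evalue = 1e-5,
                       policy = auth_policy(), scheme = scoring_scheme(),
                       out_dir = NULL) {
  if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins)) {
    proteins <- read_protein_fasta(proteins)
  }
  if (is.null(queries)) {
    queries <- c(
      read_protein_fasta(system.file("extdata", "muty_ref_synthetic.fasta",
                                     package = "mutyminer")),
      read_protein_fasta(system.file("extdata", "muty_query2_synthetic.fasta",
                                     package = "mutyminer"))
    )
  } else if (is.character(queries) && length(queries) == 1 && file.exists(queries)) {
    queries <- read_protein_fasta(queries)
  }
  if (length(queries) == 0) abort("Query set is empty.")

  n_input <- length(proteins)
  if (n_input > 0) {
    all_hits <- align_hits(proteins, queries, scheme)
    best <- all_hits |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::arrange(.data$evalue, dplyr::desc(.data$score), .data$query_id,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    passing <- dplyr::filter(best, .data$identity_pct >= min_identity,
                             .data$evalue <= max_evalue)
  } else {
    passing <- tibble(query_id = character(0), subject_id = character(0),
                      score = numeric(0), identity_pct = numeric(0),
                      evalue = numeric(0))
  }
  n_prefilter <- nrow(passing)

  survivors <- proteins[passing$subject_id]
  screen <- authenticate_all(survivors, ref, policy, scheme)
  authenticated <- screen$candidate_id[screen$decision == "authenticated"]
  n_auth <- length(authenticated)

  auth_seqs <- proteins[authenticated]
  canonical <- !grepl("X", auth_seqs, fixed = TRUE)
  if (any(!canonical)) {
    warn(sprintf(
      "%d authenticated sequence(s) contain X; physical properties skipped for them.",
      sum(!canonical)
    ))
  }
  phys <- physchem_table(auth_seqs[canonical])

  reject_reasons <- screen |>
    dplyr::filter(.data$decision == "rejected") |>
    dplyr::pull(.data$reasons) |>
    strsplit(";") |>
    unlist()
  manifest <- list(
    tool = "mutyminer", version = as.character(utils::packageVersion("mutyminer")),
    ref_id = ref$ref_id,
    thresholds = list(min_identity = min_identity, max_evalue = max_evalue,
                      min_c_len = policy$min_c_len,
                      allow_clusterless = policy$allow_clusterless),
    scoring = list(matrix = scheme$matrix_name, gap_open = scheme$gap_open,
                   gap_extend = scheme$gap_extend, lambda = scheme$lambda,
                   k = scheme$k),
    counts = list(input = n_input, prefilter_passed = n_prefilter,
                  authenticated = n_auth, rejected = n_prefilter - n_auth),
    rejected_by_reason = as.list(table(reject_reasons))
  )

  out <- structure(
    list(hits = passing, screen = screen, physchem = phys, manifest = manifest),
    class = "muty_mining"
  )
  if (!is.null(out_dir)) write_mining(out, out_dir)
  out
}

#' @export
print.muty_mining <- function(x, ...) {
  cn <- x$manifest$counts
  cat(sprintf(
    "<muty_mining> funnel: %d input -> %d prefilter -> %d authenticated\n",
    cn$input, cn$prefilter_passed, cn$authenticated
  ))
  invisible(x)
}

#' @method tidy muty_mining
#' @export
tidy.muty_mining <- function(x, ...) {
  as_tibble(x$screen)
}

#' @method glance muty_mining
#' @export
glance.muty_mining <- function(x, ...) {
  cn <- x$manifest$counts
  tibble(input = cn$input, prefilter_passed = cn$prefilter_passed,
         authenticated = cn$authenticated, rejected = cn$rejected)
}

#' Write mining outputs to a directory
#'
#' @param x A `muty_mining` result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_mining <- function(x, out_dir) {
  stopifnot(inherits(x, "muty_mining"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$hits, file.path(out_dir, "hits.tsv"))
  readr::write_tsv(as_tibble(x$screen), file.path(out_dir, "screen.tsv"))
  readr::write_tsv(x$physchem, file.path(out_dir, "physchem.tsv"))
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
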