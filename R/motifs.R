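#' Map a candidate onto the reference by two-part global alignment
#'
#' Sequence diversity in the C-terminal (OG-recognition) domain makes a
#' single global alignment unreliable there, so mapping is done in two
#' passes: a first global alignment locates the candidate residue
#' corresponding to the reference domain split; the candidate is cut at
#' that residue and each part is realigned globally against the matching
#' reference part; the two per-part residue maps are then merged.
#'
#' If the reference split column falls inside a candidate gap, the
#' C-part begins at the first candidate residue aligned at or after the
#' boundary. A candidate aligning entirely before the boundary gets an
#' empty C-part (`c_part_len = 0`) -- not an error; it is rejected
#' downstream.
#'
#' @param candidate Candidate protein sequence.
#' @param ref A [muty_reference()].
#' @param scheme A [scoring_scheme()].
#' @param candidate_id Optional identifier carried into reports.
#' @return An object of class `residue_map`: list with `candidate_id`,
#'   `mapping` (integer vector over reference positions; `NA` =
#'   unaligned), `n_part_len`, `c_part_len`, and `split_at` (1-based
#'   candidate position starting the C-part; `NA` if none).
#' @export
map_candidate <- function(candidate, ref, scheme = scoring_scheme(),
                          candidate_id = "candidate") {
  stopifnot(inherits(ref, "muty_reference"))
  candidate <- check_protein(candidate, arg = "candidate")
  ref_len <- nchar(ref$sequence)
  sb <- ref$split_before

  first <- needleman_wunsch(ref$sequence, candidate, scheme)
  ra <- strsplit(first$aligned_a, "", fixed = TRUE)[[1]]
  ca <- strsplit(first$aligned_b, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(ra != "-")
  cand_pos <- cumsum(ca != "-")
  # column where the reference C-part starts
  boundary_col <- match(TRUE, ref_pos == sb & ra != "-")
  split_at <- NA_integer_
  if (!is.na(boundary_col)) {
    # first candidate residue at or after the boundary column
    j <- which(ca != "-" & seq_along(ca) >= boundary_col)
    if (length(j) > 0) split_at <- cand_pos[j[1]]
  }

  n_cand <- if (is.na(split_at)) candidate else substr(candidate, 1, split_at - 1L)
  c_cand <- if (is.na(split_at)) "" else substr(candidate, split_at, nchar(candidate))

  mapping <- rep(NA_integer_, ref_len)
  add_part <- function(mapping, ref_part, cand_part, ref_off, cand_off) {
    if (nchar(cand_part) == 0 || nchar(ref_part) == 0) return(mapping)
    aln <- needleman_wunsch(ref_part, cand_part, scheme)
    pa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    pb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    rp <- cumsum(pa != "-")
    cp <- cumsum(pb != "-")
    both <- pa != "-" & pb != "-"
    mapping[rp[both] + ref_off] <- cp[both] + cand_off
    mapping
  }
  mapping <- add_part(mapping, substr(ref$sequence, 1, sb - 1L), n_cand, 0L, 0L)
  mapping <- add_part(mapping, substr(ref$sequence, sb, ref_len), c_cand,
                      sb - 1L, split_at - 1L)

  structure(
    list(candidate_id = candidate_id, mapping = mapping,
         n_part_len = nchar(n_cand), c_part_len = nchar(c_cand),
         split_at = split_at),
    class = "residue_map"
  )
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf(
    "<residue_map> %s: %d/%d reference positions mapped, N-part %d aa, C-part %d aa\n",
    x$candidate_id, sum(!is.na(x$mapping)), length(x$mapping),
    x$n_part_len, x$c_part_len
  ))
  invisible(x)
}

#' Scan a mapped candidate for the chemical-motif catalog
#'
#' Each anchored position is *satisfied* iff it is mapped and the
#' candidate residue at the mapped position belongs to the allowed set;
#' a motif is satisfied iff all its positions are. Positions that fall
#' in alignment gaps yield an `unaligned` verdict (and a warning, since
#' borderline homologs occasionally need manual inspection there).
#'
#' @param rm A `residue_map` from [map_candidate()].
#' @param candidate The candidate sequence the map was built from.
#' @param ref The [muty_reference()] used.
#' @return An object of class `motif_report`: list with `candidate_id`,
#'   `positions` (per-anchor tibble: `motif`, `ref_pos`, `cand_pos`,
#'   `observed`, `status`) and `motifs` (per-motif tibble: `motif`,
#'   `verdict` in satisfied/violated/unaligned, `detail`).
#' @export
scan_motifs <- function(rm, candidate, ref) {
  stopifnot(inherits(rm, "residue_map"), inherits(ref, "muty_reference"))
  candidate <- check_protein(candidate, arg = "candidate")
  cres <- strsplit(candidate, "", fixed = TRUE)[[1]]
  an <- ref$anchors
  cand_pos <- rm$mapping[an$position]
  observed <- ifelse(is.na(cand_pos), NA_character_, cres[cand_pos])
  status <- dplyr::case_when(
    is.na(cand_pos) ~ "unaligned",
    purrr::map2_lgl(observed, an$allowed, ~ .x %in% .y) ~ "satisfied",
    TRUE ~ "violated"
  )
  positions <- tibble(
    motif = an$motif, ref_pos = an$position, cand_pos = cand_pos,
    observed = observed, status = status
  )
  if (any(status == "unaligned")) {
    warn(sprintf(
      "%s: motif anchor(s) fall in alignment gaps (%s); treated as not satisfied.",
      rm$candidate_id,
      paste(unique(an$motif[status == "unaligned"]), collapse = ", ")
    ))
  }
  motifs <- positions |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(
      verdict = if (all(.data$status == "satisfied")) "satisfied"
                else if (any(.data$status == "violated")) "violated"
                else "unaligned",
      detail = paste0(
        .data$ref_pos[.data$status != "satisfied"], ":",
        dplyr::coalesce(.data$observed[.data$status != "satisfied"], "-"),
        collapse = ","
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(detail = ifelse(.data$verdict == "satisfied", "", .data$detail)) |>
    dplyr::arrange(match(.data$motif, unique(an$motif)))
  structure(
    list(candidate_id = rm$candidate_id, positions = positions, motifs = motifs),
    class = "motif_report"
  )
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("<motif_report> %s\n", x$candidate_id))
  print(x$motifs, n = Inf)
  invisible(x)
}

#' Authentication policy
#'
#' @param min_c_len Minimum candidate C-terminal part length, in
#'   residues (default 160).
#' @param allow_clusterless If `TRUE`, the iron-sulfur Cys4 motif is not
#'   required (some MutY lineages lack the cluster); the faithful
#'   default requires it.
#' @return A list of class `auth_policy`.
#' @export
auth_policy <- function(min_c_len = 160L, allow_clusterless = FALSE) {
  min_c_len <- as.integer(min_c_len)
  if (is.na(min_c_len) || min_c_len < 0L) abort("`min_c_len` must be >= 0.")
  structure(list(min_c_len = min_c_len,
                 allow_clusterless = isTRUE(allow_clusterless)),
            class = "auth_policy")
}

#' Authenticate a candidate from its motif report
#'
#' A candidate is authenticated iff its C-terminal part is at least
#' `policy$min_c_len` residues long *and* every required motif is
#' satisfied. Otherwise it is rejected with one reason per failure:
#' the offending motif names, plus `"c_part_short"` when the length
#' criterion fails.
#'
#' @param report A `motif_report` from [scan_motifs()].
#' @param rm The matching `residue_map`.
#' @param ref The [muty_reference()] (supplies which motifs are required).
#' @param policy An [auth_policy()].
#' @return One-row tibble: `candidate_id`, `decision`
#'   (`"authenticated"`/`"rejected"`), `reasons` (character, `;`-joined,
#'   empty when authenticated), `c_part_len`.
#' @export
authenticate <- function(report, rm, ref, policy = auth_policy()) {
  stopifnot(inherits(report, "motif_report"), inherits(rm, "residue_map"),
            inherits(ref, "muty_reference"), inherits(policy, "auth_policy"))
  if (!identical(report$candidate_id, rm$candidate_id)) {
    abort("`report` and `rm` refer to different candidates.")
  }
  required <- unique(ref$anchors$motif[ref$anchors$required])
  if (policy$allow_clusterless) required <- setdiff(required, "iron_sulfur")
  verd <- report$motifs
  failed <- verd$motif[verd$motif %in% required & verd$verdict != "satisfied"]
  reasons <- as.character(failed)
  if (rm$c_part_len < policy$min_c_len) reasons <- c(reasons, "c_part_short")
  tibble(
    candidate_id = report$candidate_id,
    decision = if (length(reasons) == 0) "authenticated" else "rejected",
    reasons = paste(reasons, collapse = ";"),
    c_part_len = rm$c_part_len
  )
}

#' Map, scan and authenticate a set of candidates
#'
#' Convenience wrapper running [map_candidate()], [scan_motifs()] and
#' [authenticate()] over a named set of sequences.
#'
#' @param candidates Named character vector of candidate sequences.
#' @param ref A [muty_reference()].
#' @param policy An [auth_policy()].
#' @param scheme A [scoring_scheme()].
#' @param keep_maps Keep the residue maps (needed for
#'   [reference_alignment()])? Default `TRUE`.
#' @return A tibble of class `muty_screen`: one row per candidate with
#'   `candidate_id`, `decision`, `reasons`, `c_part_len`, and one
#'   verdict column per motif. Residue maps, when kept, are in
#'   `attr(, "maps")`.
#' @export
authenticate_all <- function(candidates, ref, policy = auth_policy(),
                             scheme = scoring_scheme(), keep_maps = TRUE) {
  stopifnot(inherits(ref, "muty_reference"))
  if (length(candidates) == 0) {
    out <- tibble(candidate_id = character(0), decision = character(0),
                  reasons = character(0), c_part_len = integer(0))
    class(out) <- c("muty_screen", class(out))
    return(out)
  }
  if (is.null(names(candidates))) abort("`candidates` must be named.")
  maps <- list()
  rows <- purrr::map(names(candidates), function(id) {
    rm_ <- map_candidate(candidates[[id]], ref, scheme, candidate_id = id)
    rep_ <- suppressWarnings(scan_motifs(rm_, candidates[[id]], ref))
    dec <- authenticate(rep_, rm_, ref, policy)
    if (keep_maps) maps[[id]] <<- rm_
    verdicts <- stats::setNames(as.list(rep_$motifs$verdict), rep_$motifs$motif)
    dplyr::bind_cols(dec, as_tibble(verdicts))
  })
  out <- dplyr::bind_rows(rows)
  if (keep_maps) attr(out, "maps") <- maps
  class(out) <- c("muty_screen", class(out))
  out
}

#' Reference-frame gapped alignment of candidates
#'
#' Projects each candidate onto the reference coordinate system using
#' its residue map: column `i` holds the candidate residue mapped to
#' reference position `i`, or `-` where unaligned. The result is a
#' star-alignment suitable for [conservation_profile()].
#'
#' @param candidates Named character vector of sequences.
#' @param maps List of `residue_map`s named by candidate id (e.g.
#'   `attr(screen, "maps")` from [authenticate_all()]).
#' @param ref A [muty_reference()].
#' @return Character vector of equal-length gapped sequences, named by
#'   candidate id.
#' @export
reference_alignment <- function(candidates, maps, ref) {
  stopifnot(inherits(ref, "muty_reference"))
  ref_len <- nchar(ref$sequence)
  out <- purrr::imap_chr(maps, function(rm_, id) {
    cres <- strsplit(candidates[[id]], "", fixed = TRUE)[[1]]
    col <- rep("-", ref_len)
    ok <- !is.na(rm_$mapping)
    col[ok] <- cres[rm_$mapping[ok]]
    paste(col, collapse = "")
  })
  out
}
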