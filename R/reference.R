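#' Reference annotation for motif-anchored authentication
#'
#' A `muty_reference` couples a reference MutY protein sequence with
#' (i) the 1-based position where its C-terminal (OG-recognition) part
#' begins -- the domain split used for two-part alignment -- and (ii) a
#' catalog of chemical-motif anchors: reference positions together with
#' the residue sets tolerated at each. Positions use the reference's own
#' numbering, 1-based and inclusive.
#'
#' @param ref_id Identifier of the reference protein.
#' @param sequence Reference protein sequence.
#' @param split_before 1-based position starting the C-terminal part
#'   (the N-part ends at `split_before - 1`).
#' @param anchors A data frame with columns `motif`, `position`,
#'   `allowed` (list-column of character vectors; the wildcard `"*"`
#'   means any canonical residue), `role`, `required`.
#' @return An object of class `muty_reference`.
#' @seealso [default_reference()], [read_motif_catalog()]
#' @export
muty_reference <- function(ref_id, sequence, split_before, anchors) {
  sequence <- check_protein(sequence, allow_x = FALSE, arg = "sequence")
  len <- nchar(sequence)
  split_before <- as.integer(split_before)
  if (is.na(split_before) || split_before <= 1L || split_before > len) {
    abort("`split_before` must satisfy 1 < split_before <= length(sequence).")
  }
  anchors <- as_tibble(anchors)
  needed <- c("motif", "position", "allowed", "role", "required")
  if (!all(needed %in% names(anchors))) {
    abort(paste("`anchors` must have columns:", paste(needed, collapse = ", ")))
  }
  anchors$position <- as.integer(anchors$position)
  if (any(anchors$position < 1L | anchors$position > len)) {
    abort("Anchor positions must lie within the reference sequence.")
  }
  if (anyDuplicated(anchors[, c("motif", "position")])) {
    abort("Anchor positions must be unique within each motif.")
  }
  anchors$allowed <- purrr::map(anchors$allowed, function(a) {
    a <- toupper(a)
    if (identical(a, "*")) return(AA20)
    if (length(a) == 0 || !all(a %in% AA20)) {
      abort("Allowed sets must be nonempty subsets of the 20 canonical residues.")
    }
    a
  })
  obj <- structure(
    list(ref_id = ref_id, sequence = sequence,
         split_before = split_before, anchors = anchors),
    class = "muty_reference"
  )
  # self-consistency: the reference must satisfy its own catalog
  ref_res <- strsplit(sequence, "", fixed = TRUE)[[1]][anchors$position]
  ok <- purrr::map2_lgl(ref_res, anchors$allowed, ~ .x %in% .y)
  if (!all(ok)) {
    bad <- anchors$motif[!ok]
    abort(sprintf(
      "Catalog inconsistent with reference: residue(s) at motif(s) %s not in allowed set.",
      paste(unique(bad), collapse = ", ")
    ))
  }
  obj
}

#' @export
print.muty_reference <- function(x, ...) {
  cat(sprintf(
    "<muty_reference> %s: %d residues, C-part starts at %d, %d motifs / %d anchors\n",
    x$ref_id, nchar(x$sequence), x$split_before,
    length(unique(x$anchors$motif)), nrow(x$anchors)
  ))
  invisible(x)
}

#' The packaged default reference annotation
#'
#' Loads the motif catalog shipped with the package. The anchor
#' coordinates follow the Geobacillus-type MutY numbering used in the
#' structural literature (catalytic Glu43; wedge Tyr88; transition-state
#' Tyr126; catalytic Asp144; small linker 145; catalytic Asn146; C-part
#' starting at Val147; iron-sulfur Cys4 cluster; L-xxx-P at 265-269; the
#' H-x-FSH OG-recognition window at 305-309). The backing sequence is a
#' synthetic stand-in (see `inst/extdata/muty_ref_synthetic.fasta`) with
#' the anchor residues planted at those coordinates, so that the whole
#' pipeline runs offline; swap in a real reference by editing the JSON
#' catalog and FASTA.
#'
#' @return A [muty_reference()].
#' @export
default_reference <- function() {
  read_motif_catalog(
    system.file("extdata", "muty_motif_catalog.json", package = "mutyminer")
  )
}

#' Read / write a motif catalog
#'
#' The catalog is a JSON document with fields `ref_id`, `fasta` (path to
#' the reference FASTA, relative to the JSON file) or `sequence`,
#' `split_before`, and `anchors`: an array of
#' `{motif, positions, allowed, role, required}` where `allowed` is a
#' per-position array of residue strings (`"*"` = any residue).
#'
#' @param path Path to the catalog JSON.
#' @return A [muty_reference()].
#' @export
read_motif_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("Catalog not found: %s", path))
  doc <- jsonlite::read_json(path)
  if (!is.null(doc$sequence)) {
    seq <- doc$sequence
  } else if (!is.null(doc$fasta)) {
    fa <- file.path(dirname(path), doc$fasta)
    seqs <- read_protein_fasta(fa)
    seq <- unname(seqs[[1]])
  } else {
    abort("Catalog must supply `sequence` or `fasta`.")
  }
  anchors <- purrr::map_dfr(doc$anchors, function(a) {
    tibble(
      motif = a$motif,
      position = purrr::list_c(a$positions),
      allowed = purrr::map(a$allowed, ~ unlist(.x)),
      role = a$role,
      required = isTRUE(a$required)
    )
  })
  muty_reference(doc$ref_id, seq, doc$split_before, anchors)
}

#' @rdname read_motif_catalog
#' @param ref A [muty_reference()].
#' @param fasta Optional FASTA filename to write the sequence to
#'   (relative to `path`); if `NULL` the sequence is embedded in the JSON.
#' @export
write_motif_catalog <- function(ref, path, fasta = NULL) {
  stopifnot(inherits(ref, "muty_reference"))
  by_motif <- split(ref$anchors, factor(ref$anchors$motif,
                                        levels = unique(ref$anchors$motif)))
  anchors <- purrr::map(by_motif, function(d) {
    list(
      motif = d$motif[1],
      positions = as.list(d$position),
      allowed = purrr::map(d$allowed, function(a) {
        if (setequal(a, AA20)) list("*") else as.list(a)
      }),
      role = d$role[1],
      required = d$required[1]
    )
  })
  doc <- list(ref_id = ref$ref_id, split_before = ref$split_before,
              anchors = unname(anchors))
  if (is.null(fasta)) {
    doc$sequence <- ref$sequence
  } else {
    write_protein_fasta(stats::setNames(ref$sequence, ref$ref_id),
                        file.path(dirname(path), fasta))
    doc$fasta <- fasta
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Anchor positions constrained by the catalog
#'
#' Positions whose allowed set is a strict subset of the alphabet
#' (i.e. excluding `x` wildcards inside patterns).
#' @param ref A [muty_reference()].
#' @return Integer vector of reference positions.
#' @keywords internal
constrained_positions <- function(ref) {
  sel <- !purrr::map_lgl(ref$anchors$allowed, ~ setequal(.x, AA20))
  sort(unique(ref$anchors$position[sel]))
}
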