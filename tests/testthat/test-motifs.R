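# helpers to mutate a sequence at given 1-based positions
sub_at <- function(seq, pos, res) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos] <- res
  paste(v, collapse = "")
}
insert_after <- function(seq, pos, res) {
  paste0(substr(seq, 1, pos), res, substr(seq, pos + 1, nchar(seq)))
}

ref <- default_reference()

test_that("the packaged catalog is well formed and self-consistent", {
  expect_s3_class(ref, "muty_reference")
  expect_equal(ref$split_before, 147)
  expect_equal(nchar(ref$sequence), 372)
  expect_setequal(
    unique(ref$anchors$motif),
    c("iron_sulfur", "catalytic_glu", "wedge_gln", "wedge_tyr", "ts_tyr",
      "catalytic_asp", "small_linker", "catalytic_asn", "og_recognition",
      "l_xxx_p")
  )
  # constructing it re-runs the self-consistency check
  expect_silent(muty_reference(ref$ref_id, ref$sequence, ref$split_before,
                               ref$anchors))
  # a catalog whose reference violates its own allowed sets is refused
  broken <- sub_at(ref$sequence, 43, "A")
  expect_error(
    muty_reference(ref$ref_id, broken, ref$split_before, ref$anchors),
    "catalytic_glu"
  )
})

test_that("self-mapping is the identity and scans all-satisfied", {
  rm_ <- map_candidate(ref$sequence, ref, candidate_id = "self")
  expect_equal(rm_$mapping, seq_len(372))
  expect_equal(rm_$c_part_len, 372 - 147 + 1)
  expect_equal(rm_$n_part_len, 146)
  rep_ <- scan_motifs(rm_, ref$sequence, ref)
  expect_true(all(rep_$motifs$verdict == "satisfied"))
  dec <- authenticate(rep_, rm_, ref)
  expect_equal(dec$decision, "authenticated")
  expect_equal(dec$reasons, "")
})

test_that("an insertion shifts downstream mapped positions by one", {
  cand <- insert_after(ref$sequence, 10, "W")
  rm_ <- map_candidate(cand, ref)
  expect_equal(rm_$mapping[1:10], 1:10)
  expect_equal(rm_$mapping[11:372], 12:373)
})

test_that("truncation before the split leaves the C-part empty", {
  cand <- substr(ref$sequence, 1, ref$split_before - 1)
  rm_ <- map_candidate(cand, ref)
  expect_equal(rm_$c_part_len, 0)
  expect_true(all(is.na(rm_$mapping[147:372])))
  rep_ <- suppressWarnings(scan_motifs(rm_, cand, ref))
  dec <- authenticate(rep_, rm_, ref)
  expect_equal(dec$decision, "rejected")
  expect_true(grepl("c_part_short", dec$reasons))
  expect_true(grepl("og_recognition", dec$reasons))
})

test_that("motif verdicts react to targeted substitutions", {
  # one iron-sulfur Cys -> Ala breaks only that motif
  cand <- sub_at(ref$sequence, 199, "A")
  rm_ <- map_candidate(cand, ref)
  rep_ <- scan_motifs(rm_, cand, ref)
  expect_equal(rep_$motifs$verdict[rep_$motifs$motif == "iron_sulfur"],
               "violated")
  expect_true(all(rep_$motifs$verdict[rep_$motifs$motif != "iron_sulfur"] ==
                    "satisfied"))

  # FSH -> FTH stays satisfied (Ser/Thr both recognize the oxidized base)
  cand2 <- sub_at(ref$sequence, 308, "T")
  rep2 <- scan_motifs(map_candidate(cand2, ref), cand2, ref)
  expect_equal(rep2$motifs$verdict[rep2$motifs$motif == "og_recognition"],
               "satisfied")
})

test_that("recognition- and catalysis-style variants are rejected with the right reasons", {
  # F(S/T)H -> AAA
  recog <- sub_at(ref$sequence, c(307, 308, 309), "A")
  rm_ <- map_candidate(recog, ref)
  dec <- authenticate(scan_motifs(rm_, recog, ref), rm_, ref)
  expect_equal(dec$decision, "rejected")
  expect_equal(dec$reasons, "og_recognition")

  # catalytic Asp -> Asn and Glu -> Gln
  catal <- sub_at(sub_at(ref$sequence, 144, "N"), 43, "Q")
  rm2 <- map_candidate(catal, ref)
  dec2 <- authenticate(scan_motifs(rm2, catal, ref), rm2, ref)
  expect_equal(dec2$decision, "rejected")
  expect_setequal(strsplit(dec2$reasons, ";")[[1]],
                  c("catalytic_asp", "catalytic_glu"))
})

test_that("authentication policy switches behave", {
  clusterless <- sub_at(ref$sequence, c(192, 199, 202, 208), "A")
  rm_ <- map_candidate(clusterless, ref)
  rep_ <- scan_motifs(rm_, clusterless, ref)
  strict <- authenticate(rep_, rm_, ref, auth_policy())
  lax <- authenticate(rep_, rm_, ref, auth_policy(allow_clusterless = TRUE))
  expect_equal(strict$decision, "rejected")
  expect_equal(strict$reasons, "iron_sulfur")
  expect_equal(lax$decision, "authenticated")

  # raising min_c_len can only remove authentications (monotone policy)
  harsh <- authenticate(rep_, rm_, ref, auth_policy(min_c_len = 300,
                                                    allow_clusterless = TRUE))
  expect_equal(harsh$decision, "rejected")
  expect_equal(harsh$reasons, "c_part_short")
})

test_that("authenticate_all screens a set and keeps residue maps", {
  cands <- c(good = ref$sequence, bad = sub_at(ref$sequence, 146, "D"))
  screen <- authenticate_all(cands, ref)
  expect_s3_class(screen, "muty_screen")
  expect_equal(screen$decision, c("authenticated", "rejected"))
  expect_equal(screen$reasons[2], "catalytic_asn")
  expect_named(attr(screen, "maps"), c("good", "bad"))
  expect_equal(nrow(authenticate_all(character(0), ref)), 0)
})

test_that("reference-frame alignment projects candidates onto reference columns", {
  cands <- c(self = ref$sequence, ins = insert_after(ref$sequence, 10, "W"))
  screen <- authenticate_all(cands, ref)
  aligned <- reference_alignment(cands, attr(screen, "maps"), ref)
  expect_equal(unique(nchar(aligned)), 372)
  expect_equal(aligned[["self"]], ref$sequence)
  # the insertion candidate reproduces the reference in reference frame
  expect_equal(aligned[["ins"]], ref$sequence)
})
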