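# Independent oracles used to cross-check the implementation.
# Deliberately written against different formulations than the package
# (plain-R dynamic programming, grid scans, exhaustive enumeration).

AA20_TEST <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Affine-gap alignment score by three-state dynamic programming in plain R.
# A gap of length L costs open + L * ext. mode: "global" or "local".
oracle_align_score <- function(a, b, mat, open = 11, ext = 1,
                               mode = c("global", "local")) {
  mode <- match.arg(mode)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # last column is a residue pair
  X <- matrix(NEG, n + 1, m + 1)  # last column consumes a (gap in b)
  Y <- matrix(NEG, n + 1, m + 1)  # last column consumes b (gap in a)
  M[1, 1] <- 0
  if (mode == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- if (mode == "local") s + max(0, prev) else s + prev
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
      if (mode == "local") best_local <- max(best_local, M[i + 1, j + 1])
    }
  }
  if (mode == "local") best_local
  else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every global alignment (as gapped string
# pairs) for tiny sequences; scores each with affine gap costs. Used to
# validate the DP oracle itself.
oracle_enumerate_global <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  score_alignment <- function(ga, gb) {
    s <- 0
    state <- "M"
    for (k in seq_along(ga)) {
      if (ga[k] != "-" && gb[k] != "-") {
        s <- s + mat[ga[k], gb[k]]; state <- "M"
      } else if (gb[k] == "-") {
        s <- s - ext - if (state == "X") 0 else open; state <- "X"
      } else {
        s <- s - ext - if (state == "Y") 0 else open; state <- "Y"
      }
    }
    s
  }
  best <- -Inf
  recurse <- function(i, j, ga, gb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_alignment(ga, gb))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1, j + 1, c(ga, av[i]), c(gb, bv[j]))
    }
    if (i <= length(av)) recurse(i + 1, j, c(ga, av[i]), c(gb, "-"))
    if (j <= length(bv)) recurse(i, j + 1, c(ga, "-"), c(gb, bv[j]))
  }
  recurse(1, 1, character(0), character(0))
  best
}

# pI oracle: scan a 0.001-pH grid for the zero crossing of net charge.
oracle_pi_grid <- function(seq, pka = mutyminer::pka_set()) {
  ph <- seq(0, 14, by = 0.001)
  ch <- mutyminer::net_charge(seq, ph, pka)
  ph[which.min(abs(ch))]
}

random_peptide <- function(len, letters = AA20_TEST) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
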