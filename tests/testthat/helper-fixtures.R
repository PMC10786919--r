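# Shared fixtures and independent mini-oracles used across tests.

# Independent single-site oracle: bisection on the 1:1 mass balance
# Pt = p + Lt * p / (Kd + p), probe fraction bound = p / (Kd + p).
bisectDirectFb <- function(Kd, Lt, Pt, tol = 1e-15) {
  g <- function(p) p + Lt * p / (Kd + p) - Pt
  lo <- 0; hi <- Pt
  while (hi - lo > tol * max(Pt, 1)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  p <- (lo + hi) / 2
  p / (Kd + p)
}

# Library-template sequence with a chosen tail (bracketed archetype tokens)
templateSeq <- function(tail) {
  paste0("Ac-[KN3][bA]LTF[R8]EYWAQ[Cba][S5]", tail, "-NH2")
}

# A synthetic library with an exactly known set of filter violations:
# `nBad` of `n` records violate at least one of the selection rules.
plantedFilterTable <- function(n = 100, nBad = 37, seed = 11) {
  set.seed(seed)
  kd <- rep(5, n); cell <- rep(0.5, n)
  cs <- rep(">50", n); ldh <- rep(">50", n)
  bad <- sample.int(n, nBad)
  kind <- sample(1:3, nBad, replace = TRUE)
  kd[bad[kind == 1]] <- 20000           # Kd 20 uM: fails the 10 uM cutoff
  cs[bad[kind == 2]] <- "2"             # counterscreen within 10x of cell
  ldh[bad[kind == 3]] <- "1.5"          # LDH within 10x of cell
  LibraryTable(data.frame(
    name = sprintf("P%03d", seq_len(n)),
    kd_nM = as.character(kd),
    cell_ec50_0pct_uM = as.character(cell),
    counterscreen_ec50_uM = cs,
    ldh_ec50_uM = ldh,
    stringsAsFactors = FALSE))
}
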