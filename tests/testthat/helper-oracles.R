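# Independent oracles used by the dual-route tests. These are deliberately
# naive quadratic implementations, kept separate from the package's engines.

# Score-only affine-gap local alignment (gap of length k costs go + k*ge).
sw_oracle_score <- function(q, t, mat, go, ge) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - (go + ge), E[i + 1, j] - ge)
    F[i + 1, j + 1] <- max(H[i, j + 1] - (go + ge), F[i, j + 1] - ge)
    H[i + 1, j + 1] <- max(0, H[i, j] + mat[qs[i], ts[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# Score-only global alignment with the same gap convention.
nw_oracle_score <- function(q, t, mat, go, ge) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 1:m) { E[1, j + 1] <- -(go + j * ge); H[1, j + 1] <- E[1, j + 1] }
  for (i in 1:n) { F[i + 1, 1] <- -(go + i * ge); H[i + 1, 1] <- F[i + 1, 1] }
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - (go + ge), E[i + 1, j] - ge)
    F[i + 1, j + 1] <- max(H[i, j + 1] - (go + ge), F[i, j + 1] - ge)
    H[i + 1, j + 1] <- max(H[i, j] + mat[qs[i], ts[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
  }
  H[n + 1, m + 1]
}

# Exhaustive longest-duplicated-k oracle for TSD extraction.
tsd_oracle <- function(seq, start0, end0, k_min = 3, k_max = 6) {
  found <- NULL
  for (k in k_min:k_max) {
    left <- substr(seq, start0 - k + 1, start0)
    right <- substr(seq, end0 + 1, end0 + k)
    if (left == right) found <- k # keep the largest matching k
  }
  found
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# A random additive distance matrix: random topology + positive edge lengths.
random_additive_dm <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 3)
  list(tree = tr, dm = stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
}
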