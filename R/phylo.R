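# Protein multiple alignment (simple progressive scheme), corrected
# distances (p / Poisson / gamma, pairwise or complete deletion), NJ and
# minimum-evolution trees, bootstrap supports, and Newick output.

#' Simple progressive multiple alignment
#'
#' Guide tree from neighbor-joining on p-distances of all pairwise global
#' alignments; profiles are then merged by global profile-profile dynamic
#' programming (linear gap penalty) following the guide tree. Deterministic.
#'
#' @param seqs named character vector (>= 2 sequences), protein or DNA.
#' @param type `"protein"` (BLOSUM62) or `"dna"` (match +2 / mismatch -1).
#' @param gap linear gap penalty magnitude per column.
#' @return named character vector of aligned sequences (equal length), in
#'   the input order.
#' @export
progressive_align <- function(seqs, type = c("protein", "dna"), gap = NULL) {
  type <- match.arg(type)
  n <- length(seqs)
  if (n < 2) abort("need at least 2 sequences to align")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (anyDuplicated(names(seqs))) abort("sequence names must be unique")
  sm <- if (type == "protein") blosum62() else dna_submat(2, -1)
  if (is.null(gap)) gap <- if (type == "protein") 8 else 4
  alphabet <- paste(rownames(sm), collapse = "")
  if (n == 2) {
    r <- cpp_align(seqs[[1]], seqs[[2]], alphabet, sm, 0, gap, FALSE)
    return(setNames(c(r$q_aln, r$t_aln), names(seqs)))
  }
  # guide distances: p-distance on pairwise global alignments
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    r <- cpp_align(seqs[[i]], seqs[[j]], alphabet, sm, 0, gap, FALSE)
    p <- if (r$n_cols > 0) 1 - r$n_match / r$n_cols else 1
    d[i, j] <- d[j, i] <- p
  }
  guide <- ape::nj(stats::as.dist(d))
  # postorder profile merging
  profiles <- as.list(seqs)
  names(profiles) <- names(seqs)
  merge_clade <- function(node) {
    # returns a named character vector (profile) for the clade below `node`
    if (node <= n) return(setNames(seqs[guide$tip.label[node]], guide$tip.label[node]))
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    profs <- lapply(kids, merge_clade)
    acc <- profs[[1]]
    for (k in seq.int(2, length(profs))) {
      r <- cpp_profile_align(unname(acc), unname(profs[[k]]), alphabet, sm, gap)
      acc <- setNames(r$alignment, c(names(acc), names(profs[[k]])))
    }
    acc
  }
  root <- n + 1L
  aligned <- merge_clade(root)
  aligned[names(seqs)]
}

#' Corrected pairwise distances from a protein alignment
#'
#' p-distance = mismatches / compared columns; `pairwise` deletion drops
#' columns gapped in either member of a pair, `complete` deletion drops
#' columns gapped in any row. Corrections: Poisson `d = -ln(1 - p)`; gamma
#' `d = a((1-p)^(-1/a) - 1)`.
#'
#' @param msa named character vector of aligned sequences.
#' @param model `"p"`, `"poisson"` or `"gamma"`.
#' @param deletion `"pairwise"` or `"complete"`.
#' @param gamma_a gamma shape parameter (default 2).
#' @return a `dist` object with attributes `model`, `deletion`, `gamma_a`.
#' @export
seq_distance <- function(msa, model = c("poisson", "p", "gamma"),
                         deletion = c("pairwise", "complete"), gamma_a = 2) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  n <- length(msa)
  if (n < 2) abort("need at least 2 aligned sequences")
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_len(n))
  if (length(unique(nchar(msa))) != 1) abort("MSA rows differ in length")
  m <- do.call(rbind, strsplit(msa, ""))
  gapmat <- m == "-"
  keep_all <- !apply(gapmat, 2, any)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    keep <- if (deletion == "pairwise") !(gapmat[i, ] | gapmat[j, ]) else keep_all
    if (!any(keep)) abort(sprintf("no comparable columns between '%s' and '%s'",
                                  names(msa)[i], names(msa)[j]))
    p <- mean(m[i, keep] != m[j, keep])
    val <- switch(model,
      p = p,
      poisson = {
        if (p >= 1) abort(sprintf(
          "p-distance of 1 between '%s' and '%s': Poisson correction undefined",
          names(msa)[i], names(msa)[j]))
        -log(1 - p)
      },
      gamma = {
        if (p >= 1) abort(sprintf(
          "p-distance of 1 between '%s' and '%s': gamma correction undefined",
          names(msa)[i], names(msa)[j]))
        gamma_a * ((1 - p)^(-1 / gamma_a) - 1)
      })
    d[i, j] <- d[j, i] <- val
  }
  out <- stats::as.dist(d)
  attr(out, "model") <- model
  attr(out, "deletion") <- deletion
  attr(out, "gamma_a") <- gamma_a
  out
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via ape); negative branch lengths are clamped
#' to 0 with a message.
#'
#' @param dm a `dist` or symmetric matrix (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- stats::as.dist(dm)
  if (attr(dm, "Size") < 3) abort("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(dm)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr$edge.length <- tr$edge.length + 0 # normalise -0
  tr
}

# total OLS tree length for a topology given distances
ols_length <- function(tree, dm) {
  fit <- phangorn::nnls.tree(as.matrix(dm), tree, method = "unrooted")
  sum(pmax(fit$edge.length, 0))
}

#' Minimum-evolution tree
#'
#' Starting from `start` (default: the NJ tree), branch lengths are fitted by
#' ordinary least squares for each topology (negatives clamped to 0) and
#' nearest-neighbor-interchange moves are accepted while they reduce the
#' total tree length; the local optimum is returned. Deterministic given the
#' start tree.
#'
#' @param dm a `dist` or symmetric matrix.
#' @param start starting `phylo` topology over the same taxa.
#' @return an unrooted `phylo` tree with OLS branch lengths.
#' @export
me_tree <- function(dm, start = NULL) {
  dm <- stats::as.dist(dm)
  if (is.null(start)) start <- nj_tree(dm)
  tree <- ape::unroot(start)
  dmat <- as.matrix(dm)
  best_len <- ols_length(tree, dmat)
  repeat {
    if (length(tree$tip.label) < 4) break
    nbrs <- phangorn::nni(tree)
    lens <- vapply(nbrs, ols_length, numeric(1), dm = dmat)
    if (length(lens) == 0 || min(lens) >= best_len - 1e-12) break
    k <- which.min(lens)
    tree <- nbrs[[k]]
    best_len <- lens[k]
  }
  fit <- phangorn::nnls.tree(dmat, tree, method = "unrooted")
  fit$edge.length <- pmax(fit$edge.length, 0)
  fit
}

#' Bootstrap supports for a tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `builder`, and maps the percentage of replicates containing
#' each internal-edge bipartition of the full-data tree onto its node labels.
#'
#' @param msa named character vector of aligned sequences.
#' @param builder function(msa) returning a `phylo` tree (default: Poisson
#'   NJ, i.e. `nj_tree(seq_distance(msa))`).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed (resampling is deterministic given it).
#' @return the full-data tree with integer supports (0-100) as `node.label`.
#' @export
bootstrap_tree <- function(msa, builder = NULL, n_reps = 100L, seed = 1L) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (is.null(builder)) builder <- function(a) nj_tree(seq_distance(a))
  if (length(unique(nchar(msa))) != 1) abort("MSA rows differ in length")
  full <- builder(msa)
  m <- do.call(rbind, strsplit(msa, ""))
  L <- ncol(m)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(L, L, replace = TRUE)
      resampled <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                            names(msa))
      suppressMessages(builder(resampled)) # replicate-level clamp notes are noise
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- as.integer(round(100 * counts / n_reps))
  full$node.label <- as.character(support)
  full
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept; bootstrap supports (if present) are serialized as
#' internal-node labels.
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path a Newick file.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
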