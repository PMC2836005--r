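# Family grouping, consensus rebuilding and copy-divergence statistics.

#' Cluster element copies into families
#'
#' Single-linkage clustering on global pairwise nucleotide identity
#' (matches / alignment columns from a global alignment). Groups are numbered
#' deterministically by their leftmost (first) member.
#'
#' @param seqs character vector of element sequences (names kept as ids).
#' @param identity_threshold copies join a family when linked at or above
#'   this identity.
#' @return integer vector of cluster ids, named like `seqs`.
#' @export
cluster_copies <- function(seqs, identity_threshold = 0.8) {
  n <- length(seqs)
  if (n == 0) abort("no sequences to cluster")
  if (is.null(names(seqs))) names(seqs) <- paste0("copy", seq_len(n))
  if (n == 1) return(setNames(1L, names(seqs)))
  sm <- dna_submat()
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    r <- cpp_align(seqs[[i]], seqs[[j]], DNA_ALPHABET, sm, 0, 2, FALSE)
    id <- if (r$n_cols > 0) r$n_match / r$n_cols else 0
    d[i, j] <- d[j, i] <- 1 - id
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  grp <- stats::cutree(hc, h = 1 - identity_threshold)
  # renumber by first appearance
  grp <- as.integer(factor(grp, levels = unique(grp)))
  setNames(grp, names(seqs))
}

#' Majority-rule consensus of aligned copies
#'
#' Per column the most frequent non-gap base is emitted; columns that are
#' gaps in at least half the copies are dropped; frequency ties become IUPAC
#' ambiguity codes.
#'
#' @param aligned_copies character vector of equal-length (gapped) sequences.
#' @return consensus nucleotide string.
#' @export
build_consensus <- function(aligned_copies) {
  if (length(aligned_copies) == 0) abort("no copies supplied")
  lens <- nchar(aligned_copies)
  if (length(unique(lens)) != 1) abort("aligned copies differ in length")
  m <- do.call(rbind, strsplit(aligned_copies, ""))
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gap_frac <- mean(col == "-")
    if (gap_frac >= 0.5) next
    col <- col[col != "-"]
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    base <- if (length(top) == 1) top else {
      key <- paste(sort(top), collapse = "")
      code <- AMBIGUITY_CODE[[key]]
      if (is.null(code) || is.na(code)) "N" else code
    }
    out <- c(out, base)
  }
  paste(out, collapse = "")
}

#' Percent divergence of a copy from its consensus
#'
#' 100 x mismatches / compared columns, where columns gapped in either
#' sequence are excluded (pairwise deletion). Both inputs must already be
#' aligned to each other (equal length).
#'
#' @param copy,consensus equal-length (gapped) nucleotide strings.
#' @return percent divergence.
#' @export
copy_divergence <- function(copy, consensus) {
  if (nchar(copy) != nchar(consensus)) {
    abort("copy and consensus must be aligned (equal length)")
  }
  a <- strsplit(copy, "")[[1]]
  b <- strsplit(consensus, "")[[1]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) abort("no comparable (ungapped) columns")
  100 * mean(a[keep] != b[keep])
}

#' Per-family consensus and divergence report
#'
#' Clusters copies into families, aligns each family (copies of equal length
#' are stacked directly — the generator's substitution-only model — otherwise
#' the progressive aligner is used; families larger than `max_align` copies
#' are deterministically subsampled for the alignment), rebuilds the
#' consensus, and reports per-copy divergence under pairwise deletion.
#'
#' @param seqs named character vector of element sequences.
#' @param identity_threshold family clustering threshold.
#' @param max_align maximum copies aligned per family.
#' @return list with `report` (tibble: family, n_copies, min/mean divergence),
#'   `consensus` (named character vector) and `members` (cluster assignment).
#' @export
family_report <- function(seqs, identity_threshold = 0.8, max_align = 20L) {
  grp <- cluster_copies(seqs, identity_threshold)
  fams <- sort(unique(grp))
  reports <- list()
  cons <- character(0)
  for (f in fams) {
    members <- seqs[grp == f]
    sub <- if (length(members) > max_align) members[seq_len(max_align)] else members
    aligned <- if (length(unique(nchar(sub))) == 1) sub else progressive_align(sub)
    cs <- build_consensus(aligned)
    div <- vapply(aligned, function(s) {
      if (nchar(s) == nchar(cs)) copy_divergence(s, cs) else {
        al <- needleman_wunsch(s, cs, matrix = dna_submat(), gap_open = 0,
                               gap_extend = -2)
        copy_divergence(al$query_aln, al$target_aln)
      }
    }, numeric(1))
    fam_id <- paste0("family", f)
    cons[fam_id] <- cs
    reports[[length(reports) + 1L]] <- tibble(
      family = fam_id, n_copies = length(members),
      min_divergence = min(div), mean_divergence = mean(div)
    )
  }
  list(report = dplyr::bind_rows(reports), consensus = cons, members = grp)
}
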