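# Element-boundary logic: terminal inverted repeats, target-site
# duplications, terminal motifs, and boundary refinement around a
# transposase hit.

#' Find terminal inverted repeats
#'
#' Locally aligns the 5' window of the sequence against the reverse
#' complement of its 3' window (window = `max_len + terminal_anchor`) and
#' reports the best arm pair whose arms both start within `terminal_anchor`
#' bp of their respective termini. Scoring is match +1 / mismatch -1 /
#' gap -2 by default. If the best arm exceeds `max_len` it is reported in
#' full and flagged rather than truncated.
#'
#' @param seq element (or candidate element) nucleotide string.
#' @param min_len,max_len accepted arm-length range in bp.
#' @param min_identity minimum arm identity (matches / alignment columns).
#' @param terminal_anchor arms must begin within this many bp of the termini.
#' @param match,mismatch,gap alignment scores.
#' @param clean_run arm ends are trimmed back to the nearest run of this many
#'   consecutive matches, so that marginal chance extensions of the local
#'   alignment beyond the true arm do not inflate the arm length.
#' @return tibble of TIR pairs (0 or 1 row): `left_start0`, `left_end0`,
#'   `right_start0`, `right_end0`, `arm_length`, `arm_identity`, `score`,
#'   `flagged` (arm longer than `max_len`). Coordinates are relative to
#'   `seq`, 0-based half-open.
#' @export
find_tirs <- function(seq, min_len = 10L, max_len = 300L, min_identity = 0.8,
                      terminal_anchor = 5L, match = 1, mismatch = -1, gap = -2,
                      clean_run = 4L) {
  empty <- tibble(left_start0 = integer(0), left_end0 = integer(0),
                  right_start0 = integer(0), right_end0 = integer(0),
                  arm_length = integer(0), arm_identity = numeric(0),
                  score = numeric(0), flagged = logical(0))
  n <- nchar(seq)
  if (n <= 2 * min_len) return(empty)
  w <- min(n %/% 2L, max_len + terminal_anchor)
  w5 <- substr(seq, 1L, w)
  w3 <- substr(seq, n - w + 1L, n)
  w3rc <- revcomp(w3)
  sm <- dna_submat(match, mismatch)
  r <- cpp_align(w5, w3rc, DNA_ALPHABET, sm, 0, abs(gap), local = TRUE)
  if (r$score <= 0 || r$n_cols == 0) return(empty)
  qa <- strsplit(r$q_aln, "")[[1]]
  ta <- strsplit(r$t_aln, "")[[1]]
  is_match <- qa == ta & qa != "-"
  # trim both alignment ends back to a clean run of consecutive matches
  runs <- rle(is_match)
  ends <- cumsum(runs$lengths)
  good <- which(runs$values & runs$lengths >= clean_run)
  if (length(good) == 0) return(empty)
  first_col <- ends[good[1]] - runs$lengths[good[1]] + 1L
  last_col <- ends[good[length(good)]]
  keep <- seq.int(first_col, last_col)
  q_off <- sum(qa[seq_len(first_col - 1L)] != "-")
  t_off <- sum(ta[seq_len(first_col - 1L)] != "-")
  q_len <- sum(qa[keep] != "-")
  t_len <- sum(ta[keep] != "-")
  q_start <- r$q_start + q_off
  q_end <- q_start + q_len - 1L
  t_start <- r$t_start + t_off
  t_end <- t_start + t_len - 1L
  n_match <- sum(is_match[keep])
  n_cols <- length(keep)
  arm_len <- q_end - q_start + 1L
  identity <- n_match / n_cols
  if (arm_len < min_len || identity < min_identity) return(empty)
  if (q_start - 1L > terminal_anchor || t_start - 1L > terminal_anchor) {
    return(empty)
  }
  score <- sum(is_match[keep]) * match + sum(!is_match[keep] & qa[keep] != "-" &
                                               ta[keep] != "-") * mismatch +
    sum(qa[keep] == "-" | ta[keep] == "-") * gap
  # map the right arm from w3rc coordinates back to seq coordinates:
  # position p (1-based) in w3rc corresponds to seq position n - p (0-based)
  right_start0 <- n - t_end
  right_end0 <- n - t_start + 1L
  tibble(
    left_start0 = q_start - 1L, left_end0 = q_end,
    right_start0 = right_start0, right_end0 = right_end0,
    arm_length = arm_len, arm_identity = identity, score = score,
    flagged = arm_len > max_len
  )
}

#' Extract the target-site duplication at element bounds
#'
#' Returns the longest k in `[k_min, k_max]` such that the k-mers immediately
#' flanking the element are exactly equal; `NULL` when no k matches.
#'
#' @param genome genome (tibble, named string or plain string).
#' @param start0,end0 element bounds (0-based half-open).
#' @param k_min,k_max TSD length search range.
#' @return one-row tibble (`length`, `sequence`, flank coordinates) or `NULL`.
#' @export
extract_tsd <- function(genome, start0, end0, k_min = 3L, k_max = 6L) {
  g <- as_genome(genome)
  L <- nchar(g$seq)
  if (start0 < k_max || end0 + k_max > L) {
    abort(sprintf("element [%d,%d) too close to the contig edge for k_max=%d",
                  start0, end0, k_max))
  }
  for (k in seq.int(k_max, k_min)) {
    left <- substr(g$seq, start0 - k + 1L, start0)
    right <- substr(g$seq, end0 + 1L, end0 + k)
    if (left == right) {
      return(tibble(length = k, sequence = left,
                    left_start0 = start0 - k, left_end0 = start0,
                    right_start0 = end0, right_end0 = end0 + k))
    }
  }
  NULL
}

#' Check the conserved terminal motif of an element
#'
#' Tests the first bases against the IUPAC motif (default `TGTNR`) and the
#' last bases against its reverse complement (`YNACA`).
#'
#' @param element_seq element nucleotide string (length >= motif length).
#' @param motif IUPAC motif.
#' @return named logical vector `c(five_prime=, three_prime=)`.
#' @export
check_terminal_motif <- function(element_seq, motif = "TGTNR") {
  k <- nchar(motif)
  if (nchar(element_seq) < k) abort("element shorter than the terminal motif")
  c(five_prime = matches_iupac(element_seq, motif, at = 1L),
    three_prime = matches_iupac(element_seq, revcomp(motif),
                                at = nchar(element_seq) - k + 1L))
}

# Best local inverted-repeat pair between two genomic intervals.
# Returns NULL or list(l_start0, l_end0, r_start0, r_end0, score, n_match,
# n_cols) in genome coordinates.
inverted_pair <- function(seq, left_lo, left_hi, right_lo, right_hi,
                          gap = 2, min_len = 10L) {
  if (left_hi - left_lo < min_len || right_hi - right_lo < min_len) return(NULL)
  w5 <- substr(seq, left_lo + 1L, left_hi)
  w3rc <- revcomp(substr(seq, right_lo + 1L, right_hi))
  r <- cpp_align(w5, w3rc, DNA_ALPHABET, dna_submat(), 0, gap, local = TRUE)
  if (r$score <= 0 || (r$q_end - r$q_start + 1L) < min_len) return(NULL)
  list(
    l_start0 = left_lo + r$q_start - 1L, l_end0 = left_lo + r$q_end,
    r_start0 = right_hi - r$t_end, r_end0 = right_hi - r$t_start + 1L,
    score = r$score, n_match = r$n_match, n_cols = r$n_cols
  )
}

#' Refine element boundaries around a transposase hit
#'
#' Searches an expanding window around the hit for the inverted-repeat arm
#' pair that delimits the element, preferring candidates with an exact
#' target-site duplication and conserved terminal motifs, and among equals
#' the innermost pair. Candidate bounds are micro-adjusted within
#' `shift_range` bp to land exactly on the duplicated target site.
#'
#' @param genome genome (tibble, named string or plain string).
#' @param hit one row of [scan_for_tpase()] output (or any list with
#'   `start0`/`end0`).
#' @param search_radius maximum distance (bp) from the hit to an element
#'   terminus (searched in escalating steps).
#' @param min_arm_len minimum TIR arm length.
#' @param shift_range micro-adjustment range for boundary placement.
#' @param motif terminal motif.
#' @param k_min,k_max TSD length search range.
#' @return one-row annotation tibble (bounds, TIR pair, TSD, terminal-motif
#'   flags) or `NULL` when no TIR-delimited candidate is found.
#' @export
refine_boundaries <- function(genome, hit, search_radius = 10000L,
                              min_arm_len = 10L, shift_range = 10L,
                              motif = "TGTNR", k_min = 3L, k_max = 6L) {
  g <- as_genome(genome)
  L <- nchar(g$seq)
  hs <- as.integer(hit$start0)
  he <- as.integer(hit$end0)
  radii <- unique(pmin(search_radius, c(1500L, 3000L, 6000L, search_radius)))
  best <- NULL
  best_key <- rep(-Inf, 6) # tsd, motifs, -asymmetry, arm score, -span, -|shift|
  mk <- nchar(motif)
  motif_rc <- revcomp(motif)
  motif_re <- paste0("^", iupac_regex(motif))
  motif_rc_re <- paste0("^", iupac_regex(motif_rc))
  # lightweight longest-duplicated-k check (hot loop; no tibble/tryCatch)
  tsd_len_at <- function(s, e) {
    if (s < k_max || e + k_max > L) return(NA_integer_)
    for (k in seq.int(k_max, k_min)) {
      if (substr(g$seq, s - k + 1L, s) == substr(g$seq, e + 1L, e + k)) {
        return(k)
      }
    }
    NA_integer_
  }
  evaluate <- function(s, e, s0, e0, pair_score) {
    tsd <- tsd_len_at(s, e)
    mot <- c(
      five_prime = grepl(motif_re, substr(g$seq, s + 1L, s + mk)),
      three_prime = grepl(motif_rc_re, substr(g$seq, e - mk + 1L, e))
    )
    # the arm alignment overshoots the element symmetrically, so the true
    # boundary trims it by about the same amount on both sides; asymmetric
    # trims indicate a chance duplication. The (bucketed) arm-pair score
    # separates real TIR pairs from the weak chance alignments of random
    # flanking sequence.
    sym <- abs((s - s0) + (e - e0))
    key <- c(as.numeric(!is.na(tsd)), sum(mot), -(sym %/% 3L),
             pair_score %/% 20, -(e - s), -(abs(s - s0) + abs(e - e0)))
    list(key = key, cand = list(s = s, e = e, tsd = tsd, mot = mot))
  }
  consider <- function(cand) {
    # Local alignment of the arms often runs outward through the duplicated
    # target site (a 4-bp TSD is frequently its own reverse complement) and
    # any chance matches beyond it, so the arm-pair bounds overestimate the
    # element symmetrically. Boundary placement is therefore anchored on the
    # TSD: enumerate (start, end) pairs near the alignment bounds whose
    # flanking 4-mers are exactly duplicated, and score them by TSD
    # presence, terminal motifs, span, and shift distance.
    s0 <- cand$l_start0; e0 <- cand$r_end0
    inward <- 150L
    ss <- s0 + seq.int(-shift_range, inward)
    ee <- e0 + seq.int(-inward, shift_range)
    ss <- ss[ss >= k_max & ss <= hs & ss < e0 - 2L * min_arm_len]
    ee <- ee[ee + k_max <= L & ee >= he & ee > s0 + 2L * min_arm_len]
    top <- NULL
    top_key <- rep(-Inf, 6)
    if (length(ss) > 0 && length(ee) > 0) {
      left4 <- substring(g$seq, ss - 3L, ss)
      right4 <- substring(g$seq, ee + 1L, ee + 4L)
      hitmat <- outer(left4, right4, "==")
      idx <- which(hitmat, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        s <- ss[idx[r, 1]]; e <- ee[idx[r, 2]]
        if (e - s < 2L * min_arm_len) next
        ev <- evaluate(s, e, s0, e0, cand$score)
        if (key_greater(ev$key, top_key)) { top_key <- ev$key; top <- ev$cand }
      }
    }
    if (is.null(top) && s0 >= k_max && e0 + k_max <= L && e0 - s0 > 2L * min_arm_len) {
      ev <- evaluate(s0, e0, s0, e0, cand$score) # no duplicated 4-mer: raw bounds
      top_key <- ev$key; top <- ev$cand
    }
    if (is.null(top)) return(invisible())
    if (key_greater(top_key, best_key)) {
      best_key <<- top_key
      best <<- top
    }
  }
  for (radius in radii) {
    key_before <- best_key
    lo <- max(0L, hs - radius)
    hi <- min(L, he + radius)
    # enumerate inverted-repeat candidates, iteratively truncating each side
    # towards the hit so that the innermost enclosing pair is always seen
    right_hi <- hi
    for (i in 1:3) {
      pair_r <- inverted_pair(g$seq, lo, hs, he, right_hi, min_len = min_arm_len)
      if (is.null(pair_r)) break
      pair <- pair_r
      left_lo <- lo
      for (j in 1:3) {
        consider(pair)
        left_lo <- pair$l_end0 # exclude this left arm; look further inward
        if (hs - left_lo < min_arm_len) break
        pair2 <- inverted_pair(g$seq, left_lo, hs, he, right_hi,
                               min_len = min_arm_len)
        if (is.null(pair2)) break
        pair <- pair2
      }
      right_hi <- pair_r$r_start0
      if (right_hi - he < min_arm_len) break
    }
    # stop escalating on an unambiguous boundary (exact TSD plus both
    # terminal motifs), or when a TSD-bearing best stopped improving --
    # a bare 4-mer duplication alone is too easy by chance
    if (!is.null(best) && best_key[1] == 1 && best_key[2] == 2) break
    if (!is.null(best) && best_key[1] == 1 && identical(best_key, key_before)) break
  }
  if (is.null(best)) return(NULL)
  s <- best$s; e <- best$e
  elem <- substr(g$seq, s + 1L, e)
  tirs <- find_tirs(elem, min_len = min_arm_len, max_len = search_radius,
                    min_identity = 0, terminal_anchor = shift_range + 5L)
  tsd <- if (!is.na(best$tsd)) {
    tryCatch(extract_tsd(g, s, e, k_min, k_max), error = function(err) NULL)
  } else NULL
  tibble(
    contig = g$id, start0 = s, end0 = e, strand = "+",
    tir_left_start0 = if (nrow(tirs)) s + tirs$left_start0 else NA_integer_,
    tir_left_end0 = if (nrow(tirs)) s + tirs$left_end0 else NA_integer_,
    tir_right_start0 = if (nrow(tirs)) s + tirs$right_start0 else NA_integer_,
    tir_right_end0 = if (nrow(tirs)) s + tirs$right_end0 else NA_integer_,
    arm_length = if (nrow(tirs)) tirs$arm_length else NA_integer_,
    arm_identity = if (nrow(tirs)) tirs$arm_identity else NA_real_,
    tsd_len = if (!is.null(tsd)) tsd$length else NA_integer_,
    tsd_seq = if (!is.null(tsd)) tsd$sequence else NA_character_,
    motif_5p = unname(best$mot["five_prime"]),
    motif_3p = unname(best$mot["three_prime"])
  )
}

# lexicographic comparison of numeric keys
key_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}
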