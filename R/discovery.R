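# Candidate transposase loci: six-frame translation plus local protein
# alignment of window translations against a query panel (the in-package
# replacement for a Tblastn/Blastp step).

#' Six-frame translation
#'
#' Frames +1..+3 translate the forward strand at offsets 0..2; frames -1..-3
#' translate the reverse complement likewise. Stop codons are rendered `*`,
#' ambiguous codons `X`; trailing partial codons are dropped.
#'
#' @param seq nucleotide string (length >= 3).
#' @return named character vector of 6 protein strings
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3) abort("sequence shorter than one codon")
  rc <- revcomp(seq)
  fr <- function(s, off) translate_dna(substr(s, off + 1, nchar(s)))
  c(`+1` = fr(seq, 0), `+2` = fr(seq, 1), `+3` = fr(seq, 2),
    `-1` = fr(rc, 0), `-2` = fr(rc, 1), `-3` = fr(rc, 2))
}

#' Local protein alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under BLOSUM62 (default) with affine gap costs:
#' a gap of length k costs `|gap_open| + k * |gap_extend|`. Traceback ties
#' are broken diagonal > up > left. Residues absent from the substitution
#' matrix raise an error.
#'
#' @param query,target protein strings.
#' @param matrix substitution matrix with residue dimnames (default
#'   BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend gap scores (negative, BLAST-style defaults).
#' @return a list: `score`, 1-based `query_start/end`, `target_start/end`,
#'   aligned strings `query_aln`/`target_aln`, `identity` (matches over
#'   alignment columns; `NA` for an empty alignment).
#' @export
smith_waterman <- function(query, target, matrix = NULL,
                           gap_open = -11, gap_extend = -1) {
  if (nchar(query) == 0 || nchar(target) == 0) abort("empty sequence")
  if (is.null(matrix)) matrix <- blosum62()
  alphabet <- paste(rownames(matrix), collapse = "")
  r <- cpp_align(query, target, alphabet, matrix, abs(gap_open),
                 abs(gap_extend), local = TRUE)
  list(score = r$score,
       query_start = r$q_start, query_end = r$q_end,
       target_start = r$t_start, target_end = r$t_end,
       query_aln = r$q_aln, target_aln = r$t_aln,
       identity = if (r$n_cols > 0) r$n_match / r$n_cols else NA_real_)
}

#' Global protein/nucleotide alignment (Needleman-Wunsch, affine gaps)
#'
#' @inheritParams smith_waterman
#' @return as [smith_waterman()] (start/end span the full sequences).
#' @export
needleman_wunsch <- function(query, target, matrix = NULL,
                             gap_open = -11, gap_extend = -1) {
  if (nchar(query) == 0 || nchar(target) == 0) abort("empty sequence")
  if (is.null(matrix)) matrix <- blosum62()
  alphabet <- paste(rownames(matrix), collapse = "")
  r <- cpp_align(query, target, alphabet, matrix, abs(gap_open),
                 abs(gap_extend), local = FALSE)
  list(score = r$score,
       query_aln = r$q_aln, target_aln = r$t_aln,
       identity = if (r$n_cols > 0) r$n_match / r$n_cols else NA_real_)
}

# Map a protein-coordinate interval in a window translation back to genomic
# (forward-strand, 0-based half-open) coordinates.
map_hit_coords <- function(w0, wlen, frame, p_start, p_end) {
  off <- abs(frame) - 1L
  if (frame > 0) {
    c(w0 + off + 3L * (p_start - 1L), w0 + off + 3L * p_end)
  } else {
    rc_s0 <- off + 3L * (p_start - 1L)
    rc_e0 <- off + 3L * p_end
    c(w0 + wlen - rc_e0, w0 + wlen - rc_s0)
  }
}

#' Scan a genome for transposase-coding loci
#'
#' Translates overlapping windows in all six frames and aligns each
#' translation locally against every query peptide; hits at or above
#' `min_score` are mapped back to forward-strand genomic coordinates and
#' overlapping hits are merged keeping the best score.
#'
#' @param genome genome (tibble, named string or plain string).
#' @param query_panel protein queries: named character vector or a tibble
#'   with `id`/`seq` (e.g. from [read_fasta()]).
#' @param min_score minimum local alignment score (BLOSUM62 units).
#' @param window,step scan window size and stride in bp.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap scores.
#' @return tibble of hits: `contig`, `start0`, `end0`, `frame`, `query_id`,
#'   `score`, `identity`.
#' @export
scan_for_tpase <- function(genome, query_panel, min_score = 60,
                           window = 2000L, step = window %/% 2L,
                           matrix = NULL, gap_open = -11, gap_extend = -1) {
  g <- as_genome(genome)
  if (is.data.frame(query_panel)) {
    query_panel <- setNames(query_panel$seq, query_panel$id)
  }
  if (length(query_panel) == 0) abort("query panel is empty")
  if (is.null(names(query_panel))) {
    names(query_panel) <- paste0("query", seq_along(query_panel))
  }
  if (is.null(matrix)) matrix <- blosum62()
  alphabet <- paste(rownames(matrix), collapse = "")
  L <- nchar(g$seq)
  starts <- unique(c(seq.int(0L, max(0L, L - window), by = step),
                     max(0L, L - window)))
  empty <- tibble(contig = character(0), start0 = integer(0), end0 = integer(0),
                  frame = integer(0), query_id = character(0),
                  score = numeric(0), identity = numeric(0))
  if (L < 3) return(empty)

  # translate all windows in all six frames (batched per frame)
  wins <- vapply(starts, function(s) substr(g$seq, s + 1L, min(L, s + window)),
                 character(1))
  rcs <- revcomp(wins)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  hits <- list()
  for (f in frames) {
    src <- if (f > 0) wins else rcs
    off <- abs(f) - 1L
    trimmed <- substr(src, off + 1L, nchar(src))
    keep_len <- nchar(trimmed) - nchar(trimmed) %% 3L
    ok <- keep_len >= 3L
    if (!any(ok)) next
    prots <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(substr(trimmed[ok], 1L, keep_len[ok])),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
    idx_ok <- which(ok)
    for (q in seq_along(query_panel)) {
      df <- cpp_align_many(prots, query_panel[[q]], alphabet, matrix,
                           abs(gap_open), abs(gap_extend), TRUE)
      sel <- which(df$score >= min_score)
      for (k in sel) {
        w <- idx_ok[k]
        coords <- map_hit_coords(starts[w], nchar(wins[w]), f,
                                 df$q_start[k], df$q_end[k])
        hits[[length(hits) + 1L]] <- tibble(
          contig = g$id, start0 = coords[1], end0 = coords[2], frame = f,
          query_id = names(query_panel)[q], score = df$score[k],
          identity = df$n_match[k] / df$n_cols[k])
      }
    }
  }
  if (length(hits) == 0) return(empty)
  out <- dplyr::bind_rows(hits) %>% arrange(.data$start0, dplyr::desc(.data$score))
  # merge overlapping hits, keeping the best-scoring representative
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    if (is.null(cur)) { cur <- row; next }
    if (row$start0 < cur$end0) { # overlap
      if (row$score > cur$score) {
        keep_end <- max(cur$end0, row$end0)
        cur <- row
        cur$end0 <- keep_end
      } else {
        cur$end0 <- max(cur$end0, row$end0)
      }
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1L]] <- cur
  dplyr::bind_rows(merged)
}
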