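# End-to-end annotation: transposase scan -> boundary refinement -> feature
# assembly -> classification, plus TSD logo statistics.

#' Annotate a genome for Ginger-style DNA transposons
#'
#' Runs the transposase scan ([scan_for_tpase()]), refines element boundaries
#' around every hit ([refine_boundaries()]), optionally reconstructs the
#' transposase gene model against a full-length homolog to obtain motif
#' evidence, and classifies each locus ([classify_elements()]). Hits whose
#' surroundings yield no TIR pair are kept as TIR-less loci (candidate
#' vestiges).
#'
#' @param genome genome (tibble, named string or plain string).
#' @param query_panel protein queries for the transposase scan (named
#'   character vector or id/seq tibble).
#' @param homolog_panel optional full-length transposase homologs (named by
#'   the same ids as `query_panel`) used for spliced gene reconstruction and
#'   motif evidence; set to `NULL` to skip the gene stage.
#' @param rt_rnh_panel optional RT/RNase-H queries for the 5-kb flank veto
#'   (`NULL` skips it and records `FALSE`).
#' @param min_score minimum transposase-hit score.
#' @param search_radius boundary search radius around a hit (bp).
#' @param motif terminal motif (IUPAC).
#' @param classify append classification labels.
#' @return annotation tibble, one row per locus: bounds, TIR pair, TSD,
#'   terminal-motif flags, motif evidence, and (optionally) `label` and
#'   `evidence`.
#' @export
annotate_genome <- function(genome, query_panel, homolog_panel = NULL,
                            rt_rnh_panel = NULL, min_score = 60,
                            search_radius = 10000L, motif = "TGTNR",
                            classify = TRUE) {
  g <- as_genome(genome)
  if (is.data.frame(query_panel)) query_panel <- setNames(query_panel$seq, query_panel$id)
  if (is.data.frame(homolog_panel)) homolog_panel <- setNames(homolog_panel$seq, homolog_panel$id)
  hits <- scan_for_tpase(g, query_panel, min_score = min_score)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, ]
    ann <- refine_boundaries(g, hit, search_radius = search_radius, motif = motif)
    if (is.null(ann)) {
      ann <- tibble(
        contig = g$id, start0 = hit$start0, end0 = hit$end0, strand = "+",
        tir_left_start0 = NA_integer_, tir_left_end0 = NA_integer_,
        tir_right_start0 = NA_integer_, tir_right_end0 = NA_integer_,
        arm_length = NA_integer_, arm_identity = NA_real_,
        tsd_len = NA_integer_, tsd_seq = NA_character_,
        motif_5p = FALSE, motif_3p = FALSE)
    }
    ann$query_id <- hit$query_id
    ann$hit_score <- hit$score
    ann$frame <- hit$frame
    ann$tpase_hit <- TRUE
    ann$tir_present <- !is.na(ann$arm_length)
    # motif evidence from a spliced gene model against the full-length homolog
    ann$gpyf <- FALSE
    ann$ypyy <- FALSE
    if (!is.null(homolog_panel) && hit$query_id %in% names(homolog_panel)) {
      region <- c(max(0L, ann$start0), min(nchar(g$seq), ann$end0))
      gm <- tryCatch(
        reconstruct_cds(g, region, homolog_panel[[hit$query_id]],
                        strand = if (hit$frame < 0) "-" else "+"),
        error = function(e) NULL)
      if (!is.null(gm) && nchar(gm$protein) > 0) {
        mh <- scan_motifs(gm$protein)
        ann$gpyf <- "GPYF" %in% mh$motif
        ann$ypyy <- "YPYY" %in% mh$motif
        ann$n_introns <- nrow(gm$introns)
      }
    }
    ann$rt_rnh_flank <- if (!is.null(rt_rnh_panel) && !ann$tir_present) {
      flank_encodes_rt_rnh(g, ann$start0, ann$end0, rt_rnh_panel,
                           min_score = min_score)
    } else FALSE
    rows[[length(rows) + 1L]] <- ann
  }
  if (length(rows) == 0) {
    return(tibble(element_id = character(0), contig = character(0),
                  start0 = integer(0), end0 = integer(0), strand = character(0),
                  tir_present = logical(0), tsd_len = integer(0),
                  tsd_seq = character(0), label = character(0)))
  }
  out <- dplyr::bind_rows(rows) %>%
    arrange(.data$contig, .data$start0) %>%
    mutate(element_id = sprintf("gs%04d", dplyr::row_number()), .before = 1)
  if (classify) out <- classify_elements(out)
  out
}

#' Match recovered annotations to a planted truth set
#'
#' @param annotations output of [annotate_genome()].
#' @param truth truth tibble from [simulate_genome()].
#' @param tol maximum boundary error (bp) for a match.
#' @return `truth` with matched annotation columns (`found`, boundary errors,
#'   recovered TSD/TIR) joined on overlapping coordinates.
#' @export
match_truth <- function(annotations, truth, tol = 50L) {
  res <- lapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    cand <- annotations %>%
      filter(.data$start0 < t$end0 + tol, .data$end0 > t$start0 - tol)
    if (nrow(cand) == 0) {
      return(tibble(element_id = t$element_id, found = FALSE,
                    start_err = NA_integer_, end_err = NA_integer_,
                    det_tsd_len = NA_integer_, det_tsd_seq = NA_character_,
                    det_arm_length = NA_integer_, tir_recovered = FALSE))
    }
    cand <- cand %>%
      mutate(err = abs(.data$start0 - t$start0) + abs(.data$end0 - t$end0)) %>%
      arrange(.data$err)
    b <- cand[1, ]
    tibble(element_id = t$element_id, found = TRUE,
           start_err = b$start0 - t$start0, end_err = b$end0 - t$end0,
           det_tsd_len = b$tsd_len, det_tsd_seq = b$tsd_seq,
           det_arm_length = b$arm_length,
           tir_recovered = if ("tir_present" %in% names(b)) b$tir_present
                           else !is.na(b$arm_length))
  })
  dplyr::left_join(truth, dplyr::bind_rows(res), by = "element_id")
}

#' TSD logo statistics for an annotation table
#'
#' Builds the position frequency matrix and information content from the
#' recovered TSDs of a single length (default: the modal length).
#'
#' @param annotations annotation tibble with a `tsd_seq` column.
#' @param length TSD length to use (default: modal recovered length).
#' @return list with `pfm` (a `tsd_pfm`), `ic` (bits per position), and the
#'   `length` used.
#' @export
tsd_logo <- function(annotations, length = NULL) {
  tsds <- annotations$tsd_seq[!is.na(annotations$tsd_seq)]
  if (base::length(tsds) == 0) abort("no recovered TSDs")
  lens <- nchar(tsds)
  if (is.null(length)) {
    tab <- table(lens)
    length <- as.integer(names(tab)[which.max(tab)])
  }
  tsds <- tsds[lens == length]
  pfm <- tsd_matrix(tsds)
  list(pfm = pfm, ic = information_content(pfm), length = length)
}
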