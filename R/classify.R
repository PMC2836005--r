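# Rule-based element classification: Ginger1, Ginger2/Tdd, LTR-retro-like,
# vestige, or unclassified.

#' Do the 5-kb flanks of a region encode RT or RNase H?
#'
#' Scans both flanking windows with a reverse-transcriptase / RNase-H query
#' panel; a locus whose flanks encode either is interpreted as a decayed LTR
#' retrotransposon rather than a DNA-transposon vestige. Flanks truncated by
#' a contig edge are scanned as far as available.
#'
#' @param genome genome (tibble, named string or plain string).
#' @param start0,end0 region bounds (0-based half-open).
#' @param query_panel RT/RNase-H protein queries (named character vector or
#'   id/seq tibble); see [synthetic_rt_rnh_panel()] for bundled exemplars.
#' @param window flank width in bp.
#' @param min_score minimum alignment score (as in [scan_for_tpase()]).
#' @return `TRUE` iff either flank yields a hit at or above `min_score`.
#' @export
flank_encodes_rt_rnh <- function(genome, start0, end0,
                                 query_panel = synthetic_rt_rnh_panel(),
                                 window = 5000L, min_score = 60) {
  g <- as_genome(genome)
  L <- nchar(g$seq)
  left_lo <- max(0L, start0 - window)
  right_hi <- min(L, end0 + window)
  for (b in list(c(left_lo, start0), c(end0, right_hi))) {
    if (b[2] - b[1] < 3) next
    flank <- substr(g$seq, b[1] + 1L, b[2])
    hits <- scan_for_tpase(setNames(flank, g$id), query_panel,
                           min_score = min_score,
                           window = min(2000L, nchar(flank)))
    if (nrow(hits) > 0) return(TRUE)
  }
  FALSE
}

#' Classify one element from its structural features
#'
#' Ordered decision rules: (1) RT/RNase-H in a 5-kb flank vetoes a DNA
#' transposon call (LTR-retro-like); (2) TIRs + 4-bp TSD + GPY/F or YPYY =
#' Ginger1; (3) TIRs + 4-bp TSD without those motifs = Ginger2; (4) TIRs +
#' 5-bp TSD = Ginger2/Tdd (TDD-4/5-like); (5) a transposase hit with no TIRs
#' and clean flanks = vestige; otherwise unclassified. TSD composition
#' (GC-rich CCGG/CCGT-type vs AT-rich RTATAY context) is recorded as
#' advisory evidence, never as a hard rule.
#'
#' @param tpase_hit was a transposase-coding region detected?
#' @param tir_present were both TIR arms found?
#' @param tsd_len TSD length in bp (`NA` when absent).
#' @param tsd_seq TSD sequence (optional, used for advisory evidence).
#' @param gpyf,ypyy motif presence in the reconstructed transposase.
#' @param rt_rnh_flank result of [flank_encodes_rt_rnh()].
#' @return one-row tibble: `label` and `evidence` (a `;`-separated
#'   criterion=outcome chain; empty only for `unclassified`).
#' @export
classify_element <- function(tpase_hit, tir_present, tsd_len = NA,
                             tsd_seq = NA_character_, gpyf = FALSE,
                             ypyy = FALSE, rt_rnh_flank = FALSE) {
  ev <- character(0)
  add <- function(ev, criterion, outcome) c(ev, paste0(criterion, "=", outcome))
  tsd4 <- !is.na(tsd_len) && tsd_len == 4
  tsd5 <- !is.na(tsd_len) && tsd_len == 5
  label <- "unclassified"
  if (isTRUE(rt_rnh_flank)) {
    label <- "LTR_retro_like"
    ev <- add(ev, "rt_rnh_flank", "TRUE")
  } else if (isTRUE(tir_present) && tsd4 && (isTRUE(gpyf) || isTRUE(ypyy))) {
    label <- "Ginger1"
    ev <- add(ev, "tir", "TRUE"); ev <- add(ev, "tsd_len", "4")
    ev <- add(ev, "gpyf_or_ypyy", "TRUE")
  } else if (isTRUE(tir_present) && tsd4) {
    label <- "Ginger2"
    ev <- add(ev, "tir", "TRUE"); ev <- add(ev, "tsd_len", "4")
    ev <- add(ev, "gpyf_or_ypyy", "FALSE")
  } else if (isTRUE(tir_present) && tsd5) {
    label <- "Ginger2_Tdd5like"
    ev <- add(ev, "tir", "TRUE"); ev <- add(ev, "tsd_len", "5")
  } else if (isTRUE(tpase_hit) && !isTRUE(tir_present)) {
    label <- "vestige"
    ev <- add(ev, "tpase", "TRUE"); ev <- add(ev, "tir", "FALSE")
    ev <- add(ev, "rt_rnh_flank", "FALSE")
  }
  if (!is.na(tsd_seq) && label %in% c("Ginger1", "Ginger2")) {
    gc <- mean(strsplit(tsd_seq, "")[[1]] %in% c("G", "C"))
    ev <- add(ev, "tsd_context",
              if (gc >= 0.5) "GC_rich" else "AT_rich") # advisory only
  }
  tibble(label = label, evidence = paste(ev, collapse = ";"))
}

#' Classify a table of elements
#'
#' Vectorised [classify_element()] over the rows of a feature tibble
#' (columns `tpase_hit`, `tir_present`, `tsd_len`, and optionally `tsd_seq`,
#' `gpyf`, `ypyy`, `rt_rnh_flank`).
#'
#' @param features a tibble of per-element features.
#' @return `features` with `label` and `evidence` columns appended.
#' @export
classify_elements <- function(features) {
  col_or <- function(nm, default) {
    if (nm %in% names(features)) features[[nm]] else rep(default, nrow(features))
  }
  res <- purrr::pmap(list(
    tpase_hit = col_or("tpase_hit", TRUE),
    tir_present = features$tir_present,
    tsd_len = col_or("tsd_len", NA),
    tsd_seq = col_or("tsd_seq", NA_character_),
    gpyf = col_or("gpyf", FALSE),
    ypyy = col_or("ypyy", FALSE),
    rt_rnh_flank = col_or("rt_rnh_flank", FALSE)
  ), classify_element)
  dplyr::bind_cols(features, dplyr::bind_rows(res))
}
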