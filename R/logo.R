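# TSD composition statistics and sequence-logo information content.

#' Position frequency matrix from TSD sequences
#'
#' @param tsds character vector of equal-length A/C/G/T strings.
#' @return a `tsd_pfm` object: 4 x L frequency matrix (`$mat`, columns sum to
#'   1) plus the site count `$n_sites`.
#' @export
tsd_matrix <- function(tsds) {
  if (length(tsds) == 0) abort("no TSD sequences supplied")
  lens <- nchar(tsds)
  if (length(unique(lens)) != 1) abort("TSD sequences differ in length")
  chars <- do.call(rbind, strsplit(tsds, ""))
  bad <- setdiff(unique(as.vector(chars)), c("A", "C", "G", "T"))
  if (length(bad) > 0) abort(paste0("non-ACGT character in TSDs: ", bad[1]))
  L <- unique(lens)
  mat <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(tsds)
  }, numeric(4))
  rownames(mat) <- c("A", "C", "G", "T")
  colnames(mat) <- paste0("pos", seq_len(L))
  structure(list(mat = mat, n_sites = length(tsds)), class = "tsd_pfm")
}

#' Per-position information content (bits)
#'
#' `IC_j = 2 - H_j` with `H_j = -sum_b f_bj log2 f_bj` (and `0 log 0 := 0`).
#' With the small-sample correction, `e(n) = 3 / (2 ln(2) n)` is subtracted
#' and the result floored at 0.
#'
#' @param pfm a `tsd_pfm` (or plain column-stochastic 4-row matrix).
#' @param small_sample_correction apply the 4-letter small-sample correction.
#' @return numeric vector of per-position bits in `[0, 2]`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  mat <- if (inherits(pfm, "tsd_pfm")) pfm$mat else pfm
  n <- if (inherits(pfm, "tsd_pfm")) pfm$n_sites else NA_integer_
  ic <- apply(mat, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  if (small_sample_correction) {
    if (is.na(n)) abort("small-sample correction needs n_sites")
    ic <- pmax(ic - 3 / (2 * log(2) * n), 0)
  }
  ic
}

#' @export
print.tsd_pfm <- function(x, ...) {
  cat(sprintf("<tsd_pfm> %d positions from %d sites\n", ncol(x$mat), x$n_sites))
  print(round(x$mat, 3))
  invisible(x)
}

#' @export
tidy.tsd_pfm <- function(x, ...) {
  tibble(
    position = rep(seq_len(ncol(x$mat)), each = 4),
    base = rep(rownames(x$mat), ncol(x$mat)),
    frequency = as.vector(x$mat)
  )
}

#' @export
glance.tsd_pfm <- function(x, ...) {
  tibble(n_sites = x$n_sites, n_positions = ncol(x$mat),
         total_bits = sum(information_content(x)))
}

#' Sequence-logo style plot of a TSD frequency matrix
#'
#' Stacked per-position bars scaled by information content (bits).
#'
#' @param object a `tsd_pfm`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tsd_pfm <- function(object, ...) {
  ic <- information_content(object)
  df <- tidy(object) %>%
    mutate(bits = .data$frequency * ic[.data$position])
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$bits,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "TSD position", y = "bits", fill = "base") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
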