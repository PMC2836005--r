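# FASTA / GFF3 / TSV input-output. Internal coordinates are 0-based
# half-open; GFF3 is written 1-based inclusive (start0 + 1, end0).

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased; the record id is the first whitespace token of
#' the header and the remainder is kept as `desc`. Parse problems (empty
#' file, duplicate ids, non-IUPAC characters) raise errors naming the
#' offending line.
#'
#' @param path path to a FASTA file (plain text, wrapped or unwrapped).
#' @param alphabet `"dna"` to validate characters against the IUPAC
#'   nucleotide alphabet, `"protein"` to accept amino-acid letters,
#'   `*` and `-`.
#' @return a tibble with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("empty FASTA file: ", path))
  ok_chars <- if (alphabet == "dna") {
    paste0("^[", paste(names(IUPAC_NT), collapse = ""), "-]*$")
  } else {
    "^[A-Z*-]*$"
  }
  headers <- grep("^>", lines)
  if (length(headers) == 0 || headers[1] != 1) {
    abort(paste0(path, ": line 1 is not a FASTA header"))
  }
  ids <- character(length(headers))
  descs <- character(length(headers))
  seqs <- character(length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    h <- sub("^>", "", lines[headers[k]])
    toks <- strsplit(h, "\\s+")[[1]]
    ids[k] <- if (length(toks) >= 1) toks[1] else ""
    descs[k] <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    body <- lines[seq.int(headers[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[!grepl("^>", body)]
    body_up <- toupper(body)
    bad <- which(!grepl(ok_chars, body_up))
    if (length(bad) > 0) {
      abort(sprintf("%s: non-IUPAC character on line %d", path,
                    headers[k] + bad[1]))
    }
    seqs[k] <- paste(body_up, collapse = "")
    if (ids[k] == "") abort(sprintf("%s: empty record id on line %d", path, headers[k]))
    if (seqs[k] == "") abort(sprintf("%s: empty sequence for record '%s' (line %d)",
                                     path, ids[k], headers[k]))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate record id '%s' (line %d)", path, dup[1],
                  headers[which(duplicated(ids))[1]]))
  }
  tibble(id = ids, desc = descs, seq = seqs)
}

#' Write sequences to FASTA
#'
#' @param x a tibble with `id` and `seq` columns (optionally `desc`) or a
#'   named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x)) {
    x <- tibble(id = names(x) %||% paste0("seq", seq_along(x)), seq = unname(x))
  }
  nm <- x$id
  if ("desc" %in% names(x)) {
    has <- !is.na(x$desc) & x$desc != ""
    nm[has] <- paste(x$id[has], x$desc[has])
  }
  set <- Biostrings::BStringSet(setNames(x$seq, nm))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  gsub(";", "%3B", gsub("=", "%3D", gsub(",", "%2C", x)))
}

#' Write element annotations as GFF3
#'
#' Each element becomes a `transposable_element` feature with
#' `terminal_inverted_repeat` and `target_site_duplication` child features
#' where TIR/TSD records are present. Coordinates are converted to 1-based
#' inclusive; output is ordered by (contig, start, id).
#'
#' @param annotations an annotation tibble (see [annotate_genome()] or the
#'   truth set from [simulate_genome()]); required columns `element_id`,
#'   `contig`, `start0`, `end0`, `strand`; optional TIR/TSD columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(annotations, path) {
  lines <- "##gff-version 3"
  has <- function(col) col %in% names(annotations)
  if (nrow(annotations) > 0) {
    ann <- dplyr::arrange(annotations, .data$contig, .data$start0, .data$element_id)
    for (i in seq_len(nrow(ann))) {
      a <- ann[i, ]
      attrs <- paste0("ID=", gff3_escape(a$element_id))
      extra <- character(0)
      if (has("family") && !is.na(a$family)) {
        extra <- c(extra, paste0("family=", gff3_escape(a$family)))
      }
      if (has("label") && !is.na(a$label)) {
        extra <- c(extra, paste0("classification=", gff3_escape(a$label)))
      }
      attrs <- paste(c(attrs, extra), collapse = ";")
      lines <- c(lines, paste(
        a$contig, "gingerscan", "transposable_element",
        a$start0 + 1L, a$end0, ".", a$strand, ".", attrs, sep = "\t"))
      kid <- function(type, s0, e0, suffix) {
        paste(a$contig, "gingerscan", type, s0 + 1L, e0, ".", a$strand, ".",
              paste0("ID=", gff3_escape(a$element_id), suffix,
                     ";Parent=", gff3_escape(a$element_id)),
              sep = "\t")
      }
      if (has("tir_left_start0") && !is.na(a$tir_left_start0)) {
        lines <- c(lines,
          kid("terminal_inverted_repeat", a$tir_left_start0, a$tir_left_end0, ".tir5"),
          kid("terminal_inverted_repeat", a$tir_right_start0, a$tir_right_end0, ".tir3"))
      }
      if (has("tsd_seq") && !is.na(a$tsd_seq)) {
        k <- nchar(a$tsd_seq)
        lines <- c(lines,
          kid("target_site_duplication", a$start0 - k, a$start0, ".tsd5"),
          kid("target_site_duplication", a$end0, a$end0 + k, ".tsd3"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gingerscan GFF3 file back into an annotation tibble
#'
#' Parses `transposable_element` features (with TIR/TSD children) written by
#' [write_gff3()], restoring 0-based half-open coordinates.
#'
#' @param path a GFF3 file.
#' @return an annotation tibble.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(element_id = character(0), contig = character(0),
                  start0 = integer(0), end0 = integer(0), strand = character(0)))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  df <- tibble(
    contig = f[, 1], type = f[, 3],
    start0 = as.integer(f[, 4]) - 1L, end0 = as.integer(f[, 5]),
    strand = f[, 7], id = attr_field(f[, 9], "ID"),
    parent = attr_field(f[, 9], "Parent"),
    family = attr_field(f[, 9], "family"),
    label = attr_field(f[, 9], "classification")
  )
  el <- df %>% filter(.data$type == "transposable_element")
  out <- tibble(
    element_id = el$id, contig = el$contig, start0 = el$start0,
    end0 = el$end0, strand = el$strand, family = el$family, label = el$label
  )
  tir <- df %>% filter(.data$type == "terminal_inverted_repeat")
  if (nrow(tir) > 0) {
    left <- tir[grepl("\\.tir5$", tir$id), ]
    right <- tir[grepl("\\.tir3$", tir$id), ]
    out$tir_left_start0 <- left$start0[match(out$element_id, left$parent)]
    out$tir_left_end0 <- left$end0[match(out$element_id, left$parent)]
    out$tir_right_start0 <- right$start0[match(out$element_id, right$parent)]
    out$tir_right_end0 <- right$end0[match(out$element_id, right$parent)]
  }
  tsd <- df %>% filter(.data$type == "target_site_duplication")
  if (nrow(tsd) > 0) {
    t5 <- tsd[grepl("\\.tsd5$", tsd$id), ]
    idx <- match(out$element_id, t5$parent)
    out$tsd_len <- (t5$end0 - t5$start0)[idx]
  }
  out
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write tab-separated report tables
#'
#' Thin wrappers over readr with fixed conventions (tab separator, header,
#' no progress output) used for truth tables, hit tables and reports.
#'
#' @param x a data frame.
#' @param path file path.
#' @return `write_tsv_report()` returns the path invisibly;
#'   `read_tsv_report()` returns a tibble.
#' @export
write_tsv_report <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
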