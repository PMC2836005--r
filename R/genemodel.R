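# Homology-guided CDS reconstruction across introns, protein motif/domain
# scanning, and conserved-intron comparison between gene models.

#' Default protein motif patterns
#'
#' Regular expressions for the diagnostic integrase motifs: YPYY
#' (`Y/F-P-Y/F-Y/F`), the H2C2 zinc finger (His2-Cys2 with flexible
#' spacers), the DDE catalytic triad (two aspartates and a glutamate with
#' configurable spacing windows), and the GPY/F multimerisation motif. The
#' spacing windows are stated approximations and fully user-overridable.
#'
#' @return named character vector of regular expressions.
#' @export
motif_patterns <- function() {
  c(
    YPYY = "[YF]P[YF][YF]",
    H2C2_ZF = "H[A-Z]{2,6}H[A-Z]{15,40}C[A-Z]{2,6}C",
    DDE = "D[A-Z]{50,130}?D[A-Z]{25,50}?E",
    GPYF = "GP[YF]"
  )
}

#' Default C-terminal domain patterns (OTU / Ulp1 / PHD)
#'
#' Catalytic-residue style regexes around the protease Cys-His dyads and the
#' PHD zinc-finger cysteine spacing; approximations, user-overridable (e.g.
#' with alignment-derived patterns).
#'
#' @return named character vector of regular expressions.
#' @export
cterm_patterns <- function() {
  c(
    OTU = "D[A-Z]{1,4}G[A-Z]C[A-Z]{25,80}H[A-Z]{2}[FY]",
    Ulp1 = "H[A-Z]{2,8}[DN][A-Z]{25,80}[QE][A-Z]C",
    PHD = "C[A-Z]{2}C[A-Z]{8,21}C[A-Z]{2,4}C[A-Z]{4,10}H[A-Z]{2}C[A-Z]{8,21}C[A-Z]{2}C"
  )
}

#' Scan a protein for integrase motifs
#'
#' Pattern scan with the (overridable) default motif regexes. GPY/F hits are
#' only reported from the C-terminal third of the integrase region.
#'
#' @param protein protein string.
#' @param patterns named regex vector (default [motif_patterns()]).
#' @param integrase_end 1-based residue index bounding the integrase region
#'   (defaults to the whole protein); used for the GPY/F location rule.
#' @return tibble of hits ordered by position: `motif`, `start`, `end`
#'   (1-based, inclusive), `match`.
#' @export
scan_motifs <- function(protein, patterns = motif_patterns(),
                        integrase_end = nchar(protein)) {
  if (nchar(protein) == 0) abort("empty protein")
  hits <- list()
  for (nm in names(patterns)) {
    m <- gregexpr(patterns[[nm]], protein, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      if (nm == "GPYF") {
        if (starts[k] < ceiling(2 * integrase_end / 3) ||
            starts[k] > integrase_end) next
      }
      hits[[length(hits) + 1L]] <- tibble(
        motif = nm, start = starts[k], end = starts[k] + lens[k] - 1L,
        match = substr(protein, starts[k], starts[k] + lens[k] - 1L))
    }
  }
  if (length(hits) == 0) {
    return(tibble(motif = character(0), start = integer(0), end = integer(0),
                  match = character(0)))
  }
  dplyr::bind_rows(hits) %>% arrange(.data$start, .data$motif)
}

#' Classify the C-terminal domain of a transposase
#'
#' Scans the protein after the integrase region with the OTU/Ulp1/PHD
#' patterns. OTU and Ulp1 are mutually exclusive in the output: if both
#' patterns somehow match, the leftmost match wins.
#'
#' @param protein protein string.
#' @param integrase_end 1-based residue index where the integrase region ends.
#' @param patterns named regex vector (default [cterm_patterns()]).
#' @return one of `"OTU"`, `"Ulp1"`, `"PHD+Ulp1"`, `"none"`.
#' @export
classify_cterm_domain <- function(protein, integrase_end,
                                  patterns = cterm_patterns()) {
  if (integrase_end >= nchar(protein)) return("none")
  tail_seq <- substr(protein, integrase_end + 1L, nchar(protein))
  pos <- vapply(patterns, function(p) {
    m <- regexpr(p, tail_seq, perl = TRUE)
    as.integer(m)
  }, integer(1))
  has <- pos > 0
  otu <- has["OTU"]; ulp <- has["Ulp1"]; phd <- has["PHD"]
  if (otu && ulp) { # resolve by leftmost match; never report both
    if (pos["OTU"] <= pos["Ulp1"]) { ulp <- FALSE } else { otu <- FALSE }
  }
  if (ulp && phd) return("PHD+Ulp1")
  if (ulp) return("Ulp1")
  if (otu) return("OTU")
  "none"
}

#' Homology-guided spliced gene reconstruction
#'
#' Finds the exon/intron structure in a genomic region that maximises the
#' protein alignment score of the spliced translation against a homologous
#' protein, subject to introns beginning with GT and ending with AG (GC-AG
#' donors and GT-TG acceptors admitted when `allow_noncanonical = TRUE`).
#' The alignment is global in the homolog and local in the region; intron
#' phases are computed from the cumulative coding length at each splice.
#'
#' @param genome genome (tibble, named string or plain string).
#' @param region `c(start0, end0)` bounds of the locus (0-based half-open).
#' @param homolog protein string of the homologous (guide) protein.
#' @param allow_noncanonical admit GC-AG and GT-TG splice pairs.
#' @param strand `"+"` or `"-"` (the region is reverse-complemented for `-`).
#' @param min_intron minimum intron length in bp.
#' @param min_score minimum alignment score for a model to be reported.
#' @param gap_protein,gap_codon,stop_penalty,intron_penalty DP penalties
#'   (positive magnitudes).
#' @return a `gene_model` list (`exons` 0-based half-open genomic matrix,
#'   `introns` tibble with donor/acceptor dinucleotides and phase, `protein`,
#'   `score`, `strand`) or `NULL` when no spliced alignment reaches
#'   `min_score`.
#' @export
reconstruct_cds <- function(genome, region, homolog, allow_noncanonical = FALSE,
                            strand = "+", min_intron = 20L, min_score = 50,
                            gap_protein = 8, gap_codon = 8, stop_penalty = 50,
                            intron_penalty = 10) {
  g <- as_genome(genome)
  s0 <- as.integer(region[1]); e0 <- as.integer(region[2])
  stopifnot(s0 >= 0, e0 <= nchar(g$seq), s0 < e0)
  seq <- substr(g$seq, s0 + 1L, e0)
  if (strand == "-") seq <- revcomp(seq)
  sm <- blosum62()
  alphabet <- paste(rownames(sm), collapse = "")
  r <- cpp_spliced_align(seq, homolog, alphabet, sm,
                         codon_table_for(alphabet), gap_protein, gap_codon,
                         stop_penalty, intron_penalty, min_intron,
                         allow_noncanonical)
  if (!is.finite(r$score) || r$score < min_score) return(NULL)
  ex <- r$exons # region-local 0-based half-open
  intr <- r$introns
  # map region-local to genomic forward-strand coordinates
  to_genomic <- function(m) {
    if (strand == "+") m + s0 else {
      n <- nchar(seq)
      cbind(s0 + n - m[, 2], s0 + n - m[, 1])
    }
  }
  exons_g <- to_genomic(ex)
  if (strand == "-") exons_g <- exons_g[rev(seq_len(nrow(exons_g))), , drop = FALSE]
  cds <- paste(vapply(seq_len(nrow(ex)), function(i) {
    substr(seq, ex[i, 1] + 1L, ex[i, 2])
  }, character(1)), collapse = "")
  protein <- translate_dna(cds)
  introns <- if (nrow(intr) > 0) {
    cum <- cumsum(ex[, 2] - ex[, 1])
    tibble(
      start0 = intr[, 1], end0 = intr[, 2],
      donor = substr(seq, intr[, 1] + 1L, intr[, 1] + 2L),
      acceptor = substr(seq, intr[, 2] - 1L, intr[, 2]),
      phase = as.integer(cum[seq_len(nrow(intr))] %% 3L)
    )
  } else {
    tibble(start0 = integer(0), end0 = integer(0), donor = character(0),
           acceptor = character(0), phase = integer(0))
  }
  if (nrow(introns) > 0) {
    gi <- to_genomic(as.matrix(introns[, c("start0", "end0")]))
    if (strand == "-") gi <- gi[rev(seq_len(nrow(gi))), , drop = FALSE]
    introns$genomic_start0 <- unname(gi[, 1])
    introns$genomic_end0 <- unname(gi[, 2])
  }
  structure(list(
    contig = g$id, strand = strand, score = r$score,
    exons = exons_g, introns = introns, protein = protein
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s(%s): %d exon(s), %d intron(s), %d aa, score %.1f\n",
              x$contig, x$strand, nrow(x$exons), nrow(x$introns),
              nchar(x$protein), x$score))
  invisible(x)
}

#' @export
tidy.gene_model <- function(x, ...) {
  ex <- tibble(type = "exon", start0 = x$exons[, 1], end0 = x$exons[, 2],
               phase = NA_integer_, donor = NA_character_,
               acceptor = NA_character_)
  if (nrow(x$introns) > 0) {
    intr <- tibble(type = "intron",
                   start0 = x$introns$genomic_start0 %||% x$introns$start0,
                   end0 = x$introns$genomic_end0 %||% x$introns$end0,
                   phase = x$introns$phase, donor = x$introns$donor,
                   acceptor = x$introns$acceptor)
    ex <- bind_rows(ex, intr)
  }
  arrange(ex, .data$start0)
}

#' Introns shared by all gene models at the same alignment position and phase
#'
#' Each intron is mapped to the multiple-alignment column of the last full
#' codon before its splice, paired with its phase; the returned descriptors
#' are those present in every model with identical (column, phase).
#'
#' @param models list of `gene_model` objects (or lists with `introns` and
#'   `protein`).
#' @param protein_msa named character vector of aligned proteins; every
#'   model's protein must appear (by name matching `names(models)`).
#' @return tibble with `column` (1-based MSA column) and `phase`.
#' @export
shared_introns <- function(models, protein_msa) {
  if (is.null(names(models)) || !all(names(models) %in% names(protein_msa))) {
    abort("every model must have a name present in the protein MSA")
  }
  descr <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    row <- protein_msa[[nm]]
    res_at <- cumsum(strsplit(row, "")[[1]] != "-")
    if (nrow(m$introns) == 0) return(character(0))
    # cumulative CDS length before each intron
    ex_len <- m$exons[, 2] - m$exons[, 1]
    cum <- cumsum(ex_len)
    vapply(seq_len(nrow(m$introns)), function(k) {
      off <- cum[k] # coding nt before intron k
      phase <- off %% 3L
      res <- off %/% 3L # last full codon index (1-based residue number)
      col <- if (res == 0) 0L else which(res_at == res)[1]
      paste0(col, "_", phase)
    }, character(1))
  })
  shared <- Reduce(intersect, descr)
  if (length(shared) == 0) {
    return(tibble(column = integer(0), phase = integer(0)))
  }
  parts <- do.call(rbind, strsplit(shared, "_"))
  tibble(column = as.integer(parts[, 1]), phase = as.integer(parts[, 2])) %>%
    arrange(.data$column)
}
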