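# Synthetic-genome generator: random background genomes with planted
# Ginger1/Ginger2-style elements (TIR-flanked, 4-bp TSDs, TGTNR termini,
# intron-bearing transposase ORFs) and a machine-readable truth set, so that
# every detection stage can be tested against known ground truth.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

aa_filler <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Synthetic transposase peptide carrying the diagnostic motif architecture
#'
#' Builds a synthetic Gypsy-integrase-like transposase: an integrase region
#' with (for Ginger1) the YPYY motif, an H2C2 zinc finger, the DDE catalytic
#' triad and a C-terminal GPY/F motif, followed by an optional protease /
#' chromatin-reader tail (OTU, Ulp1, or PHD+Ulp1). Ginger2-style peptides
#' carry H2C2 and DDE but lack YPYY and GPY/F. Random filler is resampled
#' until the peptide scans cleanly (exactly the intended motifs and tail).
#' These peptides are synthetic stand-ins; no natural sequence is bundled.
#'
#' @param group `"Ginger1"` or `"Ginger2"`.
#' @param cterm_domain one of `"OTU"`, `"Ulp1"`, `"PHD+Ulp1"`, `"none"`.
#' @param seed optional integer seed (otherwise uses the current RNG stream).
#' @return a protein string with attributes `integrase_end` (residue index of
#'   the end of the integrase region), `dde_start`/`dde_end` (DDE core
#'   bounds), `group` and `cterm_domain`.
#' @export
synthetic_tpase_peptide <- function(group = c("Ginger1", "Ginger2"),
                                    cterm_domain = c("OTU", "Ulp1", "PHD+Ulp1", "none"),
                                    seed = NULL) {
  group <- match.arg(group)
  cterm_domain <- match.arg(cterm_domain)
  build <- function() {
    for (try in 1:200) {
      h2c2 <- paste0("H", aa_filler(4), "H", aa_filler(22), "C", aa_filler(4), "C")
      dde <- paste0("D", aa_filler(90), "D", aa_filler(40), "E")
      if (group == "Ginger1") {
        pre <- paste0(aa_filler(60), "YPYY", aa_filler(15), h2c2, aa_filler(60))
        post <- paste0(aa_filler(55), "GPY", aa_filler(12))
      } else {
        pre <- paste0(aa_filler(60), aa_filler(15), h2c2, aa_filler(60))
        post <- aa_filler(40)
      }
      integrase <- paste0(pre, dde, post)
      tail <- switch(cterm_domain,
        OTU = paste0(aa_filler(12), "D", aa_filler(2), "G", aa_filler(1), "C",
                     aa_filler(40), "H", aa_filler(2), "F", aa_filler(12)),
        Ulp1 = paste0(aa_filler(12), "H", aa_filler(2), "D", aa_filler(30),
                      "E", aa_filler(1), "C", aa_filler(12)),
        `PHD+Ulp1` = paste0(
          aa_filler(6), "C", aa_filler(2), "C", aa_filler(10), "C", aa_filler(3),
          "C", aa_filler(6), "H", aa_filler(2), "C", aa_filler(10), "C",
          aa_filler(2), "C", aa_filler(8),
          "H", aa_filler(2), "D", aa_filler(30), "E", aa_filler(1), "C",
          aa_filler(10)),
        none = aa_filler(25)
      )
      pep <- paste0(integrase, tail)
      iend <- nchar(integrase)
      hits <- scan_motifs(pep, integrase_end = iend)
      has <- function(m) m %in% hits$motif
      ok <- has("H2C2_ZF") && has("DDE")
      if (group == "Ginger1") {
        ok <- ok && has("YPYY") && has("GPYF")
      } else {
        ok <- ok && !has("YPYY") && !has("GPYF")
      }
      ok <- ok && identical(classify_cterm_domain(pep, iend), cterm_domain)
      if (ok) {
        dde_start <- nchar(pre) + 1L
        attr(pep, "integrase_end") <- iend
        attr(pep, "dde_start") <- dde_start
        attr(pep, "dde_end") <- dde_start + nchar(dde) - 1L
        attr(pep, "group") <- group
        attr(pep, "cterm_domain") <- cterm_domain
        return(pep)
      }
    }
    abort("failed to build a clean synthetic peptide in 200 attempts")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Extract the DDE core of a synthetic transposase peptide
#'
#' @param peptide output of [synthetic_tpase_peptide()].
#' @return the DDE catalytic-core substring (the natural Tblastn-style query).
#' @export
dde_core <- function(peptide) {
  s <- attr(peptide, "dde_start"); e <- attr(peptide, "dde_end")
  if (is.null(s) || is.null(e)) abort("peptide has no recorded DDE core bounds")
  substr(peptide, s, e)
}

#' Synthetic reverse-transcriptase / RNase-H query panel
#'
#' Two fixed synthetic peptides standing in for RT and RNase H queries in the
#' 5-kb flank test that separates DNA-transposon vestiges from decayed LTR
#' retrotransposons. They carry no natural sequence; detection fixtures plant
#' their exact coding sequence.
#'
#' @return a named character vector of two protein strings.
#' @export
synthetic_rt_rnh_panel <- function() {
  with_seed(990017L, c(
    RT_synth = aa_filler(180),
    RNaseH_synth = aa_filler(130)
  ))
}

# Back-translate a peptide into a CDS, choosing synonymous codons at random.
backtranslate <- function(peptide, stop_codon = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  aas <- strsplit(peptide, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) abort(paste0("cannot back-translate residue ", a))
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  cds <- paste(codons, collapse = "")
  if (stop_codon) cds <- paste0(cds, sample(c("TAA", "TAG", "TGA"), 1))
  cds
}

#' Family specification for the generator
#'
#' Describes one transposon family to plant: group, geometry (total and TIR
#' length), terminal motif, transposase peptide, intron layout, and the
#' C-terminal domain of the transposase. Defaults follow a mid-sized Ginger1
#' family (3,064 bp, 126 bp TIRs, one intron, OTU tail).
#'
#' @param group `"Ginger1"` or `"Ginger2"`.
#' @param family_id label used in the truth set.
#' @param element_length total element length in bp (TIR to TIR inclusive).
#' @param tir_length TIR arm length in bp.
#' @param terminal_motif IUPAC 5-mer the element must start with (default
#'   `TGTNR`; the 3' end is its reverse complement).
#' @param tpase_peptide protein string (see [synthetic_tpase_peptide()]); if
#'   `NULL`, one is synthesised when the genome is simulated.
#' @param intron_offsets integer CDS offsets (nt, counted from the first
#'   coding base) after which a spliceosomal intron is inserted; the intron
#'   phase is `offset %% 3`.
#' @param intron_length intron length in bp (including splice dinucleotides).
#' @param cterm_domain C-terminal domain planted in the transposase.
#' @param noncanonical_introns if `TRUE` the first intron is planted with a
#'   GC-AG splice pair instead of GT-AG.
#' @return a `family_spec` list.
#' @export
family_spec <- function(group = c("Ginger1", "Ginger2"),
                        family_id = NULL,
                        element_length = 3064,
                        tir_length = 126,
                        terminal_motif = "TGTNR",
                        tpase_peptide = NULL,
                        intron_offsets = 361,
                        intron_length = 90,
                        cterm_domain = c("OTU", "Ulp1", "PHD+Ulp1", "none"),
                        noncanonical_introns = FALSE) {
  group <- match.arg(group)
  cterm_domain <- match.arg(cterm_domain)
  if (2 * tir_length >= element_length) {
    abort("invalid family spec: 2 * tir_length must be < element_length")
  }
  phases <- intron_offsets %% 3
  if (!all(phases %in% 0:2)) abort("intron phases must be 0, 1 or 2")
  structure(list(
    group = group,
    family_id = family_id %||% paste0(group, "-sim"),
    element_length = as.integer(element_length),
    tir_length = as.integer(tir_length),
    terminal_motif = terminal_motif,
    tpase_peptide = tpase_peptide,
    intron_offsets = as.integer(intron_offsets),
    intron_length = as.integer(intron_length),
    cterm_domain = cterm_domain,
    noncanonical_introns = noncanonical_introns
  ), class = "family_spec")
}

#' @rdname family_spec
#' @param ... passed on to [family_spec()].
#' @export
ginger1_family <- function(...) {
  args <- list(...)
  defaults <- list(group = "Ginger1", family_id = "Ginger1-sim",
                   element_length = 3064, tir_length = 126,
                   intron_offsets = 361, cterm_domain = "OTU")
  do.call(family_spec, utils::modifyList(defaults, args))
}

#' @rdname family_spec
#' @export
ginger2_family <- function(...) {
  args <- list(...)
  defaults <- list(group = "Ginger2", family_id = "Ginger2-sim",
                   element_length = 2815, tir_length = 112,
                   intron_offsets = integer(0), cterm_domain = "none")
  do.call(family_spec, utils::modifyList(defaults, args))
}

#' Simulation configuration
#'
#' @param genome_length background genome length in bp.
#' @param gc_content background GC fraction.
#' @param n_elements number of elements to plant.
#' @param family_specs list of [family_spec()] objects; elements are assigned
#'   to families uniformly at random.
#' @param tsd_profile categorical distribution over Ginger1 target 4-mers;
#'   the reserved name `other` draws a random 4-mer outside the named set.
#' @param ginger2_site_pattern IUPAC pattern of Ginger2 insertion sites; the
#'   central 4-mer of the matched site is duplicated.
#' @param copy_divergence per-site substitution probability applied to each
#'   planted copy (substitution-only; no indels).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param strand_randomize if `TRUE` each element is planted on a random
#'   strand (default: forward only).
#' @param n_decoys number of decoy inverted repeats (TIR-like arms with a
#'   random interior, no TSD bookkeeping) planted for detector stress tests.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(genome_length = 2e6,
                       gc_content = 0.5,
                       n_elements = 100,
                       family_specs = list(ginger1_family()),
                       tsd_profile = c(CCGG = 0.75, CCGT = 0.12, ACGG = 0.12, other = 0.01),
                       ginger2_site_pattern = "RTATAY",
                       copy_divergence = 0.01,
                       seed = 1L,
                       strand_randomize = FALSE,
                       n_decoys = 0L) {
  if (abs(sum(tsd_profile) - 1) > 1e-9) {
    abort("tsd_profile probabilities must sum to 1 (tolerance 1e-9)")
  }
  if (copy_divergence < 0 || copy_divergence > 1) abort("copy_divergence must be in [0, 1]")
  if (inherits(family_specs, "family_spec")) family_specs <- list(family_specs)
  max_len <- max(vapply(family_specs, function(s) s$element_length, numeric(1)))
  if (n_elements * (max_len + 12) >= genome_length) {
    abort(sprintf(
      "genome too small: %d elements x %d bp do not fit in %d bp",
      n_elements, as.integer(max_len), as.integer(genome_length)))
  }
  structure(list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    n_elements = as.integer(n_elements), family_specs = family_specs,
    tsd_profile = tsd_profile, ginger2_site_pattern = ginger2_site_pattern,
    copy_divergence = copy_divergence, seed = as.integer(seed),
    strand_randomize = strand_randomize, n_decoys = as.integer(n_decoys)
  ), class = "sim_config")
}

#' Substitution-only sequence mutation
#'
#' Each site is independently substituted with probability `rate`, choosing
#' uniformly among the three alternative bases. Length is preserved.
#'
#' @param seq nucleotide string.
#' @param rate per-site substitution probability in `[0, 1]`.
#' @param seed optional integer seed for a deterministic result.
#' @return the mutated string.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Build one element template for a family spec. Returns list(seq, tir_len,
# gene = list(cds_start0, exons (0-based half-open, element coords), introns
# tibble, peptide)).
build_element_template <- function(spec) {
  pep <- spec$tpase_peptide %||% synthetic_tpase_peptide(spec$group, spec$cterm_domain)
  tir5 <- paste0(iupac_exemplar(spec$terminal_motif),
                 random_dna(spec$tir_length - nchar(spec$terminal_motif)))
  cds <- backtranslate(pep, stop_codon = TRUE)
  offs <- sort(unique(spec$intron_offsets))
  offs <- offs[offs > 0 & offs < nchar(cds)]
  intr <- list()
  prev <- 0L
  gene_seq <- ""
  exon_bounds <- list() # within gene, 0-based half-open
  pos <- 0L
  for (k in seq_along(offs)) {
    ex <- substr(cds, prev + 1L, offs[k])
    donor <- if (spec$noncanonical_introns && k == 1L) "GC" else "GT"
    intron <- paste0(donor, random_dna(spec$intron_length - 4L), "AG")
    exon_bounds[[k]] <- c(pos, pos + nchar(ex))
    pos <- pos + nchar(ex)
    intr[[k]] <- tibble(
      start0 = pos, end0 = pos + nchar(intron),
      donor = donor, acceptor = "AG", phase = offs[k] %% 3L
    )
    pos <- pos + nchar(intron)
    gene_seq <- paste0(gene_seq, ex, intron)
    prev <- offs[k]
  }
  last_ex <- substr(cds, prev + 1L, nchar(cds))
  exon_bounds[[length(exon_bounds) + 1L]] <- c(pos, pos + nchar(last_ex))
  gene_seq <- paste0(gene_seq, last_ex)
  introns <- if (length(intr) > 0) dplyr::bind_rows(intr) else {
    tibble(start0 = integer(0), end0 = integer(0), donor = character(0),
           acceptor = character(0), phase = integer(0))
  }
  interior <- spec$element_length - 2L * spec$tir_length
  pad <- interior - nchar(gene_seq)
  if (pad < 20) {
    abort(sprintf("family '%s': element_length too small for its gene (%d bp short)",
                  spec$family_id, 20 - pad))
  }
  utr5 <- random_dna(ceiling(pad / 2))
  utr3 <- random_dna(floor(pad / 2))
  seq <- paste0(tir5, utr5, gene_seq, utr3, revcomp(tir5))
  gene_off <- spec$tir_length + nchar(utr5)
  exons <- do.call(rbind, exon_bounds) + gene_off
  introns$start0 <- introns$start0 + gene_off
  introns$end0 <- introns$end0 + gene_off
  list(seq = seq, tir_len = spec$tir_length, peptide = pep,
       gene = list(cds_start0 = gene_off, exons = exons, introns = introns,
                   peptide = as.character(pep)))
}

draw_tsd <- function(profile) {
  nm <- sample(names(profile), 1, prob = profile)
  if (nm != "other") return(nm)
  repeat {
    x <- random_dna(4)
    if (!(x %in% setdiff(names(profile), "other"))) return(x)
  }
}

#' Plant one element into a genome sequence
#'
#' For Ginger1-style insertions the target 4-mer at `site_index` is rewritten
#' to a draw from `tsd_profile` and duplicated on both flanks. For Ginger2
#' the site must match `site_pattern` (default `RTATAY`) and the central
#' 4-mer of the site is duplicated.
#'
#' @param genome a genome (tibble, named string or plain string).
#' @param spec a [family_spec()].
#' @param site_index 0-based position of the target site in the genome (for
#'   Ginger2, the start of the pattern match).
#' @param tsd_profile Ginger1 target-4-mer distribution.
#' @param site_pattern Ginger2 site pattern (IUPAC).
#' @param element_seq optional pre-built element sequence (otherwise a fresh
#'   template is constructed from `spec`).
#' @return a list with `genome` (one-row tibble) and `annotation` (one-row
#'   truth tibble with exact bounds, TSD and TIR length).
#' @export
plant_element <- function(genome, spec, site_index,
                          tsd_profile = c(CCGG = 0.75, CCGT = 0.12, ACGG = 0.12, other = 0.01),
                          site_pattern = "RTATAY",
                          element_seq = NULL) {
  g <- as_genome(genome)
  bg <- g$seq
  L <- nchar(bg)
  if (is.null(element_seq)) element_seq <- build_element_template(spec)$seq
  if (spec$group == "Ginger1") {
    if (site_index < 4 || site_index + 4 > L - 4) abort("site too close to the contig edge")
    tsd <- draw_tsd(tsd_profile)
    new_seq <- paste0(substr(bg, 1, site_index), tsd, element_seq, tsd,
                      substr(bg, site_index + 5L, L))
    start0 <- site_index + 4L
  } else {
    k <- nchar(site_pattern)
    site <- substr(bg, site_index + 1L, site_index + k)
    if (!matches_iupac(site, site_pattern)) {
      abort(sprintf("site at %d ('%s') does not match pattern %s",
                    site_index, site, site_pattern))
    }
    tsd <- substr(bg, site_index + 2L, site_index + 5L)
    new_seq <- paste0(substr(bg, 1, site_index + 5L), element_seq, tsd,
                      substr(bg, site_index + 6L, L))
    start0 <- site_index + 5L
  }
  end0 <- start0 + nchar(element_seq)
  ann <- tibble(
    element_id = "elem1", contig = g$id, start0 = start0, end0 = end0,
    strand = "+", family = spec$family_id, group = spec$group,
    tsd = tsd, tir_len = spec$tir_length
  )
  list(genome = tibble(id = g$id, desc = "", seq = new_seq), annotation = ann)
}

#' Simulate a genome with planted elements and a truth set
#'
#' Generates an i.i.d. background genome, builds one element template per
#' family, mutates each copy at `copy_divergence`, and inserts copies at
#' non-overlapping sites with proper 4-bp target-site duplications (rewritten
#' draws from `tsd_profile` for Ginger1; the central 4-mer of an RTATAY match
#' for Ginger2). Output is byte-identical for identical seeds.
#'
#' @param config a [sim_config()].
#' @return a `ginger_sim` list: `genome` (one-row tibble id/desc/seq),
#'   `truth` (per-element annotation tibble), `genes` (planted gene models
#'   for forward-strand copies: CDS start, exon matrix, intron table,
#'   peptide), `decoys`, and the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$genome_length
    bg <- random_dna(L, config$gc_content)
    specs <- config$family_specs
    # materialise peptides/templates once per family
    templates <- lapply(specs, build_element_template)
    fam_idx <- if (config$n_elements == 0) integer(0) else if (length(specs) == 1) {
      rep(1L, config$n_elements)
    } else {
      sample(seq_along(specs), config$n_elements, replace = TRUE)
    }
    is_g2 <- vapply(specs, function(s) s$group == "Ginger2", logical(1))
    n_g2 <- sum(is_g2[fam_idx])
    margin <- 200L
    min_gap <- 12L # background-coordinate separation between insertion points

    # Ginger2 sites: matches to the site pattern in the background
    g2_sites <- integer(0)
    if (n_g2 > 0) {
      rx <- iupac_regex(config$ginger2_site_pattern)
      m <- gregexpr(paste0("(?=", rx, ")"), bg, perl = TRUE)[[1]]
      pos <- as.integer(m) - 1L
      pos <- pos[pos > margin & pos < L - margin]
      if (length(pos) < n_g2) {
        abort(sprintf("only %d %s sites available for %d Ginger2 insertions",
                      length(pos), config$ginger2_site_pattern, n_g2))
      }
      pos <- sample(pos)
      keep <- integer(0)
      for (p in pos) {
        if (length(keep) == n_g2) break
        if (all(abs(keep - p) > min_gap)) keep <- c(keep, p)
      }
      if (length(keep) < n_g2) abort("could not place all Ginger2 insertions without overlap")
      g2_sites <- keep
    }
    # Ginger1 (and decoy) sites: anywhere, avoiding chosen sites
    n_g1 <- config$n_elements - n_g2
    n_pts <- n_g1 + config$n_decoys
    g1_sites <- integer(0)
    if (n_pts > 0) {
      taken <- g2_sites
      pool <- sample(seq.int(margin, L - margin), min(L, n_pts * 50L))
      for (p in pool) {
        if (length(g1_sites) == n_pts) break
        if (all(abs(c(taken, g1_sites) - p) > min_gap)) g1_sites <- c(g1_sites, p)
      }
      if (length(g1_sites) < n_pts) abort("could not place all insertions without overlap")
    }
    decoy_sites <- utils::tail(g1_sites, config$n_decoys)
    g1_sites <- utils::head(g1_sites, n_g1)

    # assemble the insertion schedule (background coordinates)
    sched <- tibble(
      site = c(g1_sites, g2_sites, decoy_sites),
      kind = c(rep("g1", n_g1), rep("g2", n_g2), rep("decoy", length(decoy_sites)))
    )
    fam_for <- integer(nrow(sched))
    fam_for[sched$kind == "g1"] <- fam_idx[!is_g2[fam_idx]]
    fam_for[sched$kind == "g2"] <- fam_idx[is_g2[fam_idx]]
    sched$fam <- fam_for
    sched <- sched[order(sched$site), ]

    pieces <- character(0)
    truth <- list()
    genes <- list()
    decoys <- list()
    cursor <- 0L # background position consumed so far (0-based)
    offset <- 0L # cumulative inserted length
    eid <- 0L
    for (r in seq_len(nrow(sched))) {
      p <- sched$site[r]
      kind <- sched$kind[r]
      if (kind == "decoy") {
        arm <- random_dna(80)
        dec <- paste0(arm, random_dna(400), revcomp(arm))
        pieces <- c(pieces, substr(bg, cursor + 1L, p), dec)
        decoys[[length(decoys) + 1L]] <- tibble(
          start0 = p + offset, end0 = p + offset + nchar(dec))
        cursor <- p
        offset <- offset + nchar(dec)
        next
      }
      eid <- eid + 1L
      spec <- specs[[sched$fam[r]]]
      tmpl <- templates[[sched$fam[r]]]
      elem <- mutate_sequence(tmpl$seq, config$copy_divergence)
      strand <- "+"
      if (config$strand_randomize && stats::runif(1) < 0.5) strand <- "-"
      planted <- if (strand == "+") elem else revcomp(elem)
      if (kind == "g1") {
        tsd <- draw_tsd(config$tsd_profile)
        pieces <- c(pieces, substr(bg, cursor + 1L, p), tsd, planted, tsd)
        start0 <- p + offset + 4L
        cursor <- p + 4L # the original 4-mer is rewritten (consumed)
        offset <- offset + nchar(planted) + 4L
      } else {
        tsd <- substr(bg, p + 2L, p + 5L)
        pieces <- c(pieces, substr(bg, cursor + 1L, p + 5L), planted, tsd)
        start0 <- p + 5L + offset
        cursor <- p + 5L
        offset <- offset + nchar(planted) + 4L
      }
      end0 <- start0 + nchar(planted)
      id <- sprintf("elem%04d", eid)
      truth[[eid]] <- tibble(
        element_id = id, contig = "chr1", start0 = start0, end0 = end0,
        strand = strand, family = spec$family_id, group = spec$group,
        tsd = tsd, tir_len = spec$tir_length
      )
      if (strand == "+") {
        gn <- tmpl$gene
        intr <- gn$introns
        intr$start0 <- intr$start0 + start0
        intr$end0 <- intr$end0 + start0
        genes[[length(genes) + 1L]] <- tibble(
          element_id = id,
          cds_start0 = start0 + gn$cds_start0,
          exons = list(gn$exons + start0),
          introns = list(intr),
          peptide = gn$peptide
        )
      }
    }
    pieces <- c(pieces, substr(bg, cursor + 1L, L))
    seq <- paste(pieces, collapse = "")
    empty_truth <- tibble(
      element_id = character(0), contig = character(0), start0 = integer(0),
      end0 = integer(0), strand = character(0), family = character(0),
      group = character(0), tsd = character(0), tir_len = integer(0))
    out <- list(
      genome = tibble(id = "chr1", desc = "gingerscan synthetic genome", seq = seq),
      truth = if (length(truth) > 0) dplyr::bind_rows(truth) else empty_truth,
      genes = if (length(genes) > 0) dplyr::bind_rows(genes) else NULL,
      decoys = if (length(decoys) > 0) dplyr::bind_rows(decoys) else NULL,
      templates = lapply(templates, function(t) t$seq),
      peptides = lapply(templates, function(t) t$peptide),
      config = config
    )
    class(out) <- "ginger_sim"
    out
  })
}

#' @export
print.ginger_sim <- function(x, ...) {
  cat(sprintf("<ginger_sim> %d bp genome, %d planted elements (%s), seed %d\n",
              nchar(x$genome$seq[[1]]), nrow(x$truth),
              paste(unique(x$truth$family), collapse = ", "),
              x$config$seed))
  invisible(x)
}

#' @export
tidy.ginger_sim <- function(x, ...) x$truth

#' @export
glance.ginger_sim <- function(x, ...) {
  tibble(
    genome_length = nchar(x$genome$seq[[1]]),
    n_elements = nrow(x$truth),
    n_families = length(x$config$family_specs),
    copy_divergence = x$config$copy_divergence,
    seed = x$config$seed
  )
}

#' Write a simulation to disk (FASTA + GFF3 + TSV truth table)
#'
#' @param sim a `ginger_sim` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  tr <- sim$truth
  tr$tsd_seq <- tr$tsd
  tr$tir_left_start0 <- tr$start0
  tr$tir_left_end0 <- tr$start0 + tr$tir_len
  tr$tir_right_start0 <- tr$end0 - tr$tir_len
  tr$tir_right_end0 <- tr$end0
  write_gff3(tr, file.path(dir, "truth.gff3"))
  write_tsv_report(
    sim$truth[, c("element_id", "start0", "end0", "family", "tsd", "tir_len")],
    file.path(dir, "truth.tsv"))
  write_fasta(setNames(unlist(sim$peptides),
                       vapply(sim$config$family_specs, function(s) s$family_id,
                              character(1))),
              file.path(dir, "tpase_peptides.faa"))
  invisible(dir)
}
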