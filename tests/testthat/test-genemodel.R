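test_that("motif scanning honours the degeneracies and invariant positions", {
  hits <- scan_motifs(paste0(strrep("A", 10), "YPYY", strrep("A", 10)))
  expect_true("YPYY" %in% hits$motif)
  expect_equal(hits$start[hits$motif == "YPYY"], 11)
  expect_true("YPYY" %in% scan_motifs(paste0(strrep("A", 10), "FPFF"))$motif)
  expect_false("YPYY" %in% scan_motifs(paste0(strrep("A", 10), "YAYY"))$motif)
})

test_that("motif scanning is position-equivariant", {
  withr::with_seed(71, {
    pep <- synthetic_tpase_peptide("Ginger1", "OTU")
    base <- scan_motifs(pep, patterns = motif_patterns()[c("YPYY", "H2C2_ZF", "DDE")])
    shifted <- scan_motifs(paste0(strrep("G", 7), pep),
                           patterns = motif_patterns()[c("YPYY", "H2C2_ZF", "DDE")])
    expect_equal(shifted$start, base$start + 7)
    expect_equal(shifted$motif, base$motif)
  })
})

test_that("C-terminal domain classification follows the decision table", {
  for (dom in c("OTU", "Ulp1", "PHD+Ulp1", "none")) {
    pep <- synthetic_tpase_peptide("Ginger1", dom, seed = 72 + match(dom, c("OTU", "Ulp1", "PHD+Ulp1", "none")))
    expect_equal(classify_cterm_domain(pep, attr(pep, "integrase_end")), dom)
  }
})

test_that("an intronless exact ORF gives a single-exon model equal to the homolog", {
  withr::with_seed(73, {
    pep <- random_protein(60)
    cds <- gingerscan:::backtranslate(pep, stop_codon = FALSE)
    region <- paste0(random_dna(150), cds, random_dna(150))
    gm <- reconstruct_cds(region, c(0, nchar(region)), pep)
    expect_equal(nrow(gm$exons), 1)
    expect_equal(nrow(gm$introns), 0)
    expect_identical(gm$protein, pep)
    expect_equal(unname(gm$exons[1, ]), c(150, 150 + nchar(cds)))
  })
})

test_that("planted GT-AG introns are recovered with exact bounds and phases", {
  withr::with_seed(74, {
    pep <- random_protein(80)
    fx <- gene_region_fixture(pep, offsets = c(50, 121)) # phases 2 and 1
    gm <- reconstruct_cds(fx$region, c(0, nchar(fx$region)), pep)
    expect_identical(gm$protein, pep)
    expect_equal(nrow(gm$introns), 2)
    expect_equal(gm$introns$start0, unname(fx$introns[, "start0"]))
    expect_equal(gm$introns$end0, unname(fx$introns[, "end0"]))
    expect_equal(gm$introns$phase, unname(fx$introns[, "phase"]))
    expect_true(all(gm$introns$donor == "GT" & gm$introns$acceptor == "AG"))
    # phases recomputed from exon lengths match the stored phases
    cum <- cumsum(gm$exons[, 2] - gm$exons[, 1])
    expect_equal(cum[seq_len(nrow(gm$introns))] %% 3, gm$introns$phase)
    # the spliced CDS is a whole number of codons
    expect_equal(sum(gm$exons[, 2] - gm$exons[, 1]) %% 3, 0)
  })
})

test_that("GC-AG introns are admitted only with allow_noncanonical", {
  withr::with_seed(75, {
    pep <- random_protein(70)
    fx <- gene_region_fixture(pep, offsets = 100, donors = "GC")
    with_flag <- reconstruct_cds(fx$region, c(0, nchar(fx$region)), pep,
                                 allow_noncanonical = TRUE)
    expect_equal(with_flag$introns$donor, "GC")
    expect_identical(with_flag$protein, pep)
    without <- reconstruct_cds(fx$region, c(0, nchar(fx$region)), pep,
                               allow_noncanonical = FALSE)
    expect_false(!is.null(without) && identical(without$protein, pep) &&
                   nrow(without$introns) == 1)
  })
})

test_that("minus-strand gene models are reconstructed in forward coordinates", {
  withr::with_seed(76, {
    pep <- random_protein(60)
    fx <- gene_region_fixture(pep, offsets = 64)
    rc <- revcomp(fx$region)
    gm <- reconstruct_cds(rc, c(0, nchar(rc)), pep, strand = "-")
    expect_identical(gm$protein, pep)
    expect_equal(nrow(gm$introns), 1)
  })
})

test_that("generator-planted intron structure is recovered from the genome", {
  sim <- small_sim()
  gn <- sim$genes[1, ]
  t <- sim$truth[sim$truth$element_id == gn$element_id, ]
  gm <- reconstruct_cds(sim$genome, c(t$start0, t$end0), sim$genes$peptide[1])
  expect_identical(gm$protein, gn$peptide)
  planted <- gn$introns[[1]]
  expect_equal(unname(gm$introns$genomic_start0), planted$start0)
  expect_equal(unname(gm$introns$genomic_end0), planted$end0)
  expect_equal(gm$introns$phase, planted$phase)
})

test_that("shared introns require identical alignment position and phase", {
  withr::with_seed(77, {
    pep <- random_protein(120)
    shared_offs <- c(31, 62, 100) # phases 1, 2, 1
    mk <- function(extra) {
      fx <- gene_region_fixture(pep, offsets = c(shared_offs, extra))
      reconstruct_cds(fx$region, c(0, nchar(fx$region)), pep)
    }
    models <- list(tpase = mk(150), gin1 = mk(c(45, 80)), gin2 = mk(integer(0)),
                   host = mk(17))
    msa <- setNames(rep(pep, 4), names(models))
    sh <- shared_introns(models, msa)
    expect_equal(nrow(sh), 3)
    expect_equal(sh$phase, c(1L, 2L, 1L))

    # identical models share their full intron set
    two <- list(a = models$gin2, b = models$gin2)
    expect_equal(nrow(shared_introns(two, setNames(rep(pep, 2), c("a", "b")))), 3)

    # same position but different phase is excluded
    fx_a <- gene_region_fixture(pep, offsets = 60) # phase 0
    fx_b <- gene_region_fixture(pep, offsets = 61) # phase 1, same codon
    ma <- reconstruct_cds(fx_a$region, c(0, nchar(fx_a$region)), pep)
    mb <- reconstruct_cds(fx_b$region, c(0, nchar(fx_b$region)), pep)
    expect_equal(nrow(shared_introns(list(a = ma, b = mb),
                                     setNames(rep(pep, 2), c("a", "b")))), 0)
    expect_error(shared_introns(list(z = ma), c(other = pep)), "MSA")
  })
})
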