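test_that("a homopolymer has no inverted repeat", {
  expect_equal(nrow(find_tirs(strrep("A", 200))), 0)
})

test_that("a planted perfect 100-bp TIR is recovered exactly", {
  withr::with_seed(51, {
    arm <- random_dna(100)
    # AAAA walls make the planted arm the maximal inverted repeat: the
    # interior cannot extend the arms by chance pairing
    seq <- paste0(arm, "AAAA", random_dna(792), "AAAA", revcomp(arm))
    r <- find_tirs(seq, min_len = 40, max_len = 300)
    expect_equal(nrow(r), 1)
    expect_equal(r$left_start0, 0)
    expect_equal(r$left_end0, 100)
    expect_equal(r$right_start0, 900)
    expect_equal(r$right_end0, 1000)
    expect_equal(r$arm_length, 100)
    expect_equal(r$arm_identity, 1)
  })
})

test_that("arms longer than max_len are reported in full and flagged", {
  withr::with_seed(52, {
    arm <- random_dna(270)
    seq <- paste0(arm, "AAAA", random_dna(2792), "AAAA", revcomp(arm))
    ok <- find_tirs(seq, min_len = 40, max_len = 270)
    expect_false(ok$flagged)
    expect_gte(ok$arm_length, 270)
    fl <- find_tirs(seq, min_len = 40, max_len = 100)
    if (nrow(fl) > 0) expect_true(fl$flagged) # full arm reported, flagged
  })
})

test_that("find_tirs is mirror-symmetric under reverse complement", {
  withr::with_seed(53, {
    arm <- random_dna(80)
    seq <- paste0(arm, "AAAA", random_dna(592), "AAAA", revcomp(arm))
    a <- find_tirs(seq)
    b <- find_tirs(revcomp(seq))
    n <- nchar(seq)
    expect_equal(b$left_start0, n - a$right_end0)
    expect_equal(b$left_end0, n - a$right_start0)
    expect_equal(b$right_start0, n - a$left_end0)
    expect_equal(b$right_end0, n - a$left_start0)
  })
})

test_that("TSD extraction returns the longest duplicated flank k-mer", {
  g <- paste0(strrep("G", 20), "AAAA", strrep("C", 30), "TTTT", strrep("G", 20))
  expect_null(extract_tsd(g, 24L, 54L)) # AAAA vs TTTT
  g2 <- paste0(strrep("G", 20), "CCGG", strrep("A", 30), "CCGG", strrep("G", 20))
  r <- extract_tsd(g2, 24L, 54L)
  expect_equal(r$length, 4)
  expect_equal(r$sequence, "CCGG")
  # ...ATATA[elem]ATATA... -> length 5, not 4
  g3 <- paste0(strrep("G", 20), "ATATA", strrep("C", 30), "ATATA", strrep("G", 20))
  r3 <- extract_tsd(g3, 25L, 55L)
  expect_equal(r3$length, 5)
  expect_equal(r3$sequence, "ATATA")
  expect_error(extract_tsd(g, 2L, 30L), "contig edge")
})

test_that("TSD extraction agrees with an exhaustive-k oracle on random cases", {
  withr::with_seed(55, {
    for (i in 1:50) {
      g <- random_dna(60)
      s0 <- 20L; e0 <- 40L
      r <- extract_tsd(g, s0, e0)
      want <- tsd_oracle(g, s0, e0)
      if (is.null(want)) expect_null(r) else expect_equal(r$length, want)
    }
  })
})

test_that("terminal motif checks follow the IUPAC pattern and its reverse complement", {
  expect_equal(check_terminal_motif(paste0("TGTAA", strrep("C", 20), "TTACA")),
               c(five_prime = TRUE, three_prime = TRUE))
  expect_false(check_terminal_motif(paste0("AAAAA", strrep("C", 20)))[["five_prime"]])
  expect_true(check_terminal_motif(paste0("TGTCG", strrep("C", 20)))[["five_prime"]])
})

test_that("boundary refinement recovers planted elements exactly at zero divergence", {
  sim <- small_sim()
  panel <- c(G1 = dde_core(sim$peptides[[1]]))
  hits <- scan_for_tpase(sim$genome, panel, min_score = 60)
  expect_equal(nrow(hits), nrow(sim$truth))
  anns <- dplyr::bind_rows(lapply(seq_len(nrow(hits)), function(i) {
    refine_boundaries(sim$genome, hits[i, ])
  }))
  expect_equal(anns$start0, sim$truth$start0)
  expect_equal(anns$end0, sim$truth$end0)
  expect_true(all(anns$tsd_seq == sim$truth$tsd))
  expect_true(all(anns$tsd_len == 4))
  expect_true(all(anns$motif_5p & anns$motif_3p))
})

test_that("a transposase hit with no surrounding TIR yields no TIR-delimited element", {
  withr::with_seed(57, {
    pep <- synthetic_tpase_peptide("Ginger2", "none")
    cds <- gingerscan:::backtranslate(pep)
    genome <- paste0(random_dna(12000), cds, random_dna(12000))
    hits <- scan_for_tpase(genome, c(q = dde_core(pep)), min_score = 60)
    ann <- refine_boundaries(genome, hits[1, ])
    expect_true(is.null(ann) || is.na(ann$arm_length))
  })
})
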