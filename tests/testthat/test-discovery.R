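test_that("six-frame translation follows the standard code", {
  expect_equal(six_frame_translate("ATGGCC")[["+1"]], "MA")
  expect_equal(six_frame_translate("TTA")[["-1"]], "*")
  expect_equal(six_frame_translate("ATGGCCA")[["+2"]], "WP") # TGG CCA
})

test_that("frame +1 equals frame -1 of the reverse complement", {
  withr::with_seed(21, {
    for (i in 1:5) {
      s <- random_dna(300)
      expect_identical(six_frame_translate(s)[["+1"]],
                       six_frame_translate(revcomp(s))[["-1"]])
    }
  })
})

test_that("Smith-Waterman matches an independent DP oracle and Biostrings", {
  b62 <- gingerscan:::blosum62()
  r <- smith_waterman("HEAGAWGHEE", "PAWHEAE")
  expect_equal(r$score, sw_oracle_score("HEAGAWGHEE", "PAWHEAE", b62, 11, 1))
  withr::with_seed(31, {
    for (i in 1:20) {
      q <- random_protein(sample(4:12, 1))
      t <- random_protein(sample(4:12, 1))
      expect_equal(smith_waterman(q, t)$score,
                   sw_oracle_score(q, t, b62, 11, 1))
    }
  })
  skip_if_not_installed("Biostrings")
  withr::with_seed(32, {
    for (i in 1:10) {
      q <- random_protein(30)
      t <- random_protein(25)
      mine <- smith_waterman(q, t)$score
      ref <- Biostrings::pairwiseAlignment(
        q, t, substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
        type = "local", scoreOnly = TRUE)
      expect_equal(mine, ref)
    }
  })
})

test_that("self-alignment under a diagonal matrix scores 4 x length", {
  ab <- "ACDEFG"
  mat <- matrix(-1, 6, 6, dimnames = list(strsplit(ab, "")[[1]],
                                          strsplit(ab, "")[[1]]))
  diag(mat) <- 4
  r <- smith_waterman("ACDEFG", "ACDEFG", matrix = mat)
  expect_equal(r$score, 4 * 6)
  expect_equal(r$identity, 1)
})

test_that("disjoint alphabets with all-negative scores give the local floor", {
  ab <- c("A", "C", "W", "Y")
  mat <- matrix(-2, 4, 4, dimnames = list(ab, ab))
  r <- smith_waterman("AAAA", "WWWW", matrix = mat)
  expect_equal(r$score, 0)
  expect_equal(r$query_aln, "")
})

test_that("unknown residues raise an explicit error", {
  expect_error(smith_waterman("ACDE", "AC1E"), "unknown residue")
})

test_that("an exactly encoded panel peptide is found with identity 1 at its CDS", {
  withr::with_seed(41, {
    pep <- random_protein(120)
    cds <- gingerscan:::backtranslate(pep, stop_codon = FALSE)
    genome <- paste0(random_dna(3000), cds, random_dna(3000))
    hits <- scan_for_tpase(genome, c(q = pep), min_score = 60)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$identity, 1)
    expect_equal(hits$start0, 3000)
    expect_equal(hits$end0, 3000 + nchar(cds))
    expect_gt(hits$frame, 0)

    # minus-strand planting: same forward coordinates, negative frame
    genome_rc <- revcomp(genome)
    hits_rc <- scan_for_tpase(genome_rc, c(q = pep), min_score = 60)
    expect_equal(nrow(hits_rc), 1)
    expect_lt(hits_rc$frame, 0)
    L <- nchar(genome)
    expect_equal(hits_rc$start0, L - hits$end0)
    expect_equal(hits_rc$end0, L - hits$start0)
  })
})

test_that("a random genome with a stringent threshold yields no hits", {
  withr::with_seed(43, {
    genome <- random_dna(20000)
    hits <- scan_for_tpase(genome, c(q = random_protein(150)), min_score = 120)
    expect_equal(nrow(hits), 0)
  })
})
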