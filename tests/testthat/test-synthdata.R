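test_that("simulation is byte-identical for identical seeds", {
  cfg <- sim_config(genome_length = 5e4, n_elements = 2, seed = 1)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
})

test_that("n_elements = 0 gives a background genome and empty truth set", {
  sim <- simulate_genome(sim_config(genome_length = 2e4, n_elements = 0, seed = 2))
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nchar(sim$genome$seq), 2e4)
})

test_that("a genome too small for the requested elements is rejected", {
  expect_error(sim_config(genome_length = 5e3, n_elements = 10),
               "genome too small")
  expect_error(sim_config(tsd_profile = c(CCGG = 0.8, CCGT = 0.1)),
               "sum to 1")
})

test_that("every planted element has a duplicated flanking 4-mer and TGTNR termini", {
  sim <- small_sim()
  g <- sim$genome$seq
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    left <- substr(g, t$start0 - 3, t$start0)
    right <- substr(g, t$end0 + 1, t$end0 + 4)
    expect_identical(left, right)
    expect_identical(left, t$tsd)
    elem <- substr(g, t$start0 + 1, t$end0)
    mot <- check_terminal_motif(elem)
    expect_true(mot[["five_prime"]])
    expect_true(mot[["three_prime"]])
  }
})

test_that("zero-divergence copies are recoverable by exact string search", {
  sim <- small_sim()
  hits <- gregexpr(sim$templates[[1]], sim$genome$seq, fixed = TRUE)[[1]]
  expect_equal(length(hits), nrow(sim$truth))
  expect_equal(as.integer(hits) - 1L, sim$truth$start0)
})

test_that("empirical TSD draws follow the configured profile (chi-square, n = 1000)", {
  profile <- c(CCGG = 0.75, CCGT = 0.12, ACGG = 0.12, other = 0.01)
  draws <- withr::with_seed(99, {
    vapply(1:1000, function(i) gingerscan:::draw_tsd(profile), character(1))
  })
  cat_counts <- c(
    CCGG = sum(draws == "CCGG"), CCGT = sum(draws == "CCGT"),
    ACGG = sum(draws == "ACGG"),
    other = sum(!draws %in% c("CCGG", "CCGT", "ACGG")))
  p <- stats::chisq.test(cat_counts, p = profile)$p.value
  expect_gt(p, 0.01)
})

test_that("Ginger1 TSD composition matches the generator profile at n = 200", {
  sim <- simulate_genome(sim_config(genome_length = 4e6, n_elements = 200, seed = 2))
  frac <- mean(sim$truth$tsd == "CCGG")
  sd3 <- 3 * sqrt(0.75 * 0.25 / 200)
  expect_lt(abs(frac - 0.75), sd3)
})

test_that("plant_element constructs a valid Ginger1 insertion", {
  bg <- withr::with_seed(5, random_dna(2e4))
  spec <- ginger1_family()
  res <- withr::with_seed(6, plant_element(bg, spec, 9000L))
  g <- res$genome$seq
  a <- res$annotation
  expect_identical(substr(g, a$start0 - 3, a$start0),
                   substr(g, a$end0 + 1, a$end0 + 4))
  elem <- substr(g, a$start0 + 1, a$end0)
  expect_match(substr(elem, 1, 5), "^TGT[ACGT][AG]$")
})

test_that("plant_element at an RTATAY site duplicates a 4-mer from the site", {
  bg <- withr::with_seed(8, {
    paste0(random_dna(5000), "ATATAT", random_dna(5000))
  })
  spec <- ginger2_family()
  res <- plant_element(bg, spec, 5000L, site_pattern = "RTATAY",
                       element_seq = withr::with_seed(9, {
                         gingerscan:::build_element_template(spec)$seq
                       }))
  a <- res$annotation
  expect_equal(a$tsd, "TATA")
  g <- res$genome$seq
  expect_identical(substr(g, a$start0 - 3, a$start0),
                   substr(g, a$end0 + 1, a$end0 + 4))
  # a non-matching site is rejected
  expect_error(plant_element(bg, spec, 10L, site_pattern = "RTATAY"),
               "does not match")
})

test_that("mutate_sequence follows its substitution model", {
  s <- withr::with_seed(1, random_dna(10000))
  expect_identical(mutate_sequence(s, 0), s)
  m1 <- mutate_sequence(s, 1, seed = 2)
  expect_false(any(strsplit(m1, "")[[1]] == strsplit(s, "")[[1]]))
  m <- mutate_sequence(s, 0.005, seed = 3)
  frac <- mean(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  expect_lt(abs(frac - 0.005), 3 * sqrt(0.005 * 0.995 / 10000))
  expect_identical(mutate_sequence(s, 0.01, seed = 7),
                   mutate_sequence(s, 0.01, seed = 7))
})

test_that("synthetic peptides carry exactly the intended motif architecture", {
  p1 <- synthetic_tpase_peptide("Ginger1", "OTU", seed = 11)
  h1 <- scan_motifs(p1, integrase_end = attr(p1, "integrase_end"))
  expect_true(all(c("YPYY", "H2C2_ZF", "DDE", "GPYF") %in% h1$motif))
  expect_equal(classify_cterm_domain(p1, attr(p1, "integrase_end")), "OTU")
  p2 <- synthetic_tpase_peptide("Ginger2", "none", seed = 12)
  h2 <- scan_motifs(p2, integrase_end = attr(p2, "integrase_end"))
  expect_false(any(c("YPYY", "GPYF") %in% h2$motif))
  expect_true(all(c("H2C2_ZF", "DDE") %in% h2$motif))
})
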