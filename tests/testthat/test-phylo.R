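test_that("progressive alignment handles identical and gapped cases", {
  al <- progressive_align(c(a = "ACDEFG", b = "ACDEFG"))
  expect_identical(unname(al), c("ACDEFG", "ACDEFG"))
  al2 <- progressive_align(c(a = "ACDE", b = "ACE"))
  expect_equal(nchar(al2[[1]]), nchar(al2[[2]]))
  expect_gte(nchar(al2[[1]]), 4) # columns >= longest input
  # pairwise case equals the global DP oracle score
  b62 <- gingerscan:::blosum62()
  r <- gingerscan:::cpp_align("ACDE", "ACE", paste(rownames(b62), collapse = ""),
                              b62, 0, 8, FALSE)
  expect_equal(r$score, nw_oracle_score("ACDE", "ACE", b62, 0, 8))
  withr::with_seed(101, {
    msa <- progressive_align(setNames(replicate(4, random_protein(40)), letters[1:4]))
    expect_equal(length(unique(nchar(msa))), 1)
    expect_gte(nchar(msa[[1]]), 40)
  })
})

test_that("distance corrections match their closed forms", {
  msa <- c(a = strrep("A", 100), b = paste0(strrep("A", 50), strrep("C", 50)))
  expect_equal(unname(seq_distance(msa, model = "p")[1]), 0.5)
  expect_equal(unname(seq_distance(msa, model = "poisson")[1]), -log(0.5))
  expect_equal(unname(seq_distance(msa, model = "gamma", gamma_a = 2)[1]),
               2 * (sqrt(2) - 1))
  same <- c(a = "ACDEF", b = "ACDEF")
  for (mod in c("p", "poisson", "gamma")) {
    expect_equal(unname(seq_distance(same, model = mod)[1]), 0)
  }
  sat <- c(a = "AAAA", b = "CCCC")
  expect_error(seq_distance(sat, model = "poisson"), "undefined")
  expect_error(seq_distance(sat, model = "gamma"), "undefined")
})

test_that("pairwise deletion drops only the columns gapped within each pair", {
  msa <- c(a = "ACGTACGT", b = "ACGTACGA", c = "ACGT--GT")
  dp <- as.matrix(seq_distance(msa, model = "p", deletion = "pairwise"))
  dc <- as.matrix(seq_distance(msa, model = "p", deletion = "complete"))
  expect_equal(dp["a", "b"], 1 / 8) # full 8 columns compared
  expect_equal(dc["a", "b"], 1 / 6) # gap columns removed for everyone
  expect_equal(dp["a", "c"], 0)
})

test_that("Poisson and gamma corrections are consistent and ordered", {
  for (p in c(0.05, 0.2, 0.5, 0.8)) {
    d <- -log(1 - p)
    expect_equal(1 - exp(-d), p, tolerance = 1e-12)
    g2 <- 2 * ((1 - p)^(-1 / 2) - 1)
    expect_gte(g2, d)
    expect_gte(d, p)
    ghuge <- 1e4 * ((1 - p)^(-1 / 1e4) - 1)
    expect_lt(abs(ghuge - d) / d, 1e-3) # gamma -> Poisson as a -> Inf
  }
})

test_that("NJ reconstructs additive matrices exactly", {
  dm <- matrix(c(0, 3, 6, 5, 3, 0, 7, 6, 6, 7, 0, 3, 5, 6, 3, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(stats::as.dist(dm))
  pd <- stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_lt(max(abs(pd - dm)), 1e-9)
  # ((A,B),(C,D)) topology: A and B are siblings
  expect_equal(suppressMessages(phangorn::RF.dist(
    tr, ape::read.tree(text = "((A,B),(C,D));"))), 0)
  withr::with_seed(111, {
    for (n in c(5, 8)) {
      gen <- random_additive_dm(n)
      tr2 <- nj_tree(stats::as.dist(gen$dm))
      pd2 <- stats::cophenetic(tr2)[rownames(gen$dm), rownames(gen$dm)]
      expect_lt(max(abs(pd2 - gen$dm)), 1e-8)
    }
  })
  expect_error(nj_tree(stats::as.dist(matrix(c(0, 1, 1, 0), 2))), "3 taxa")
})

test_that("three taxa resolve by the closed three-point formulas", {
  d3 <- stats::as.dist(matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
                              dimnames = list(letters[1:3], letters[1:3])))
  tr <- nj_tree(d3)
  pd <- stats::cophenetic(tr)[letters[1:3], letters[1:3]]
  expect_lt(max(abs(pd - as.matrix(d3))), 1e-9)
})

test_that("NJ agrees with UPGMA on ultrametric matrices", {
  withr::with_seed(112, {
    tr0 <- ape::rcoal(6) # ultrametric by construction
    dm <- stats::cophenetic(tr0)
    nj <- nj_tree(stats::as.dist(dm))
    up <- phangorn::upgma(stats::as.dist(dm))
    expect_equal(suppressMessages(phangorn::RF.dist(nj, up)), 0)
  })
})

test_that("minimum evolution recovers additive trees and never beats itself", {
  withr::with_seed(113, {
    gen <- random_additive_dm(6)
    me <- me_tree(stats::as.dist(gen$dm))
    expect_equal(suppressMessages(phangorn::RF.dist(me, gen$tree)), 0)
    expect_equal(sum(me$edge.length), sum(gen$tree$edge.length), tolerance = 1e-6)
    # fixed point: restarting from the optimum returns the same topology
    me2 <- me_tree(stats::as.dist(gen$dm), start = me)
    expect_equal(suppressMessages(phangorn::RF.dist(me, me2)), 0)
    # perturbed 5-taxon matrix: ME total length <= NJ total length
    gen5 <- random_additive_dm(5)
    noisy <- gen5$dm + matrix(stats::runif(25, 0, 0.3), 5) * upper.tri(gen5$dm)
    noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
    nj <- nj_tree(stats::as.dist(noisy))
    njfit <- phangorn::nnls.tree(noisy, nj, method = "unrooted")
    me5 <- me_tree(stats::as.dist(noisy))
    expect_lte(sum(me5$edge.length), sum(pmax(njfit$edge.length, 0)) + 1e-9)
  })
})

test_that("bootstrap supports are deterministic, bounded and signal-consistent", {
  msa <- c(a = strrep("AC", 30), b = strrep("AC", 30),
           c = paste0(strrep("GC", 25), strrep("AC", 5)),
           d = paste0(strrep("GC", 25), strrep("AT", 5)))
  bt <- bootstrap_tree(msa, n_reps = 100, seed = 4)
  sup <- as.integer(bt$node.label[nzchar(bt$node.label)])
  expect_true(all(sup >= 0 & sup <= 100))
  # the (a,b) | (c,d) split is supported by every column
  expect_true(100 %in% sup)
  bt2 <- bootstrap_tree(msa, n_reps = 100, seed = 4)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
  expect_error(bootstrap_tree(msa, n_reps = 0), "n_reps")
})

test_that("Newick output round-trips topology and branch lengths", {
  withr::with_seed(114, {
    for (i in 1:5) {
      tr <- ape::rtree(sample(4:9, 1))
      f <- withr::local_tempfile(fileext = ".nwk")
      write_newick(tr, f)
      txt <- readLines(f)
      expect_length(txt, 1)
      expect_match(txt, ";$")
      back <- read_newick(f)
      expect_equal(suppressMessages(phangorn::RF.dist(ape::unroot(tr),
                                                      ape::unroot(back))), 0)
      expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
    }
  })
})
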