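test_that("FASTA parsing normalises case and splits id from description", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some description", "acgt", "ACGT", ">y", "NNRY"), f)
  r <- read_fasta(f)
  expect_equal(r$id, c("x", "y"))
  expect_equal(r$desc[1], "some description")
  expect_equal(r$seq, c("ACGTACGT", "NNRY"))
})

test_that("FASTA parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty FASTA")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate record id 'a' \\(line 3\\)")
  writeLines(c(">a", "ACGT", "AC1T"), f)
  expect_error(read_fasta(f), "non-IUPAC character on line 3")
})

test_that("write_fasta then read_fasta is identity on sequence content", {
  seqs <- c(alpha = "ACGTACGTACGT", beta = strrep("ACGTT", 40))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 60)
  r <- read_fasta(f)
  expect_identical(setNames(r$seq, r$id), seqs)
})

test_that("GFF3 output uses 1-based inclusive coordinates and round-trips", {
  ann <- tibble::tibble(
    element_id = c("e2", "e1"), contig = "chr1",
    start0 = c(200L, 10L), end0 = c(400L, 20L), strand = c("-", "+"),
    family = "fam", label = c("Ginger2", "Ginger1"),
    tir_left_start0 = c(200L, 10L), tir_left_end0 = c(240L, 13L),
    tir_right_start0 = c(360L, 17L), tir_right_end0 = c(400L, 20L),
    tsd_seq = c(NA, "CCGG"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(first[4]), 11) # start0 10 -> GFF start 11
  expect_equal(as.integer(first[5]), 20)
  # minus-strand feature keeps start <= end with strand column "-"
  minus <- strsplit(grep("e2", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(minus[7], "-")
  expect_lt(as.integer(minus[4]), as.integer(minus[5]))
  back <- read_gff3(f)
  back <- back[match(ann$element_id, back$element_id), ]
  expect_equal(back$start0, ann$start0)
  expect_equal(back$end0, ann$end0)
  expect_equal(back$tir_left_start0, ann$tir_left_start0)
  # second write is byte-identical (coordinate round-trip identity)
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(back, f2)
  keep <- function(x) grep("transposable_element|terminal_inverted", x, value = TRUE)
  expect_identical(keep(readLines(f)), keep(readLines(f2)))
})

test_that("written GFF3 is accepted by an independent parser", {
  skip_if_not_installed("rtracklayer")
  ann <- tibble::tibble(element_id = "e1", contig = "chr1", start0 = 10L,
                        end0 = 20L, strand = "+")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  gr <- rtracklayer::import(f)
  expect_equal(as.integer(GenomicRanges::start(gr)), 11L)
  expect_equal(as.integer(GenomicRanges::end(gr)), 20L)
})

test_that("an empty annotation list yields a valid header-only file", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tibble::tibble(element_id = character(0), contig = character(0),
                            start0 = integer(0), end0 = integer(0),
                            strand = character(0)), f)
  expect_identical(readLines(f), "##gff-version 3")
  expect_equal(nrow(read_gff3(f)), 0)
})
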