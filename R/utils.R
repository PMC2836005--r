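# Sequence utilities shared across modules. All internal coordinates are
# 0-based half-open; conversion to 1-based happens only at file boundaries.

IUPAC_NT <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

AMBIGUITY_CODE <- setNames(names(IUPAC_NT), IUPAC_NT)

DNA_ALPHABET <- "ACGTN"

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`; IUPAC ambiguity codes are complemented correctly.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random nucleotide sequence with given GC content
#'
#' @param n length in bp.
#' @param gc_content fraction of G+C in `[0, 1]`.
#' @return a single string of length `n`.
#' @export
random_dna <- function(n, gc_content = 0.5) {
  stopifnot(n >= 0, gc_content >= 0, gc_content <= 1)
  if (n == 0) return("")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2, (1 - gc_content) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Convert an IUPAC nucleotide motif to a regular expression.
iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_NT))
  if (length(bad) > 0) abort(paste0("not an IUPAC nucleotide motif: ", motif))
  paste0(vapply(chars, function(ch) {
    opts <- IUPAC_NT[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

# Does `seq` match IUPAC `motif` starting at 1-based position `at`?
matches_iupac <- function(seq, motif, at = 1L) {
  k <- nchar(motif)
  if (at < 1 || at + k - 1 > nchar(seq)) return(FALSE)
  grepl(paste0("^", iupac_regex(motif)), substr(seq, at, at + k - 1))
}

# Draw one concrete sequence matching an IUPAC motif.
iupac_exemplar <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(IUPAC_NT[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# Run code with a temporary RNG seed (restores the caller's RNG state).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Accept a genome as a one-row tibble (id, seq), a named string, or a plain
# string; return list(id=, seq=).
as_genome <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1, all(c("id", "seq") %in% names(genome)))
    return(list(id = genome$id[[1]], seq = genome$seq[[1]]))
  }
  if (is.character(genome) && length(genome) == 1) {
    id <- names(genome)
    return(list(id = if (is.null(id) || id == "") "seq1" else id,
                seq = unname(genome)))
  }
  if (is.list(genome) && !is.null(genome$seq)) {
    return(list(id = genome$id %||% "seq1", seq = genome$seq))
  }
  abort("cannot interpret `genome`: expected a one-row tibble with id/seq, a (named) string, or a list")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BLOSUM62 and its alphabet, fetched once from Biostrings.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Nucleotide substitution matrix over ACGTN (N scores 0 against everything).
dna_submat <- function(match = 1, mismatch = -1) {
  k <- nchar(DNA_ALPHABET)
  ab <- strsplit(DNA_ALPHABET, "")[[1]]
  m <- matrix(mismatch, k, k, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# Translate DNA (frame +1 of the given string); partial trailing codon dropped.
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(seq, 1, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

# 125-entry codon -> amino-acid index table (bases coded A,C,G,T,other) used
# by the spliced aligner; indices refer to `alphabet`.
codon_table_for <- function(alphabet) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T", "N")
  ab <- strsplit(alphabet, "")[[1]]
  out <- integer(125)
  for (b1 in 0:4) for (b2 in 0:4) for (b3 in 0:4) {
    codon <- paste0(bases[b1 + 1], bases[b2 + 1], bases[b3 + 1])
    aa <- if (grepl("N", codon)) "X" else unname(gc[[codon]])
    idx <- match(aa, ab)
    if (is.na(idx)) idx <- match("X", ab)
    out[25 * b1 + 5 * b2 + b3 + 1] <- idx - 1L
  }
  out
}
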