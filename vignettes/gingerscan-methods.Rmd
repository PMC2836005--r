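---
title: "Methods: structural annotation of Gypsy-integrase DNA transposons"
author: "gingerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural annotation of Gypsy-integrase DNA transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gingerscan)
```

## The problem

Cut-and-paste DNA transposons of the *Ginger* superfamily encode a
transposase whose N-terminal ~400 residues closely resemble the integrase of
*Gypsy* LTR retrotransposons: an H2C2 zinc finger, the DDE catalytic triad
and — in the *Ginger1* group — the YPYY motif (Y/F-P-Y/F-Y/F) upstream of the
zinc finger and the GPY/F multimerisation motif at the integrase C-terminus.
Structurally the elements are delimited by terminal inverted repeats (TIRs,
roughly 40–270 bp in *Ginger1*, 50–180 bp in *Ginger2*), start with the
conserved `TGTNR` pentamer (hence end with `YNACA`), and are flanked by 4-bp
target-site duplications (TSDs): *Ginger1* targets are GC-rich and highly
specific (CCGG ~75%, CCGT/ACGG ~24%), while *Ginger2* inserts into AT-rich
`RTATAY` sites, duplicating the central 4-mer. *Ginger1* transposases carry
an additional C-terminal protease domain (OTU or Ulp1, the latter sometimes
with a PHD finger), and their genes may be interrupted by 1–4 spliceosomal
introns, almost all canonical GT-AG.

`gingerscan` implements the discovery, structural annotation, family and
classification workflow for such elements, together with a synthetic-genome
generator that plants elements with exactly this architecture so that every
stage can be validated against known ground truth without any external
database.

## The synthetic-data generator

`simulate_genome()` draws an i.i.d. background genome (default GC content
0.5 — a neutral choice; real host genomes are often AT-richer, which mainly
makes chance GC-rich TSD matches rarer than in our tests), builds one element
template per family, and plants `n_elements` mutated copies:

* **Ginger1 insertions** rewrite the target 4-mer to a draw from the TSD
  profile (default CCGG 0.75 / CCGT 0.12 / ACGG 0.12 / other 0.01) and
  duplicate it on both flanks. Rewriting, rather than searching for
  pre-existing CCGG sites, guarantees exact control of composition at any
  copy number.
* **Ginger2 insertions** are placed at genuine `RTATAY` matches in the
  background; the central 4-mer of the site is duplicated. Which 4 of the
  6 site bases are duplicated is not documented for the real elements; the
  central `TATA` is the natural reading of the site logo.
* **Element bodies** are `TIR5 + UTR + transposase gene + UTR + revcomp(TIR5)`,
  with the TIR starting at a concrete `TGTNR` instance. The transposase gene
  is a back-translated synthetic peptide whose motif content is constructed
  (and verified by the package's own scanner) to match its group; introns are
  inserted at configurable CDS offsets as `GT…AG` (GC-AG behind a flag,
  mirroring the two known non-canonical cases).
* **Copy divergence** is substitution-only (default 1% per site, the level at
  which recently active families sit just under 1% consensus divergence).
  No indel process is simulated: the source material gives no indel model,
  and substitution-only divergence keeps copies alignment-free (equal
  length), which the family module exploits. Consequently the tests say
  nothing about indel robustness of the detectors.
* Default family geometries follow two published rows: a 3,064 bp / 126 bp
  TIR *Ginger1* family and a 2,815 bp / 112 bp TIR *Ginger2* family.

The truth set records exact bounds, TSD, TIR length and the planted gene
structure; by construction the flanking 4-mers are equal for 100% of planted
elements, and at zero divergence every copy equals its template.

What the generator does **not** emulate: nested insertions, excision
footprints, solo arms, repeat-rich backgrounds (a decoy inverted-repeat
option exists for stress tests), CpG-biased substitution, and indels. Passing
recovery tests on this material therefore demonstrate correctness of the
detection logic, not performance on real, repeat-dense genomes.

## Discovery

`scan_for_tpase()` mirrors a Tblastn-style search: overlapping windows
(default 2 kb, 50% overlap — linear memory at desk scale) are translated in
all six frames and aligned locally against the query panel under BLOSUM62
with affine gaps (open −11 / extend −1, the conventional protein-search
parameterisation; a gap of length *k* costs 11 + *k*). The raw-score
threshold defaults to 60; no E-value calibration is attempted. Overlapping
hits are merged keeping the best score. The bundled DDE-core queries play
the role of the published searches' integrase query.

## Boundary refinement

`find_tirs()` aligns the element's 5' window against the reverse complement
of its 3' window (match +1, mismatch −1, gap −2, minimum identity 0.8,
arms anchored within 5 bp of the termini). Two numerical details matter:

* Local alignments frequently overrun the true arm: a 4-bp TSD is often its
  own reverse complement (CCGG, TATA), giving a guaranteed 4-column
  extension, and cheap gaps let the alignment meander tens of bp further at
  ~50% identity. Arm ends are therefore trimmed back to the nearest run of
  4 consecutive matches, and `refine_boundaries()` re-anchors boundaries on
  the TSD rather than on raw alignment ends.
* `refine_boundaries()` enumerates inverted-repeat candidate pairs in an
  escalating window around the transposase hit (1.5/3/6/10 kb), iteratively
  truncating each side so the innermost enclosing pair is always among the
  candidates. For every pair it scans boundary positions whose flanking
  4-mers are exactly duplicated and ranks them lexicographically by:
  TSD present > terminal motifs matched > symmetric trim of the arm
  alignment > arm-pair alignment score (bucketed) > smaller span > smaller
  shift. The symmetry term rejects chance duplications far from the arm
  ends; the score term rejects candidates derived from weak chance
  alignments of flanking sequence; the span term resolves the cross-pairing
  ambiguity when two same-family copies sit within one search window (their
  TSD draws collide ~58% of the time, so TSD equality alone cannot).
  Escalation stops once a candidate has both a TSD and both terminal motifs,
  or when a TSD-bearing best stops improving.

TSD extraction (`extract_tsd()`) is exact-match only over k = 6..3, longest
k wins; a mismatch tolerance would inflate false TSDs given how likely 4-mer
matches are by chance. Elements whose best arm exceeds `max_len` are
reported in full and flagged, never truncated — published TIR ranges are
descriptive, not algorithmic.

## Families and divergence

Copies are grouped by single-linkage clustering on global pairwise identity
at a 0.80 threshold (a community-standard family cutoff; the source material
names families without stating a rule). Consensus rebuilding is per-column
majority with IUPAC codes on ties, dropping columns that are gaps in at
least half the copies. Divergence is 100 × mismatches / compared columns
with columns gapped in either sequence excluded (pairwise deletion) — indels,
where present, are deliberately not counted. Equal-length copies (the
generator's substitution-only output) are stacked directly; unequal copies go
through the progressive aligner, subsampling families above 20 copies
deterministically.

## Gene models and motifs

`reconstruct_cds()` performs a spliced alignment: dynamic programming over
(genomic position, homolog residue, partial-codon state) that consumes exons
codon-by-codon against BLOSUM62 and allows introns at any phase, provided
they begin with GT (GC optional) and end with AG (TG optional for GT-TG),
with a minimum length of 20 bp and a fixed intron penalty (10) that
discourages spurious splits while remaining far below the cost of aligning
through an intron's stop codons. The alignment is global in the homolog and
local in the genome; a model below score 50 is reported as no-model. This is
an exon-chaining formulation, not a full gene-prediction HMM — homology is
strong in every intended use, and the DP is exact under its scoring.

Motif scanning is pattern-based (no profile-HMM dependency): YPYY =
`[YF]P[YF][YF]`, H2C2 = `H x(2,6) H x(15,40) C x(2,6) C`, DDE =
`D x(50,130) D x(25,50) E`, GPY/F = `GP[YF]` restricted to the C-terminal
third of the integrase region. The spacing windows are stated approximations
read from published domain alignments that are not machine-readable; all
patterns are user-overridable, as are the OTU/Ulp1/PHD tail patterns (which
are regexes around the protease Cys-His dyad and the PHD cysteine spacing).
OTU and Ulp1 are never reported together; the leftmost match wins if both
somehow occur.

Intron conservation (`shared_introns()`) maps each intron to the alignment
column of the last full codon before the splice plus its phase (0/1/2 bases
of the split codon on the 5' exon); an intron is shared only when both agree
in every model.

## Classification

Ordered rules, the first match winning: RT/RNase-H coding capacity in either
5-kb flank ⇒ LTR-retro-like (the veto comes first because it is the decisive
argument against a DNA-transposon reading); TIRs + 4-bp TSD + GPY/F or YPYY
⇒ Ginger1; TIRs + 4-bp TSD without them ⇒ Ginger2; TIRs + 5-bp TSD ⇒
Ginger2/Tdd (TDD-4/5-like); transposase without TIRs and with clean flanks ⇒
vestige; otherwise unclassified. GC-rich vs AT-rich TSD context is recorded
as advisory evidence only — composition is a tendency with documented
exceptions, while motif content is the hard discriminator. The label set
deliberately does not encode whether Ginger1 and Ginger2 form one
superfamily or two.

## Logo statistics

`tsd_matrix()` and `information_content()` compute the per-position
frequencies and `IC = 2 − H` in bits. The 4-letter small-sample correction
`e(n) = 3/(2 ln 2 · n)` is available but off by default, since the published
logos' rendering settings are not stated.

## Phylogenetics

Protein distances support p, Poisson (`−ln(1−p)`) and gamma
(`a((1−p)^(−1/a) − 1`, default shape 2) corrections under pairwise or
complete deletion; a saturated pair (p = 1) is an explicit error, never a
silent infinity. NJ trees come from the Saitou–Nei agglomeration with
negative branches clamped to zero. The minimum-evolution search fits OLS
branch lengths per topology (non-negative least squares) and hill-climbs
over nearest-neighbour interchanges, accepting only length-reducing moves —
NNI is the level-1 analogue of the close-neighbour-interchange search used
by the MEGA-era tools, and is documented as an approximation. Bootstrap
supports resample alignment columns, rebuild per replicate, and map the
bipartition frequencies of the full-data tree onto its node labels (rather
than building a majority-rule consensus), which matches how such trees are
conventionally annotated. The progressive aligner builds its guide tree from
NJ on pairwise global-alignment p-distances and merges profiles by global
DP with a linear gap penalty; it is a deliberately simple, deterministic
stand-in for a full multiple aligner and is not intended to match one
column-for-column.

## Problem sizes and determinism

The validation suite works at desk scale: genomes of 0.1–3 Mb with up to 112
planted elements, families of up to 30 copies of 3-kb elements, alignments
of a few hundred residues, and 50–100 bootstrap replicates. All randomness
flows through explicit integer seeds (`sim_config(seed=)`, `--seed` on the
command line); identical seeds give byte-identical genomes, truth sets and
artifacts. Known limitations: detection robustness is only demonstrated for
substitution-only divergence up to ~1–2%; arm lengths can differ from the
planted value by a few bp when chance matches directly abut a TIR; and the
classification of a diverged copy depends on its own (possibly degraded)
motif content, not its family consensus.
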