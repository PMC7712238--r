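---
title: "Structural annotation of nematode GATA factors: methods and design"
author: "nemaGATA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of nematode GATA factors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaGATA)
```

## The problem

GATA transcription factors bind DNA through a Cys2-Cys2 (C4) zinc finger
followed by a lysine/arginine-rich *basic domain*, recognising sites with
the core `HGATAR` (H = A/C/T, R = A/G). Across the nematode phylum these
factors fall into a small number of structural classes:

* **ELT-1-like** — two DNA-binding domains (DBDs) in tandem, the
  arrangement shared with vertebrate and arthropod GATA factors;
* **ELT-2-like** — a single DBD preceded, at a variable distance, by a
  poorly conserved *degenerate* C4 finger (`CX2C-X9–20-CX2C`);
* **ELT-3-like / ELT-5-like** — single-DBD factors distinguished by
  sequence, tail length and intron positions;
* **ELT-X** — a catch-all for diverged single-DBD factors that cannot be
  confidently placed.

`nemaGATA` turns the structural reasoning behind this classification into
a reproducible pipeline: deterministic scanners for every domain type,
intron mapping into codon coordinates relative to the finger cysteines,
rule-based class assignment backed by consensus identity, anchored
alignments with conservation statistics, paralog synteny, and targeted
flank motif scans. A seeded synthetic-genome generator provides ground
truth so that every stage is testable without any external download.

## Domain scanners

**GATA fingers.** The scanner enumerates all matches of
`C-X(f)-C-X(L)-C-X2-C` with the first spacer `f` in 2–4 and the loop `L`
in 16–19 residues, resolving overlapping candidates leftmost-first, then
longest — a deterministic rule that mimics greedy visual annotation.
Only the exact canonical geometry (`f` = 2, `L` = 17) is labelled
`gata_canonical`; everything else in range is `gata_variant`, which
admits the rare `CSNSNC`-type spacer seen in some diverged factors. The
loop tolerance is a deliberate design choice: 17 is the canonical GATA
loop, but real orthologues drift by a residue or two, so the scanner
accepts 16–19 while keeping the strict canonical label informative. All
ranges are configurable through `scanConfig()`.

**Basic domain.** The 30 residues after the fourth cysteine, reported
with its K+R fraction and a truncation flag when the protein ends early
(some predicted orthologues retain only 13 of the 30 residues).

**Degenerate fingers.** `CX2C-X9–20-CX2C` motifs that do not overlap a
GATA finger and sit at most 200 residues upstream of one (observed
distances run from 34 to 152 residues; the default doubles the upper
bound for safety). Motifs with no downstream DBD are reported separately
as orphans rather than silently dropped.

**Diagnostic hexapeptide.** The loop of well-conserved fingers carries a
`T-X-[LA]-W-R-R` hexapeptide whose literal form is class-informative:
TPLWRR (amino ELT-1 finger), TTLWRR (carboxyl ELT-1 and ELT-2 fingers),
TSLWRR (some ELT-3), TTAWRR (ELT-5). The first match inside the
finger-plus-basic window is reported.

**Poly-serine segments.** Every 10-residue window containing at least 6
serines qualifies; overlapping or adjacent windows are merged into
maximal untrimmed segments. Reporting the union rather than a trimmed
core matches the visual annotation style of regions "about 10–20
residues" long. The worked example `AAAAASSSSSSAAAAA` yields exactly one
segment over residues 2–15 (1-based closed).

## Intron landmarks

Introns are deduced from CDS coordinates: each gap between consecutive
CDS segments, taken in transcription order, yields a `cds_offset` (the
spliced-CDS nucleotides 5' of it), a `codon_index` (`offset %/% 3`) and a
`phase` (`offset %% 3`; phase 0 falls between codons).

Positions are then re-expressed relative to a finger cysteine: with
`nt_after` the nucleotides between the end of the landmark's codon and
the intron, the descriptor is `codon_offset = ceiling(nt_after / 3)`
with the phase unchanged. This single rule reproduces both conventions
used for the conserved intron trio:

* the amino basic-domain intron *between the 20th and 21st codons after
  the fourth cysteine* → (C4, 20, phase 0);
* the carboxyl basic-domain intron → (C4, 8, phase 0);
* the zinc-finger intron *1 bp after the codon for the third cysteine*
  → (C3, 1, phase 1).

Introns 5' of a landmark receive a negative offset and a
`non_canonical` flag rather than being discarded — needed to
distinguish "same intron, different landmark" hypotheses. Matching for
signature flags is exact; descriptors are computed against every
detected finger, since for three-finger proteins there is no principled
way to single one out.

## Classification

`assignClass()` applies a total, ordered rule sequence:

1. **ELT1** — at least two GATA DBDs with an adjacent pair: C4-to-C1 gap
   ≤ `tandem_gap` (default 50). Real tandem fingers sit ~29 residues
   apart while non-tandem double-DBD factors show spacings of 100–311
   residues; 50 splits the regimes. This call is purely structural and
   never consults consensus identity.
2. **ELT2** — one GATA DBD plus at least one upstream degenerate finger.
3. **Single DBD** — anchored-window identity against each single-finger
   class consensus; argmax wins if it reaches `min_identity`
   (default 0.60, bracketed by the observed within-class conservation of
   ELT-5 at 76% and ELT-3 at 35%); ties break on the TTAWRR hexapeptide,
   then the conserved intron flags; otherwise **ELTX**.
4. **Widely spaced multi-DBD** — each DBD is scored by rule 3; agreeing
   labels win, disagreement falls to ELTX.

Identity is computed only over the 55-column DBD window because there is
little conservation elsewhere in these proteins; whole-protein homology
would mostly add noise. The shipped consensus library
(`inst/extdata/consensus_dbd_synthetic.fasta`) is a synthetic stand-in
carrying each class's structural hallmarks, and deliberately doubles as
the template set of the synthetic-genome generator so that classifier
and generator share a single source of truth. For benchmarking against
real proteomes, substitute a library transcribed from curated
alignments via `consensusLibrary(path)`; derived Elegans-Supergroup
factors (MED, END, ELT-7, ELT-4) are not modelled as separate labels and
will fall into ELT3/ELTX under the default library.

## Anchored alignment and conservation

`anchorAlign()` avoids progressive alignment entirely: the four
cysteines pin columns 1, 4, 22 and 25 of a fixed 55-column layout
(C1, spacer ×2, C2, loop ×17, C3, spacer ×2, C4, basic ×30). Short loops
are center-padded (the extra gap goes right of center — a stated,
deterministic convention), long loops and spacers are center-trimmed
with the removed residues recorded per row as insertions, and truncated
basic domains are gap-padded on the right.

Consensus strings follow the case convention: uppercase for absolute
conservation (one residue, no gaps), lowercase for a strict majority
(> 50%), `.` otherwise; ties yield `.`. `conservationCount()` reports
`k/55` in both *absolute* and *majority* modes, since published counts
of this kind do not always state which rule produced them. Amino and
carboxyl DBDs of tandem-finger factors are aligned as separate blocks —
their conservation patterns differ and pooling them destroys column
majorities.

The 18 DNA-contact positions used by `contactVariability()` are shipped
as data (`contact_positions_synthetic.tsv`), a synthetic stand-in
modelled on the distribution of base-contacting residues in the chicken
GATA1 solution structure; a contact column counts as varied unless every
class consensus shows the same absolutely conserved residue there.

## Synteny and flank motifs

Paralog pairs (same species, same class) are emitted once each with the
gap between facing gene ends (0 when spans overlap) and an orientation:
`same_direction`, `convergent` (3' ends facing), `divergent` (5' ends
facing), or `n/a` across scaffolds. Gene spans are taken over CDS
segments because UTR annotations are unavailable for most gene models.
Pairs closer than 50 kbp are flagged nearby, covering the observed
2.6–35 kbp band with margin.

Flank scanning is targeted rather than discovery-based: `HGATAR` on both
strands (minus-strand hits at forward coordinates), the inverted
*convergent* double-GATA arrangement (a plus-strand site 5' of a
minus-strand site, spacer ≤ 20 bp by default — the motif itself carries
no published spacer, so the bound is a stated default), and
polypyrimidine tracts (merged 12-bp windows with ≥ 90% C/T; thresholds
are stated defaults, not reproductions, as the source observations are
qualitative). All overlapping double-GATA pairs are reported so the
operation stays a pure function of the sequence.

## The synthetic-data generator

`generateCorpus()` emulates the corpus structure the analysis assumes —
it is a test harness, not an evolutionary simulation. Per class it
plants: tandem DBDs 29 residues apart with both basic-domain introns
(ELT1); a degenerate finger 34–152 residues upstream plus the
zinc-finger intron (ELT2); a short-tailed DBD with the zinc-finger
intron (ELT3); a 38–126 residue tail with the carboxyl basic-domain
intron (ELT5); and a diverged intronless DBD (ELTX). Poly-serine runs
are planted at the observed per-class frequencies (26/32, 11/30, 2/22,
3/26; 1/3 for ELTX). Proteins are mutated at a configurable per-residue
rate (cysteines and hexapeptides optionally protected), then
reverse-translated with uniform synonymous codons — codon usage is
irrelevant to every downstream operation. Linker and tail residues
exclude C and S so that planted fingers and poly-serine runs are the
only such features at mutation rate zero.

Two generator choices deserve emphasis:

* **Degenerate loop lengths** are sampled from {9–15, 20}, not the full
  9–20 band: loops of 16–19 are structurally identical to the canonical
  GATA finger and cannot be told apart without cross-species
  conservation information (real analyses hit exactly this ambiguity in
  borderline orthologues). The observed extremes 9 and 20 are retained.
* **Flank cleaning.** Planted motifs must be the only hits for recovery
  scoring to be meaningful, so flank backgrounds are scrubbed: chance
  HGATAR matches and qualifying pyrimidine windows outside the expected
  spans are resampled to purines until none remain. Planted
  polypyrimidine tracts carry purine guards, and the truth manifest
  records the maximal detectable segment (guard to guard) rather than
  the raw insert.

Because of these simplifications, passing recovery tests demonstrates
correctness of the machinery — coordinate handling, strand handling,
scanner logic, classification rules — not performance on real genomes,
where gene prediction errors, pseudogenes and background motif density
dominate. Linked paralog pairs are planted on dedicated scaffolds at
stated separations/orientations (defaults within the observed 2.6–35 kbp
band, mostly same-direction with one convergent pair, echoing the
observed 5:2 ratio).

## Numerical and degenerate-input conventions

* Coordinates are 1-based closed throughout the R API (the
  IRanges/Biostrings convention); GFF3 needs no conversion.
* Scans are case-insensitive; `X` never matches `C` or `S`; codons
  containing ambiguity codes translate to `X`.
* A trailing incomplete codon is dropped with a warning; a terminal stop
  is removed; an internal stop is an error by default, with a
  `truncate` mode for suspect gene models (the pipeline uses it and
  flags rather than repairs — automated re-splicing is out of scope).
* Annotated GFF3 phases are validated against coordinates and
  disagreement is a warning; splicing always derives from coordinates.
* Empty inputs return empty tables, never errors; a genome with no GATA
  factor is a successful run with empty output.
* Determinism: identical inputs and configuration give byte-identical
  outputs; all randomness flows through explicit seeds, and library
  code restores the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from
seeds: oracle-equivalence families run 500 fuzzed instances each
against brute-force enumeration; recovery runs use a 5-class × 10-gene
corpus (~0.2 Mb of scaffold sequence); the mutation-rate sweep uses
5 × 3 genes per corpus, 10 replicates at rates 0.05/0.10/0.20. These
sizes were chosen so the whole battery completes in minutes on one CPU
while still exercising every code path; all of them scale up through
`synthConfig()`.

## Known limitations

* Classification formalises rules that were partly judgement calls in
  manual practice; borderline factors sharing features of two classes
  (tandem-like ELT-2 orthologues, degenerate loops of canonical length)
  are resolved by fixed precedence, and the `evidence` field of every
  call records which rule fired so such cases can be audited.
* The shipped consensus library and contact-position set are synthetic
  stand-ins; quantitative agreement with published per-class
  conservation figures requires transcribing the corresponding curated
  alignments, which are not distributable as text here.
* No tree building, no ancestral intron reconstruction, no de novo
  motif discovery: anchored alignments are exported as FASTA for
  external phylogenetics tools, and flank scanning is limited to the
  three targeted motif families.
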