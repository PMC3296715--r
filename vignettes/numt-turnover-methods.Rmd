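---
title: "Detecting and dating nuclear mitochondrial pseudogenes: methods and design"
author: "numtdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating nuclear mitochondrial pseudogenes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtdyn)
```

# The problem

Numts are nuclear copies of mitochondrial DNA. They arise when a fragment
of the mitochondrial genome integrates into a nuclear chromosome; from that
moment the copy is a pseudogene evolving at the (much slower) nuclear
substitution rate, while the mitochondrial genome it came from keeps
evolving at the fast mitochondrial rate. Because numts are effectively
unconstrained sequence with a known, datable origin, their complement in a
set of related genomes is a window on the gain, duplication and loss
dynamics of neutral DNA.

`numtdyn` implements the full analysis chain for a genus-scale numt survey
across a calibrated species tree — the concrete defaults describe eleven
*Drosophila* species with sequenced nuclear and mitochondrial genomes and
an *Anopheles* outgroup:

1. **Detection** — entropy masking, seed-and-extend nucleotide search of
   the mitochondrial genome against nuclear scaffolds with Karlin–Altschul
   E-values, and linking of high-scoring pairs (HSPs) separated by at most
   50 bases on both sequences.
2. **Annotation** — grouping of linked hits within 25 kb, merging into
   single numt annotations under an explicit event grammar, and
   classification of gross rearrangements (interruptions, internal
   deletions, inversions, internal duplications) of at least 200 bases.
3. **Dating** — projection of each numt onto a panel alignment of the
   mitochondrial genomes, exhaustive maximum-likelihood placement on every
   branch of the fixed species tree under the F84 substitution model, and
   an insertion-age window from the branches not significantly worse than
   the best (one-sided KH-style test at alpha = 0.05).
4. **Homology** — paralog/ortholog calls by comparing the best tree with
   two numts clustered as sisters against the best tree with them apart,
   with micro-synteny confirmation from masked flanking sequence.
5. **Rates** — genus-average insertion rate N_i/T on branches younger than
   ~20 My, duplication rate Dp/(N·T/2) with one event per paralog set, and
   a steady-state deletion rate (gain rate)/N with half-life ln(2)/rate.
6. **Simulation** — a generative counterpart of all of the above with full
   truth tables, so that every stage is tested against a known answer.

# Substitution model and likelihood engine

All likelihood work uses F84: unequal stationary base frequencies and a
transition/transversion bias, parameterised here by two event intensities
(a within-class "transition" intensity and an any-base intensity) scaled
so one unit of branch length is one expected substitution per site.
Defaults follow the classic ML phylogeny programs: ts/tv ratio 2.0, no
among-site rate variation, empirical base frequencies from the alignment
in hand. Likelihoods are computed by Felsenstein pruning over compressed
site patterns; the engine is validated against explicit summation over all
internal-node state assignments on trees of up to five taxa (agreement
within 1e-9 log units).

Placement attaches the numt as a pendant leaf to each branch in turn. The
attachment point along the branch and the pendant length are optimized by
Brent's method (tolerance 1e-4 expected substitutions) after a midpoint
start; panel branch lengths are fitted once per dataset — a strict-clock
scaling of the calibrated branch durations followed by one per-edge
coordinate-ascent sweep on up to 2000 alignment columns — and frozen for
all placements. "Not significantly less probable" is operationalized as a
one-sided KH-style normal test on per-site log-likelihood differences; the
age window spans the node ages of the in-group significance set, and
density weights distribute one insertion across those branches in
proportion to branch duration. Numts whose window extends past the
configured deep split (the *Drosophila*–*Sophophora* node by default) are
flagged and excluded from rate inputs, as are zero-signal alignments.

# Search design

The similarity search is a classic seed-and-extend nucleotide search:
exact 11-mer seed words on both strands, a two-hit same-diagonal trigger,
and ungapped X-drop extension (X = 80 raw score units) under +5/−4
match/mismatch scores. Karlin–Altschul lambda is solved numerically for
the observed background composition of each query/subject pair; K defaults
to 0.1 and E-values above 1e-6 are discarded. Two deliberate choices
deserve note:

* **No gapped extension stage.** Linking HSPs with a maximum separation of
  50 bases on both the query and subject axes — the survey's original
  hit-combination semantics — already chains alignments across small
  indels; the gapped dynamic programming a general-purpose aligner would
  add is redundant here, and the boundary semantics of ungapped X-drop
  extension are easier to validate. Fragment-level identity is computed
  from the ungapped columns.
* **Changepoint boundaries.** Within the raw-score X-drop extension, each
  HSP end is placed by a changepoint log-likelihood ratio: a match scores
  `log(p1/p0)` and a mismatch `log((1-p1)/(1-p0))`, with `p1 = 0.85` (the
  per-base identity at the design detectability envelope) and `p0` the
  chance match probability of the two background compositions; the
  boundary is the earliest argmax. A raw +5/−4 argmax frequently wanders
  10–20 bases into flanking sequence on a near-neutral chance excursion
  (especially in A+T-rich context where random sequences match 40–50% of
  bases); the LLR boundary reduces such >10-base excursions from ~2% to
  under 1% per boundary in controlled plantings, at negligible cost on
  genuinely diverged ends.

Masking is entropy segmentation in the spirit of the classic
low-complexity filters: windows of 21 bases with Shannon entropy at or
below 1.4 bits trigger a segment that extends through adjacent windows at
or below 1.6 bits; masked residues are lowercased, never altered. Masked
positions cannot seed but are aligned normally during extension. On a 78%
A+T mitochondrial genome roughly half the sequence is masked — the price
of suppressing spurious hits in A+T-rich genomes, and the reason a small
fraction of short numts in maximally A+T-rich regions is undetectable by
design.

Merging reads the original curation step as a deterministic grammar: a
group of linked hits within 25 kb on one scaffold is accepted as a single
numt whenever its fragments can be explained as one mitochondrial source
region transformed by deletions, inversions, internal duplications and
interruptions. Partial nuclear overlaps between consecutive fragments are
alignment-end jitter across junctions and are trimmed back; an overlap
that would consume an entire fragment (the same nuclear bases carrying two
mitochondrial origins) rejects the group with a diagnostic. Event sizes
use the natural evidence axis of each class: interruptions in nuclear
bases, deletions in mitochondrial bases (measured around the circle when
the removed stretch crossed the origin of the circular genome),
duplications as multiply-covered mitochondrial bases, inversions as the
mitochondrial length of the strand-flipped fragment run. The reference
orientation of a numt is the strand carrying more fragments (ties broken
by total length, then by "+"), so a lone flipped fragment is the
inversion regardless of its length.

# The simulator

`simulateNumtHistory()` is the generative counterpart of the analysis and
defines the study conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| mitochondrial length | 16 kb | insect mitochondrial genome scale |
| A+T fraction | 0.78 | *Drosophila* mitochondrial composition |
| mito substitution rate | 0.004 /site/My | gives ~4–5% divergence between 5-My-separated mitochondrial genomes |
| nuclear rate divisor | 6.0 | middle of the reported 4.5–9× nuclear/mitochondrial synonymous-rate ratio |
| insertion rate | 0.75 /lineage/My | the genus-average insertion rate |
| duplication rate | 0.010 /numt/My | the genus-average duplication rate |
| deletion rate | 0.052 /numt/My | the steady-state deletion estimate |
| fragment length | log-normal, median ~1 kb, truncated to [200 b, 16 kb] | reproduces the observed size spectrum qualitatively, with occasional near-complete genomes |
| rearrangement propensities | 0.195 / 0.16 / 0.02 / 0.06 events per numt (interruption/deletion/inversion/duplication) | per-numt event frequencies implied by the published event table |
| rearrangement sizes | log-normal matched to published class means/s.d., truncated at 200 b | observed size spectra |
| assembly | 4 scaffolds × 2 Mb per species, 60% A+T | a deliberately scaled-down assembly that keeps end-to-end experiments tractable while leaving numts sparse enough that unrelated insertions rarely fall within one 25-kb merge window |

Events are generated by a Gillespie walk along each branch: insertions
copy the mitochondrial sequence *at the insertion time* on that lineage (a
contiguous, possibly origin-spanning fragment on either strand), after
which the copy evolves at the nuclear rate; duplications copy an existing
numt together with its tracked flanking sequence; deletions censor copies
(logged in the truth tables); copies are inherited through speciations, so
ortholog sets arise naturally. Insertion times are uniform within a branch
conditional on the Poisson count. Structural rearrangements are drawn once
per new copy (at most one deletion/inversion/duplication, Poisson
interruptions) and realized in the copy's layout; substitutions being
site-independent, sequence evolution and structural layout commute, so
layouts are applied at realization time.

What the generator deliberately does **not** model: selection,
recombination between numts, indels within un-rearranged numt bodies,
compositional drift of numts toward nuclear base composition, divergence
between tandem internal-duplication copies, orthologous nuclear flanking
context across species (each species' background scaffolds are drawn
independently), and the length-variable mitochondrial control region
(available behind a flag, off by default, since most real assemblies lack
it). Passing tests therefore demonstrate correctness of the pipeline's
logic under a clean substitution-only regime, not robustness to assembly
artifacts, alignment indels, or repeat-driven false joins in real genomes.

# Validation experiments and their problem sizes

The test suite runs every stage against simulator truth; the heavier
experiments and the sizes chosen for them (as a balance between
statistical resolution and a test suite that runs in minutes) are:

* **Annotation recall** — one default-condition history (~200 extant
  copies across 11 genomes of 8 Mb); recall is scored among planted numts
  with at least 200 b of sequence and at most 15% divergence from the host
  mitochondrial genome, requiring both outer boundaries within ±10 b.
  More-diverged numts sit beyond the search's design envelope (they are
  also heavily masked), mirroring the original survey's own caveat that
  old numts may be missing from its annotation.
* **Rearrangement classification** — classes planted singly (10–12 numts
  per class at ~8% divergence) and pushed through the complete
  mask–search–link–group–merge–classify pipeline; an event of at least
  400 b counts as recovered when an event of the same class and size
  (within max(50 b, 10%)) is reported for the overlapping annotation. In
  full default histories two event classes are unrecoverable by
  construction — interruptions larger than the 25-kb grouping window split
  the annotation, and events inside numts beyond the divergence envelope
  are never seen — so classifier accuracy is measured on the
  singly-planted design.
* **Placement coverage** — 50 numts sampled from the default history;
  the true insertion branch must lie in the alpha = 0.05 significance set
  at least 90% of the time.
* **Homology calibration** — 50 power replicates (a duplication 1 My ago
  of a numt inserted 15 My ago on a terminal branch) and 50 type-I
  replicates (independent insertions of the same mitochondrial region at
  15 and 8 My on the same lineage), sharing ten panel realizations.
* **Rate recovery** — 30 seeds per arm, event-level truth fed to the
  estimators. The insertion arm runs with the deletion rate set to zero:
  with deletion active the estimator systematically undershoots the
  planted rate because deleted insertions are invisible — precisely why
  such rates are lower-bound estimates — so the censoring-free arm is the
  meaningful test of the estimator itself. The duplication arm runs at full default
  turnover, where the half-branch-time exposure correction and survival
  censoring approximately cancel. The steady-state deletion arm checks the
  gain/complement identity at the simulated equilibrium (the complement
  reaches ~96% of equilibrium over the tree depth, so a small tolerance is
  added to the Monte-Carlo band).

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only when writing BED (unchanged) or GFF3 (1-based inclusive).
* Circular mitochondrial coordinates are normalized to [0, L); fragments
  crossing the origin are stored as two sub-intervals flagged
  origin-spanning.
* The ultrametricity tolerance for calibrated trees is 1e-6 My; violating
  trees are rejected with the observed leaf-depth spread.
* Karlin–Altschul lambda is solved by `uniroot` on (1e-9, 10) to 1e-12;
  the expected score must be negative, otherwise the scoring scheme is
  rejected.
* Zero-signal placements (all branches equally likely) return a window
  spanning the whole tree and are flagged low-information and excluded.
* A linked hit covering ≥95% of the mitochondrial genome at ≥99% identity
  is flagged for review rather than silently annotated — in real
  assemblies such a hit is usually the organellar genome itself riding
  along in the nuclear assembly.
* Homology tests demand at least 100 shared gap-free columns; pairs below
  that are untestable. Micro-synteny contexts with fewer than 200 unmasked
  flanking bases are untestable.
* Correlation P values use the two-sided t approximation for both Pearson
  and Spearman (average ranks for ties); constant inputs yield NA.
* The recent-branch set for genus-average rates is a configurable list of
  branch labels (ten by default); branch time is truncated at the 20-My
  age cutoff, and insertions are counted consistently (insertion time at
  or below the cutoff).

# Known limitations

* The search is ungapped within HSPs; heavily indel-riddled numts in real
  data will fragment into more HSPs than strictly necessary (linking
  recovers them when gaps are below 50 b on both axes).
* Entropy masking removes roughly half of a 78% A+T mitochondrial query;
  numts falling entirely inside maximally A+T-rich regions are
  undetectable, and boundary accuracy degrades where numt ends are masked.
* The steady-state deletion rate inherits the constant-complement
  assumption; it is arithmetic on the gain rate and the average
  complement, not an independent measurement. The published half-life and
  deletion rate cannot both be reproduced from half-life = ln 2 / rate
  with any single complement size; the package exposes the computation and
  reports what the inputs imply.
* Homology testing anchors the unclustered alternative at the first
  numt's maximum-likelihood attachment rather than optimizing both
  attachments jointly — an approximation that is accurate when the first
  placement is confident and keeps the test at two tree optimizations per
  pair.
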