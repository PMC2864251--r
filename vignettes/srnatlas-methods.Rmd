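---
title: "srnatlas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnatlas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnatlas)
```

This vignette is the package's own account of the statistics it
implements: the models and decision rules, the tunable parameters and
their defaults, the synthetic-data generators used for validation, and
the numerical conventions that make results reproducible.

## The data model

The pipeline operates on mapped small-RNA reads. Internally a read is a
row of an `aligned_reads` data frame: 0-based half-open genomic
coordinates, strand, the read sequence in read (5′→3′) orientation, a
collapsed-copy count, and a per-read mismatch list (`offset` from the
read's 5′ end, reference and read base, both in read orientation).
Indels are rejected at the boundary: the analyses below are defined for
perfectly matching reads plus, for editing only, single-substitution
reads, so supporting gapped alignments would add complexity without
adding usable signal. SAM input is parsed by Rsamtools with mismatches
recovered from MD tags; BED and GFF3 come through rtracklayer, with
1-based GFF coordinates converted at the boundary so that exactly one
coordinate convention exists inside the package.

Multi-mapping reads are taken at face value — each alignment record
counts where it maps; no rescue or weighting is attempted, because the
read-to-locus assignment policy of the upstream mapper is not
recoverable downstream.

## Quantification and ocm normalization

`quantify()` counts *perfect* reads per miRNA hairpin arm. Each arm is
a separate row, and reads antisense to an arm are accumulated in a
separate `<arm>(as)` row — arm-level read counts are subject to capture
bias, so arms are deliberately not aggregated per precursor. A read
counts toward an arm when it overlaps it on either strand by at least
half the read length (configurable); when two arms tie, the 5′ arm of
the precursor wins, deterministically, and the event is reported. No
minimum count gates antisense rows.

Small RNA libraries are dominated by a handful of miRNAs — a single
liver miRNA can carry over 20% of the library — which makes a plain
mean normalizer track the outliers, while the many lowly covered rows
make the median unstable. The outlier-corrected mean (ocm) removes
exactly the three highest-covered rows per sample (ties at the third
rank broken lexicographically by row id, so the removal is
deterministic) and takes the arithmetic mean of everything that
remains, zeros included. All counts in the sample are divided by its
ocm. Normalization is scale-equivariant per column and requires at
least four nonzero rows per sample.

### The pseudocount floor

Ratio- and log-based statistics need a defined value at zero. The
package floors normalized values at half a read on the normalized
scale, ε = 0.5/ocm per sample, *at comparison time only* — the stored
matrix is untouched. A floor (v′ = max(v, ε)) rather than an additive
pseudocount is used for fold-ratio calls and for the DE log-ratio: an
additive pseudocount shifts every ratio below its nominal value, so a
planted noise-free 5.0-fold row would not be called at a 5-fold
threshold; the floor leaves exact threshold cases exact while still
bounding zero denominators. The log10 heatmap transform, where no
threshold decision is taken, uses the conventional additive form
log10(v + ε).

## Tissue specificity and avoidance

A row is **tissue-specific** when its normalized value in the focal
tissue is at least `fold` (default 5) times the *maximum* over all
other tissues, in **every strain individually** (replicates averaged
first); **tissue-avoidant** mirrors this with at most 1/`fold` of the
*minimum* over other tissues. Both thresholds are inclusive ("at
least"). Requiring the rule per strain guards the calls against
strain-specific effects masquerading as tissue effects. The 5-fold
default is strict by design: it trades sensitivity for calls that are
unambiguous on DGE data. Whether a published analysis of this kind
applied its fold rule before or after pseudocounting is generally
unstated; here the ε-floor rule above *is* the documented behavior, and
the boundary sits exactly at the nominal fold on noise-free data (the
acceptance script verifies 5.0 on a 0.5-step grid).

`sample_correlation()` reports Spearman's ρ between samples over rows
expressed in at least one member of each pair; `mirna_tree()` clusters
rows by Euclidean distance on log10(normalized + ε) with complete
linkage by default (the linkage is configurable; nothing in the method
pins it down, and complete linkage gives compact, display-oriented
clusters for heatmaps).

## A-to-G editing detection

ADAR deaminates adenosine to inosine, which basecallers report as
guanine. `scan_editing()` therefore calls a read *edited at p* iff its
mismatch list is exactly one substitution, that substitution is A→G in
precursor-sense orientation, and it lies at precursor offset p; a read
is *consensus at p* iff it covers p with no mismatch at all. Reads with
two or more mismatches, or one non-A→G mismatch, are likely sequencing
errors or SNVs and count toward neither side. The one-substitution rule
is the base-space analogue of platform-specific confidence filters
(e.g. dual coherent color changes in two-base encoding): both exclude
multi-error reads; ours is platform-neutral. Editing is called on the
precursor's annotated strand only — ADAR acts on the transcript — so
antisense-arm reads are excluded.

The per-sample edited fraction is edited/(edited + consensus). A site
is reported when in at least one sample the fraction reaches
`min_fraction` (default 0.10, inclusive) **and** coverage reaches
`min_coverage` (default 20, inclusive). The coverage gate is an
addition over a bare 10% rule, which alone would fire on one read in
nine; 20 observations bound the binomial standard error of a 10%
estimate below ~7 percentage points, which is the least one can accept
for a reported site. The fraction threshold is applied per position
(whether a cumulative per-miRNA rule was ever intended is ambiguous in
the field's descriptions; per-position is the stricter and more
interpretable reading). Positions are reported 1-based on the
precursor; the seed flag marks mature-arm offsets 1–8, covering both
seed conventions (nt 1–7 and nt 2–8).

## Sliding-window strain differential expression

With three replicates per strain, per-row variance estimates are too
unstable for row-wise tests. Instead, the statistic borrows strength
across rows of similar abundance: from strain means mB and mS of
ocm-normalized expression, A = (mB + mS)/2 orders the rows and
D = log2(mB/mS) (ε-floored) is the effect measure; for each row, the
mean and SD of D over the `window` = 41 rows centered on it estimate
the local null, giving Z = (D − win_mean)/win_sd. The 20 rows at each
extreme reuse the window of the first fully interior row, so the
extremes share "identical values". This is the classical MA-style
local-null construction: at similar abundance, most miRNAs are not
strain-differential, so the local spread of D estimates count noise at
that abundance.

Choices a user should know:

- **Direction.** The default converts Z to p = P(X > |Z|), i.e. a
  one-sided test in the direction of each row's own deviation, so both
  strain-up and strain-down rows are discoverable; `direction =
  "literal"` applies P(X > Z) unconditionally, which tests only one
  direction.
- **Focal inclusion.** The focal row's D is included in its own window
  ("41 surrounding" read as centered-and-inclusive); with 41 values the
  dilution of a single outlier is at most 1/41 of itself.
- **Extremes.** `extreme_mode = "pad"` replaces window reuse with
  replicate-padding of the D vector; both readings of the extreme rule
  are available, reuse is the default.
- **Estimator and ties.** Sample SD (n − 1); ties in A broken by row
  id; `alpha` defaults to 0.05, accepted as appropriate for low
  replicate numbers with high expected variation.
- **Degeneracy.** A window with zero SD (all D identical, e.g. an
  exactly balanced contrast) raises an error pointing at the ε/jitter
  settings rather than silently producing infinite Z.

P-values get Benjamini–Hochberg adjustment (`bh_fdr()`, delegating to
`stats::p.adjust`); `significant` marks q < alpha. Under the observed-
direction convention p-values live in (0, 0.5), which makes the FDR
adjustment conservative under the null; null simulations in the test
suite confirm a mean discovery fraction well below 1% at q < 0.05.

## Ping-pong signature

The ping-pong amplification cycle cleaves a target across from guide
position 10, so a secondary piRNA's 5′ end overlaps its guide's 5′ end
by exactly 10 nt. `overlap_histogram()` counts, for every
(plus-read, minus-read) pair, the overlap (minus 5′) − (plus 5′) + 1
over lengths 1–30, strictly from genomic 5′ coordinates (plus: start;
minus: end − 1) — the standard operationalization. Pairs are counted
over unique (position, strand, sequence) reads by default, echoing the
clonality caution applied to cluster detection; `weight_by_copies`
restores copy-weighted counting. All pairwise interactions are counted
(not one per read): both modes of pairing appear in the literature, and
all-pairs is the one the randomized control calibrates directly.
`randomized_control()` redraws the observed per-strand read counts as
uniformly placed 30-mers in the same region, seeded. The summary
`pingpong_zscore()` standardizes the 10-nt bin against the mean and SD
of the other 29 bins of the observed histogram — a flat histogram gives
z ≈ 0 — while the control histogram is reported alongside for
comparison rather than folded into the score.

`positional_content()` reports base frequencies (U for T) at read
positions 1 and 10, counted from each read's own 5′ end: the primary
piRNA's 5′-terminal U and the secondary's position-10 A are the
sequence fingerprints of the mechanism.

## piRNA cluster detection

Cluster calling works on **unique 5′ start positions** per strand —
clonal amplification and cloning bias inflate raw counts, so each
distinct start counts once.

- **Cores.** A core exists wherever *more than* 20 (strictly ≥ 21)
  unique same-strand starts fall within a 2-kb window. Windows are
  anchored on the starts themselves (positions i..i+20 qualify when
  starts[i+20] − starts[i] < 2000) rather than on a fixed genomic grid;
  grid-free scanning is the natural reading and is verified exactly
  against an exhaustive window scan. Overlapping qualifying windows
  coalesce before extension.
- **Extension.** Each boundary absorbs the nearest same-strand start
  while it lies within 1 kb, iteratively per side, stopping when the
  next start is farther — i.e. extension continues while reads keep
  appearing within 1 kb, and stops at the first larger gap.
- **Merging.** Clusters on either strand that overlap or lie within
  `merge_gap` (default 1 kb, matching the extension scale; "adjacent"
  has no canonical definition, so this is configurable) merge into
  locations. Two-strand locations are classified *divergent* when the
  minus-strand member lies left of the plus-strand member
  (transcription pointing outwards from a central origin), *convergent*
  when inwards, *tandem* otherwise.
- No chromosome is excluded a priori: absence of clusters from a
  particular chromosome is a result, not a rule.

Cluster boundaries track 5′ start positions (the quantity the algorithm
counts), with the interval end at the last start + 1; read 3′ extents
are not tracked. `cluster_characteristics()` summarizes gene density
inside vs outside locations (any-overlap and fully-inside counts),
repeat base fractions, and the fraction of bases with a conservation
score > 0.5 from a user-supplied per-base track (the package consumes
such tracks; it does not compute alignments).

## The synthetic-data generators

Each generator is a pure function of its seed (byte-identical reruns,
caller's RNG state untouched) and emits objects that are valid inputs
to the corresponding readers and operations, plus a planted-truth
table.

- `simulate_counts()`: six tissues × two strains, liver in triplicate
  and single libraries elsewhere; log-normal baseline (median 50,
  sdlog 1.5 — a heavy right tail, as real libraries show) shared across
  tissues; negative-binomial counts with size = 100. That size gives
  ~10% extra-Poisson CV between replicates — several-fold-Poisson
  variance at abundant rows — and was fixed by a power calculation so
  that the generator's calibration contract holds: a planted 8-fold
  tissue effect at coverage ≥ 200 yields a realized ≥ 5-fold call in
  ≥ 95% of seeds, while 2–3-fold rows are never called. `dispersion =
  NULL` produces noise-free expectation matrices for boundary
  experiments. Planted tissue effects multiply the focal tissue in both
  strains; planted strain effects multiply all liver replicates of the
  focal strain.
- `simulate_editing_reads()`: one 80-nt precursor per planted site with
  a 22-nt mature arm; reads are arm copies independently edited (single
  A→G) at the planted rate, or exact mixtures (`exact = TRUE`) for
  threshold scans; plus- and minus-strand loci exercise orientation
  handling.
- `simulate_pingpong_reads()`: 27-nt primary plus-strand reads with
  forced 5′ U; each spawns a secondary minus-strand read with its 5′
  end opposite guide position 10; uniform background on both strands at
  a configurable fraction of all reads.
- `simulate_cluster_reads()`: k strand-specific clusters (5–20 kb, 30
  unique starts per 2 kb) over a uniform background of 1 start per
  10 kb across both strands on a 10-Mb chromosome, with a configurable
  fraction arranged as abutting divergent pairs; gene/repeat/
  conservation tracks planted at separate inside/outside densities.

What the generators do **not** emulate: sequencing error, adapter
artifacts, ligation/capture bias (real arm-level counts are biased in
ways no public model captures), multi-mapping ambiguity, and genuine
SNV-versus-editing confounding between strains. Tests passing on this
synthetic data therefore validate the *algorithms and their decision
boundaries*, not robustness to every artifact of real libraries.

## Problem sizes and numerical conventions

The validation suite runs at desk scale, chosen so properties are
statistically meaningful yet quick: 100–500-row count matrices, 100 DE
power simulations and 200 null datasets, editing coverage 500,
1,000-pair ping-pong simulations on 50-kb regions, and 20 cluster
genomes of 10 Mb. Determinism contracts are tested byte-for-byte on
written outputs. All internal coordinates are 0-based half-open;
1-based representations exist only at format boundaries (SAM, GFF3,
reported editing positions). Sample labels are `tissue.strain.replicate`
throughout.

## Known limitations

- The editing module cannot distinguish editing from strain SNVs
  without genotypes; it reports candidate sites.
- The DE statistic is the descriptive local-null z-score described
  above, not a count-model GLM; it is the method of record here, not a
  modern replacement.
- Cluster merging and the ping-pong pairing mode have no single
  canonical definition in the literature; defaults are documented above
  and configurable.
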