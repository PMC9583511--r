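---
title: "Methods: single-cell CNA landscapes of replication stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell CNA landscapes of replication stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repstress)
```

This vignette is the package's account of its models and the choices behind
them: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and where the method's limits lie.

## The measurement model

Low-pass single-cell whole-genome sequencing yields, per cell, read counts
over fixed genomic bins (here 40 kb, 500 kb and 1 Mb grids; coordinates are
0-based half-open throughout, BED convention). The count of bin $b$ in a
cell is modelled as negative binomial with mean

$$\mu_b \propto s_b \cdot w_b \cdot g(\mathrm{GC}_b),$$

where $s_b$ is the integer copy state, $w_b$ the bin width, and $g$ a
unimodal multiplicative GC bias. Variance is $\mu_b + \phi\,\mu_b^2$. The
simulator draws counts from exactly this model
(`simulate_g1_cells`); the caller assumes it.

**Default depth and dispersion.** Real platforms give no canonical
read-per-cell figure at this scale, so the fixture defaults are chosen for
caller testability: `reads_per_cell = 1e5` on the default 2 × 100 Mb
genome, i.e. ~250 reads per 500-kb bin, and dispersion $\phi = 0.01$
(variance/mean ≈ 2 at that depth, modestly over-dispersed relative to
Poisson as good pre-amplification-free libraries are). At these settings a
single-copy step is a ~3σ shift per bin, so a 4-bin (2-Mb) event carries
enough evidence to be decoded reliably while single-bin noise does not.

## GC correction

Counts are divided by the median count of their GC-decile, then rescaled to
preserve the genome-wide mean; deciles with median zero are flagged missing.
A plain one-pass decile median is biased whenever a decile is dominated by
bins of one copy-number event — the correction then "removes" the event.
`gc_correct` therefore runs two passes: the first pass yields a preliminary
relative copy number per bin (half-integer multiples of the modal corrected
coverage), and the decile medians are re-estimated from counts descaled by
it. For copy-neutral profiles the two passes coincide.

The generator's GC track is a smooth deterministic function of position
evaluated at bin midpoints of every grid (so the 40-kb, 500-kb and 1-Mb
tracks are mutually consistent), built from a long-range (2-Mb-knot,
isochore-like) plus a short-range (~0.3-Mb-knot) spline component. The
short-range component matters: real genomes disperse any GC stratum across
many loci on many chromosomes, and with a purely long-range field a whole
GC decile can be a single contiguous block — if that block coincides with
one CNA, GC bias and copy number become unidentifiable for any correction
scheme.

## Quality control

AneuFinder-style pipelines exclude poor libraries by multivariate
clustering; that procedure is not fully auditable, so here QC is two scalar
thresholds: total reads ≥ `min_reads` (default 10,000) and spikiness — the
mean absolute difference of consecutive mean-normalized bin counts — at most
`max_spikiness` (default 0.35, roughly 2.5× the value a clean
negative-binomial profile shows at default depth). Every excluded cell is
reported with the threshold it violated.

## Copy-number segmentation

Hidden states are integer copies $0..K$ (default `max_state = 8`).
Emissions are Gaussian with mean $s\,\hat\mu_1$ (state 0 sits at a small
floor of $0.05\hat\mu_1$) and state-dependent variance
$m_s + \hat\phi m_s^2$, the negative-binomial form, with $\hat\phi$
calibrated so the baseline state reproduces a robust scale estimate
(1.4826·median|Δv|/√2 of consecutive differences, insensitive to segment
structure). Constant variance is a poor substitute: it understates noise at
higher states and fabricates short spurious higher-state islands inside
genuine gains.

$\hat\mu_1$ is anchored on the modal coverage cluster (kernel density
peak), i.e. the most common copy state is assumed to be the baseline
ploidy. This is the standard — and, from relative depth alone, the only —
identifiable choice: a fully triploid cell is indistinguishable from a
diploid one without external information. Cells whose modal state is not
their true baseline are miscalled; per-chromosome baseline overrides
(`baseline_by_chrom`) handle known aneuploidies such as a trisomic
chromosome.

**Transition probability.** The per-bin probability of leaving the current
state defaults to $4\times10^{-4}$ at 40 kb, scaled linearly with bin size,
and is shared equally among target states. The choice balances two error
modes: each boundary of a real event must be paid for by one transition
(~8–9 log-units at these defaults), which a 4-bin single-copy event's
~30 log-units of emission evidence comfortably covers, while 1–2-bin noise
excursions (a few log-units) cannot. A much stickier chain (e.g.
$10^{-6}$) would price 2-Mb events out of the model entirely; a looser one
admits noise calls. Decoding is global maximum-likelihood (Viterbi) per
chromosome; chromosomes with fewer than 10 usable bins are skipped with a
warning. Segments at the baseline are not emitted; reported CNAs span at
least `min_bins = 2` bins, since single-bin events are indistinguishable
from noise at low pass. All scale estimates are equivariant, so calling is
invariant to multiplying a cell's counts by a constant.

## Clonal masking

Pre-existing (clonal) CNAs are learned from control cells only: segments
with identical integer copy state and ≥ 50% reciprocal overlap are grouped
by single linkage, and groups supported by ≥ 3 distinct control cells
("more than two") become clonal events whose representative interval is the
union of members. Matching on identical state rather than direction is the
literal reading of "same ploidy"; a direction-only mode is available.
Reciprocal overlap (required of both segments) prevents a whole-arm event
from absorbing small focal events; whether one-sided overlap was intended
is not decidable from the published description, so the threshold is
configurable.

Masking removes, from all cells, every segment matching a clonal event;
then sub-megabase chromosome-end segments and segments within 1 Mb of a
centromere are removed as repetitive-sequence mapping artifacts; then cells
with > 10 surviving CNAs are dropped (except in siRNA mode, where elevated
background is expected). The stage order follows the narrative order of the
underlying protocol and each stage logs its in/out counts. All filters are
idempotent and order-stable in their inputs.

**Breakpoint refinement.** Each surviving 500-kb segment adopts the left
boundary of the leftmost and the right boundary of the rightmost
overlapping same-cell, same-state 40-kb segment. "Overlapping" is
thresholded on the fraction of the *40-kb* segment covered (default 0.5):
a reciprocal criterion would reject exactly the focal high-resolution
fragments the refinement is meant to exploit (a 4.7-Mb 40-kb call inside a
20-Mb 500-kb call has reciprocal overlap 0.24 but is plainly the same
event's sub-structure).

## CNA classes and rates

Small means < 20 Mb; large means ≥ 20 Mb (exactly 20 Mb is large).
Direction is the sign of state − baseline. Terminal means one boundary
within one bin of a chromosome end — defined against the chromosome end
rather than the arm boundary, because centromere-adjacent events are
already removed upstream. Rates divide class counts by cells sequenced per
condition; fold changes divide treated by control rates and are flagged
undefined when the control rate is zero rather than silently infinite.

## Single-cell replication timing

Cells sorted from four S-phase gates (late G1/early S … late S/early G2)
are binned at 1 Mb. Per cell, bin counts become proportions of the cell's
total; bins below the per-cell 0.1 quantile are excluded (computed
separately for autosomes and X in male samples when `sex_stratified`).
Mappability is corrected against G1 reference cells: each bin's factor is
the average usable-bin proportion divided by that bin's mean G1 proportion,
so applying the factors to the G1 reference itself gives a flat profile.

Binarization designates as replicated the top $p$ fraction of a cell's
corrected proportions, where $p$ is the gate's expected replicated genome
fraction — 0.125, 0.375, 0.635, 0.875 by default. The printed mid-late
value 0.635 is kept verbatim although the geometric midpoint of that gate
would be 0.625; whether it is intentional cannot be determined, so
`fractions` is configurable. Operationally the cutoff is the $(1-p)$
type-1 empirical quantile; bins strictly above it are replicated and bins
tied at the cutoff are admitted in index order up to exactly
$\lfloor p\,n \rfloor$ bins. The tie rule matters with integer counts:
many bins share the cutoff value, and a naive strict-above rule would leave
each cell's replicated fraction drifting from $p$ by the tie mass, while
this rule pins it within one bin of $p$ deterministically (an all-tied
profile degenerates to the first $\lfloor p\,n\rfloor$ bins by index, with
a warning).

The replication timing factor of a bin sums, over the four gates, the
proportion of that gate's cells that replicated it — a value in [0, 4],
higher = earlier. Averaging across cells before summing (rather than
summing per-cell 0/1 calls and then averaging) is the reading consistent
with a population-level score; the two coincide in expectation. Quartile
categories split the observed RTF *range* (not the bin count) into four
equal intervals — late, mid-late, mid-early, early — read literally from
"categorized the range".

ΔRT subtracts control from treated RTF on mutually usable bins and flags
the empirical 2.5% tails as shifted much later/much earlier. Empirical
quantiles are used rather than a fitted normal: the distributional phrase
describes the shape of ΔRT, and empirical tails are assumption-free; a
constant ΔRT yields no flags.

## Breakpoint–feature association

Breakpoints: small CNAs contribute both boundaries; large terminal CNAs
only the interstitial one (a chromosome end is not a breakpoint); large
interstitial CNAs both; a whole-chromosome event has none. In-silico
controls are `n = 500` coordinates drawn uniformly (chromosome probability
proportional to length); coordinates landing in an exclusion mask are
dropped, not resampled — mirroring the loss of random coordinates during
mapping — and each retained coordinate is paired with a 1-Mb interval
clipped at chromosome ends. Point coordinates serve distance analyses;
the intervals serve window/timing analyses.

Distances are to the nearest end of the nearest feature (0 inside a
feature; either gene end counts, the literal "nearest end"); per CNA the
minimum over its breakpoints; proportion-within uses a 1-Mb cutoff. Window
expression sums the mean expression of every gene overlapping a 2-Mb
window centred on the breakpoint by at least 1 bp (any-overlap, since no
containment rule is stated). Positions within large genes are normalized
from the 5′ end; near-gene breakpoints get signed Mb offsets (negative
upstream of the 5′ end).

Repeat enrichment removes the first and last 1-Mb bin of every chromosome,
ranks the rest by repeat coverage, splits at the top-fraction rank boundary
(default 0.5), and tests each CNA class's breakpoint split against the bin
split with a 1-df chi-square goodness-of-fit; classes with any expected
group count below 5 are dropped, and p-values are Benjamini–Hochberg
adjusted across the tested classes only — enrichment families are never
pooled with other analyses. Group comparisons use Kruskal–Wallis over all
classes plus control, followed by Dunn's rank-based post hoc z-tests of
each class against the control with tie-corrected pooled variance and
Bonferroni correction (the classical Dunn adjustment); groups with fewer
than 3 values are flagged, not dropped. The replication-timing comparison
assigns each breakpoint the RTF of its containing 1-Mb bin (the breakpoint
bin, not an average over the CNA body, which is not specified).

## The synthetic-data generator

The generator emulates: a diploid G1 population carrying clonal events (all
cells of a condition), sub-clonal events (a configured cell fraction,
default 30% — the real prevalence of sub-clones is not quantified, so this
is a fixture parameter), and de-novo events (independent per-cell incidence);
S-phase cells whose replicated-bin sets derive from a smooth ground-truth
timing profile via a per-cell progression threshold; GC bias; and
negative-binomial counting noise. Every simulated cell exposes its realized
events and replicated bins (`cell_truth`) for oracle tests.

It does **not** emulate: read-level artifacts (duplicates, strand,
mappability gaps), library-preparation chimeras, sex chromosomes (the
default is all-autosome diploid; X/Y handling reduces to the configurable
quantile stratification downstream), mitotic error mechanisms, or selection.
Passing tests therefore demonstrate the pipeline's correctness under its
own statistical model, not robustness to every artifact of real libraries.

Ground-truth events are drawn with a 3-Mb minimum separation: closer
same-state events would merge into one segment under any segmentation and
the truth would be unidentifiable. Different clonality classes are drawn on
mutually exclusive regions for the same reason. Event boundaries snap to
the calling grid so recovery oracles can compare boundaries bin-for-bin.

## Validation problem sizes

The test suite and the acceptance script exercise: 100 single cells with
0–3 events of 2–30 Mb each on a 2 × 100 Mb genome (caller recovery within
±1 bin at 500 kb and bin-level accuracy); exhaustive brute-force
enumeration of clonal groups on ≤ 5-cell × ≤ 3-segment toy sets; a
24-cell two-condition masking experiment with 500-kb and 40-kb calls;
replication timing over 1,000 1-Mb bins with 4 × 50 S-phase cells plus 10
G1 references; ΔRT with a −2 shift injected into 2% of 1,000 bins; 20
random datasets for the Dunn-versus-permutation check and 200 simulations
for the uniform-p check; and a hotspot experiment seeding large terminal
losses at expressed large genes in late-replicating bins of a 2 × 200 Mb
genome. These sizes keep each property statistically decisive (binomial
standard errors of a few percent at the 95% thresholds) on a single CPU.

## Known limitations

* Baseline ploidy is assumed to be the modal copy state per cell; global
  ploidy shifts are invisible to relative-depth calling.
* Breakpoints are resolved only to bin boundaries; the 40-kb refinement is
  the floor of resolution.
* The Edivisive change-point alternative to the HMM is not implemented.
* GC correction shares the general confound of all coverage-based
  corrections: a copy-number event perfectly aligned with a unique GC
  stratum of the genome cannot be separated from bias; the two-pass
  estimator reduces, but cannot eliminate, this at desk-scale genomes.
* Sub-clonal structure is modelled as a fixed carrier fraction, not an
  evolutionary process; no model-based subclone inference is attempted.
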