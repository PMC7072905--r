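---
title: "Methods: bin-map construction and QTL mapping in selfed RILs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-map construction and QTL mapping in selfed RILs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltgmap)
```

## The problem

`ltgmap` implements the genetic-mapping workflow used to dissect
low-temperature germinability (LTG) in a *japonica* rice recombinant inbred
line (RIL) population: 144 F11 lines from a cross between the cold-sensitive
Shennong265 (SN265) and the cold-tolerant landrace Lijiangxintuanheigu (LTH).
Low-coverage resequencing of each line yields, at every SNP distinguishing
the parents, a noisy per-site call of parental origin. The pipeline turns
those calls into window genotypes, recombination breakpoints, a 15-kb bin
map, a genetic map, composite-interval-mapping (CIM) QTL scans with
permutation thresholds and 1.5-LOD support intervals, and finally
substitution fine mapping of a QTL region with candidate-gene extraction.

Throughout, `AA` denotes the SN265-type homozygote, `BB` the LTH-type
homozygote. The trait is the germination percentage after six days at
15&nbsp;°C; the parents anchor the scale at 15.4% (SN265) and 86.5% (LTH).

## Sliding-window genotype calling

For one line and one chromosome, the calls at consecutive SNPs are scanned
with a window of `window_size = 20` calls advancing one SNP at a time. With
`a` parent-A and `b` parent-B calls in the window, the window genotype is

* `AA` when `a / (a + b) >= 0.75` (the "15:5 or higher" rule),
* `BB` when `a / (a + b) <= 0.25`,
* `HET` otherwise,
* missing when fewer than `min_informative = 10` calls are non-missing.

A 20-call window is implied by the published 15:5 ratio; expressing the rule
as a proportion lets it degrade gracefully when sites are missing at
7.75&times; coverage.

**Breakpoint detection.** Runs of equal window genotypes become segments.
Three smoothing steps are applied, in order:

1. *Missing runs* are absorbed into their flanks (flanks sharing a genotype
   merge; otherwise the preceding run wins, which is also the tie rule
   everywhere else).
2. *HET transition ribbons are collapsed.* A ratio rule over a 20-call
   window necessarily produces a stretch of intermediate ratios wherever
   the window straddles a clean homozygous breakpoint — roughly half a
   window of spurious `HET` calls at every crossover. A `HET` run of at
   most `max_het_transition` (= one window) flanked by opposite homozygotes
   is therefore replaced by a single breakpoint at its centre, the point
   where the parental ratio crosses 50%. A genuine residual heterozygous
   segment shorter than one window span is statistically indistinguishable
   from this artifact, so nothing is lost; longer `HET` runs are retained
   as real segments (at F11 about 0.1% of the genome is expected to remain
   heterozygous).
3. *Short runs* (fewer than `min_run = 3` windows) are absorbed
   smallest-first; at 7.75&times; depth with ~1% call error such runs are
   overwhelmingly noise. The filter is configurable because the published
   procedure does not state its own.

Breakpoints are placed at the midpoint between the anchor SNP (window
centre) of the last window of one run and the first window of the next;
terminal segments extend to the chromosome ends. Coordinates are 1-based
inclusive in every report.

## Bin-map assembly

Each chromosome is tiled into 15-kb cells (`grid_bp = 15000`); a line's
genotype in a cell is that of its segment covering the cell midpoint.
Adjacent cells whose genotype vector across *all* lines is identical are
merged, so each resulting bin marker is an interval within which no line
recombines — the population-level merge is what makes bins usable as shared
markers. The published map reports 2,818 bins in the text and 2,828 markers
in its per-chromosome table; the package simply reports its own computed
count rather than matching either figure.

## Genetic-map estimation

Bins are dense and physically ordered, so the package estimates the map
from adjacent marker pairs rather than refitting a multipoint EM model:
order is taken from the reference genome, never re-estimated. For each
adjacent pair, the observed recombinant fraction `R` is the proportion of
discordant lines among lines homozygous at both markers (`HET` carries
negligible information at F11 and the inbred-line correction assumes
homozygotes, so it is treated as missing). `R` is converted to a
per-meiosis recombination fraction via the Haldane–Waddington relation for
selfed RILs, `r = R / (2(1 - R))`, and then to centimorgans with the
Kosambi map function by default (standard for rice; Haldane is available,
and is used by the package's own recovery tests because the simulator's
crossover process has no interference). Raw fractions above 0.5 are capped
at 0.4999 and flagged; distances above `ceiling_cM = 50` (unlinked) are
reported at the ceiling and flagged; intervals with no informative line get
distance 0 and a flag.

Genotyping error inflates this map: an isolated miscalled bin creates two
spurious "recombinants". The published total of 2,840 cM — roughly twice a
typical rice map — is consistent with such inflation, and the package
documents the effect rather than reproducing the printed total.

## QTL scanning

**Genotype probabilities.** On a grid of `step_cM = 1` plus all marker
positions, each line's probability of carrying `BB` is computed
conditionally on the nearest non-missing homozygous flanking markers, using
the two-state chain with step probability `R(d) = 2 r(d) / (1 + 2 r(d))`,
`r(d)` from the inverse map function. A position with no typed flank gets
probability 1/2; at a typed marker the observed genotype has probability 1.

**Haley–Knott regression.** At each position the phenotype is regressed on
the expected genotype score `x = P(BB) - P(AA)`; the LOD is
`(n/2) log10(RSS_reduced / RSS_full)` with the reduced model omitting only
`x`. Haley–Knott equals the mixture-ML scan at fully typed markers and is
the standard fast choice; the additive effect is the coefficient of `x`,
positive when the LTH allele increases the trait (the sign convention of
the positive-allele column in the QTL report). Degenerate inputs are
flagged, not scored: a zero-variance phenotype yields an all-zero LOD
curve, and a perfect fit is capped at `lod_ceiling = 50`.

**CIM.** Background covariates are bin markers chosen by greedy forward
selection on residual sum of squares, up to `max_cov = 5`; during the scan,
covariates within `exclusion_window_cM = 10` of the test position are
dropped. Both values are conventional CIM defaults — the publication names
the method but not its settings — and are exposed in the configuration.

**Permutation threshold.** The phenotype is permuted across lines
(`n_perm = 1000`, `alpha = 0.05` by default), covariate selection is redone
inside every permutation so the null stays exchangeable, and the threshold
is the empirical 95th percentile of the genome-wide maximum LOD. A fixed
LOD > 3 rule can be used instead by passing a constant threshold to
`qtl_report()`.

**Support intervals.** The 1.5-LOD support interval spans the *outermost*
positions on the chromosome whose LOD is within `drop = 1.5` of the peak,
with endpoints linearly interpolated to the threshold crossing (cM and bp,
bp interpolated linearly within the cM grid). Taking the outer bounds —
the behaviour of the established `lodint()` implementation — matters on
dense bin maps, where sampling jitter produces shallow dips that would
otherwise truncate the interval and erode its coverage. When two peaks on
one chromosome are separated by a dip below `threshold - 1`, they are
reported as distinct QTLs (the published map reports two QTLs each on three
chromosomes) and their support intervals are confined to their own side of
the LOD minimum between them.

**Variance explained** is `100 (1 - 10^(-2 LOD / n))`; with `n = 144` this
conversion reproduces the published variance column from the published LOD
column within 0.1 percentage points on all 11 QTLs, which the test suite
asserts.

## Substitution fine mapping

Key homozygous recombinant lines genotyped at ordered fine markers are
first classified against the parents, by default with one-sample t-tests
on their progeny-test replicates (the class is the parent the line does
*not* differ from at `alpha = 0.05`; lines differing from both or neither
are set aside with a warning). A midpoint rule (above/below the midparent)
is provided for synthetic data and for lines without replicate variance.
The QTL interval is the longest contiguous run of markers at which every
classified line is concordant — tolerant lines carrying `BB`, sensitive
lines `AA` — i.e. the intersection of per-line concordant regions,
reported at the bounding markers' positions (marker-bounded, not
interpolated). Contradictory lines (discordant across the whole region)
raise an error naming them; a panel with no informative recombinant
returns the whole region with a warning.

Candidate genes are annotation entries overlapping the interval by at
least 1 bp, ordered by start. Coordinates are normalised to
`start <= end` on load because minus-strand gene models are often listed
end-first — the bundled reference annotation of the fine-mapped qLTG6
region itself contains one such entry.

## The synthetic population generator

The generator's defaults are the conditions of the mapped population, and
they are deliberately not tunable study-to-study knobs:

* 144 lines, F11, single-seed descent from the F1; each meiosis draws a
  Poisson(L Morgans) crossover count with uniform positions and no
  interference (the publication is silent on interference; Haldane's model
  is the simplest defensible choice).
* 12 chromosomes with the physical lengths of the published map
  (373.1 Mb total) and genetic lengths of 4 cM/Mb, a standard rice
  recombination rate — the published 2,840-cM map is treated as inflated
  rather than as the simulated truth.
* 123,859 parent-distinguishing SNPs emulated as 0.332 SNPs/kb, sampled
  uniformly.
* Poisson(7.75) per-site depth; depth 0 is missing; calls flip with
  probability 1% (the publication does not state a call error rate; 1% is
  the rate the package's own recovery properties are stated at).
* Phenotypes are additive across 11 QTLs placed at the published peak
  positions. The published additive effects (8.1–12.0 points) sum far
  beyond the parental difference because they are marginal estimates, so
  they are used as relative weights and rescaled so that a fully LTH
  genome scores exactly 86.5% and a fully SN265 genome 15.4%. Residual
  noise is Normal with SD 10 germination points (not published; chosen as
  a realistic triplicate-mean measurement spread), and values are
  truncated to [0, 100] after noise because germination is a percentage.
* A fully penetrant single-locus trait (`simulate_major_locus_trait()`)
  emulates a DEP1-type qualitative panicle phenotype as the degenerate
  noise-free single-QTL case.

What the generator does **not** emulate: read-level data (FASTQ/alignment),
reference bias, depth heterogeneity along the genome, segregation
distortion, crossover interference, dominance or epistasis, and the
germination time-course (only the day-6 endpoint is modelled, the value
used for mapping). Passing tests therefore demonstrate correctness of the
algorithms under an idealised but faithful statistical model of the study
design, not robustness to every artefact of real resequencing data.

## Scales used by the tests and the acceptance script

Statistical properties are exercised at reduced, fixed scales chosen to
make the checks sharp yet fast, and stated here as the package's own
choices: heterozygosity decay at F6/F11 with 300–400 lines; breakpoint
recovery on one 25-Mb / 100-cM chromosome with 40 lines at 8&times; depth
and 1% error (recovery within 30 kb); map-length recovery with 500
error-free lines on one 150-cM chromosome (within 5%); permutation
type-I calibration over 200 null replicates of a 60-line chromosome at
200 permutations; and single-QTL interval coverage over 100 replicates of
144 lines with a QTL explaining ~25% of variance. The acceptance script
runs the full pipeline at the complete study scale (144 lines, 12
chromosomes, ~120k SNPs, CIM, 1000 permutations).

## Known limitations

* The pairwise adjacent-interval map estimator is auditable and fast but
  has no multipoint error correction, so its total length inherits the
  full genotyping-error inflation; this mirrors the published map's
  inflation but means cM totals should be read comparatively.
* HET bins are kept in the bin matrix but are uninformative downstream.
* Map positions between bins are linear interpolations; peak bp positions
  are therefore only as fine as the local bin structure.
* The fine-mapping interval is marker-bounded, so its physical width
  depends on the marker panel, as in the original substitution-mapping
  design.
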