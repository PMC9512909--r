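---
title: "Modelling stochastic DNA fragmentation and the Fragment Calculator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stochastic DNA fragmentation and the Fragment Calculator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmetrics)
```

## The problem

Clinical DNA samples — sonicated genomic DNA, bisulfite-converted DNA, DNA
from FFPE blocks, and circulating cell-free DNA (cfDNA) — are heavily
fragmented. A PCR assay only amplifies copies of its target region that are
not interrupted by a breakpoint, so the measured concentration depends on
both the true genome copy number and the amplicon length. fragmetrics models
that dependence and inverts it: from two assays of different lengths it
estimates how many genome copies a sample contains, how fragmented it is,
and how many intact copies exist at *any* region length.

## The fragmentation model

For DNA broken into fragments of a single length $f$, slide a fragment-sized
window across a region of length $r$: of the $f$ distinct phases of the cut
grid, $f - r + 1$ leave the region inside one fragment. Hence

$$p_{\text{intact}}(r, f) = \frac{f - r + 1}{f}, \qquad f \ge r,$$

and $0$ when $f < r$ (a region cannot survive on a fragment shorter than
itself). Real samples fragment as a distribution: with $C_f$ the mass
concentration (pg/µl) at fragment length $f$, ranging over the shortest
($m$) to longest ($n$) observed lengths,

$$p_{\text{intact}}(r) =
  \frac{\sum_{f=r}^{n} \frac{f-r+1}{f}\, C_f}{\sum_{f=m}^{n} C_f}.$$

The weighting uses mass concentrations directly (genome-equivalent
weighting): $C_f$ is proportional to (molecules at length $f$) × $f$, i.e.
to the number of genome-equivalents contributed by that bin, which is the
relevant weight when the quantity of interest is the fraction of *region
copies* that survive. The ratio of intact proportions at two amplicon
lengths $b > s$,

$$\frac{[\mathrm{long}]}{[\mathrm{short}]} =
  \frac{\sum_{f=b}^{n} \frac{f-b+1}{f} C_f}
       {\sum_{f=s}^{n} \frac{f-s+1}{f} C_f},$$

is a dimensionless fragmentation index in $[0, 1]$: 1 for intact DNA,
tending to 0 with increasing fragmentation. It is measurable directly by a
pair of assays (here 175 bp and 125 bp by default) without any sizing
instrument.

Mass converts to genome copies through the mass of one haploid genome,

$$m_{\text{genome}} =
  \frac{3{,}234{,}830{,}000 \times 650 \times 10^{12}}{6.022\times 10^{23}}
  \approx 3.4917\ \mathrm{pg},$$

commonly quoted as 3.5 pg. `genome_mass_model()` computes the constant from
its factors rather than hard-coding 3.5, because copy numbers derived from
the rounded value drift visibly in the third significant figure.

```{r}
gm <- genome_mass_model()
signif(mass_to_copies(35270, gm), 3)   # 35.27 ng/ul of DNA
```

## The Fragment Calculator

Direct inversion of the model needs the sample's full size distribution,
which is rarely measured. The Fragment Calculator instead interpolates
against *reference profiles* — samples whose distributions and average
fragment lengths are known, spanning the fragmentation range of interest.
Each reference contributes an anchor: its model-predicted
$[175]/[125]$ ratio. For a measured ratio $x$:

1. find the two anchors $x_1 \le x \le x_2$;
2. compute each anchor profile's response $y_i$ — its
   $[125]/[r]$ ratio for region-copy estimates (from the model applied to
   the reference distribution), or its average fragment length;
3. interpolate linearly, $y = m x + y_0$ with $m = (y_2-y_1)/(x_2-x_1)$;
4. for copies, divide the measured 125 bp concentration by the interpolated
   ratio. Genome copies are the $r = 1$ case: every single base survives
   fragmentation, so $[125]/[1\,\mathrm{bp}]$ maps amplifiable 125 bp
   copies back to total genome equivalents.

Two properties anchor the method's correctness and are enforced by tests:
when the queried sample *is* a reference profile the estimates are exact
(no interpolation error), and at $r = 125$ the estimate returns the
measured concentration identically. Between tight anchors the interpolation
error is small; the parameter-recovery tests plant a known copy number $G$
between references 40 bp apart in modal length and recover it well within
5% (typically < 0.1%).

```{r}
d1 <- synth_distribution("unimodal", mode = 200, seed = 1)
d2 <- synth_distribution("unimodal", mode = 300, seed = 2)
refs <- reference_set(list(
  reference_profile("modal200", d1, average_fragment_length(d1)),
  reference_profile("modal300", d2, average_fragment_length(d2))))
fit <- fragment_calculator(c_short = 1000, c_long = 700, refs)
fit
predict(fit, region = c(50, 125, 200))
```

Design choices in the calculator:

* **Full precision internally.** An opt-in `printed_rounding` mode rounds
  the slope and intercept to three decimals before evaluating the line —
  matching the convention of quoting the interpolation chain at three
  decimals — and exists so that worked examples reproduce digit-for-digit;
  it is never used in analysis.
* **Out-of-range ratios error by default.** The interpolation is defined
  only between anchors; a reference set should bound the expected range
  (a highly fragmented profile at the bottom, high-molecular-weight
  profiles at the top). `clamp = TRUE` uses the terminal bracket with a
  warning instead.
* **Ratios above 1 are rejected outright** — the model cannot produce them;
  they indicate copy number aberration at one target or measurement error.
* **Regions longer than the long amplicon** are estimated by the same rule
  but flagged as extrapolated in model space: no measured amplicon
  constrains that end.
* **FFPE caveat.** FFPE DNA carries single-strand breaks and residual
  crosslinks, so it amplifies *worse* than its size profile predicts. The
  calculator does not correct for this; for FFPE the assay pair itself is
  the more faithful measure of amplifiable DNA.

### Average fragment length

`average_fragment_length()` defaults to number-weighting
($\sum C_f / \sum C_f/f$: each molecule counted once); mass weighting
($\sum f C_f / \sum C_f$: each picogram counted once) is available via
`weighting = "mass"`. Sizing instruments do not document a single
convention for the "average size" they report, so reference profiles accept
their stated averages as given, and the calculator interpolates those
values without re-deriving them. Number-average ≤ mass-average always, with
equality only for single-length samples — a useful sanity check.

## The Monte Carlo oracle

`equal_length_fragmentation()` and `mixture_fragmentation()` estimate the
intact proportion by actually cutting a genome: draw a uniform phase in
$\{0, \dots, f-1\}$, place cuts every $f$ bp, and check whether the region
is uncut; the mixture version first draws $f$ with probability proportional
to $C_f$, matching the model's mass weighting. The genome is circular by
default so the sliding-window law holds exactly for every region; a linear
genome differs only within a fragment length of its ends, a relative effect
of order $f/L$ that vanishes for interior regions. Every simulation takes a
mandatory seed and records the RNG (Mersenne-Twister), so estimates are
bit-reproducible.

The test suite sweeps ≥ 50 cells of $(r, f)$ pairs and random distributions
at 100,000 replicates and requires agreement with the closed forms within
three binomial standard errors in at least 95% of cells — the standard
coverage expectation for a correct estimator.

## Synthetic data

The generators produce the two families of inputs the methods are used on:

* `synth_distribution("unimodal")`: log-normal mass density (default
  `sdlog = 0.45`, truncated to 35–10,000 bp, unit-binned) — the shape of a
  sonicated DNA smear. The default total mass of 1000 pg/µl is arbitrary;
  every model quantity is scale-invariant in total mass.
* `synth_distribution("nucleosome_ladder")`: Gaussian peaks at multiples of
  166 bp (mono-, di-, tri-nucleosome protection, default `peak_sd = 20`,
  weights decaying by 0.6 per peak) — the shape of a cfDNA profile.
* `synth_fragment_set()`: cfDNA-like fragment intervals with lengths
  $N(166, 10)$, each fragment nucleosome-bound with probability equal to
  the planted protection strength (centred on the nucleosome ±10 bp
  jitter), otherwise placed uniformly.

What these emulate — and what they do not: real electropherograms carry
marker artefacts, baseline noise and instrument-specific smoothing; real
cfDNA has sequence-dependent cut biases, variable linker lengths and mixed
nucleosome spacing. Passing tests on synthetic data therefore demonstrate
the *algorithms* are correct against their definitions and recover planted
truth under the stated noise model; they do not certify performance on any
particular instrument's exports.

## Windowed Protection Score

For each genome position $p$, the WPS counts eligible fragments
(120–180 bp) that wholly span the 120 bp window centred at $p$, minus those
with an endpoint strictly inside it. Conventions this package fixes, since
the source method leaves them open:

* an even window is centred as $[p - w/2,\ p + w/2)$ — the scored position
  belongs to the left half;
* a fragment with one *or both* endpoints inside the window contributes −1
  once (per-fragment, not per-endpoint), keeping every fragment's
  contribution in $\{-1, 0, +1\}$.

Both are arguments to `wps_config()`/`compute_wps()` in the sense that the
window and length band are configurable; the endpoint rule is documented
here and verified against a brute-force per-position recount on random
instances (integer-exact equality).

`call_peaks()` subtracts a 1 kb running median, smooths with a 21 bp moving
mean, and emits maximal positive runs of length 40–150 bp, with the apex at
the maximum raw WPS (leftmost on ties). Two defaults deserve comment. The
lower length bound is 40 bp because the fully-spanned run of a tightly
positioned nucleosome is approximately the fragment length minus the window
width — about 46 bp for 166 bp fragments and a 120 bp window — so a 50 bp
floor would reject precisely the signature being sought. And `min_score = 1`
discards runs whose raw apex score is not positive: median subtraction can
lift zero-coverage stretches above a locally negative baseline, producing
"elevated" runs with no spanning fragment at all. Both are heuristics and
both are arguments.

`amplicon_peak_distance()` scores assay placement as the farthest amplicon
base from a peak apex — the quantity to minimise when designing cfDNA
assays, since protection (and hence intact copies) decays with distance
from the nucleosome centre.

## Copy-neutral region selection

Assays that report genome copy number must avoid regions recurrently
amplified or deleted in cancer. The pipeline, exercised on synthetic
fixtures:

1. `dedupe_and_filter_records()` — drop cell-line records, records missing
   total copy number or minor allele counts, and per-sample duplicates;
2. `interval_coverage()` — exact per-base counts of CNA records,
   run-length encoded (internal zero-coverage runs are kept: truly
   CNA-free bases count as zero);
3. `threshold_low_cna()` — keep runs at or below a count threshold and
   merge. The operative published rule is the explicit hard cut
   (≤ 34 of 10,610 samples); the percentile path derives the cut as the
   length-weighted (per-base, type-1) quantile of counts, since "bottom
   10th percentile of regions" does not pin down a weighting;
4. `probe_gap_filter()` — drop candidates whose local probe spacing cannot
   support CNA detection. Internal probe gaps are clipped to the candidate
   (what matters is the unassayable stretch *inside* it) and each edge
   must have a probe within the gap limit; an unclipped rule would drop a
   well-probed candidate merely grazed by a distant gap;
5. `flank_and_intersect()` — ±65 bp windows around protection-peak apexes
   intersected with the surviving copy-neutral space;
6. `cytosine_free_windows()` — candidate priming sites free of 'C' (and
   'N') on the given strand, so one assay amplifies both genomic and
   bisulfite-converted DNA; the caller screens the other strand via
   `revcomp()`.

Every interval operation is tested for exact agreement with independent
per-base brute-force implementations on fixtures up to ~100 kb, and all
coordinates are 0-based half-open (BED convention) throughout.

## Quantitation helpers

`plex_ratio()` averages within amplicon-length classes before dividing
(the multiplex convention); `bisulfite_correct()` applies the factor-2
strand correction for qPCR of converted DNA (never for ddPCR, which counts
molecules absolutely); `recovery()` is conversion yield against the diluted
input; `ratio_to_mean()` normalises assays at a locus to their mean, which
makes the ratios average to exactly 1 by construction.

## Problem sizes and numerical notes

The shipped tests use 100,000 Monte Carlo replicates per grid cell
(54 cells), 500-fragment WPS instances, and ~20 kb interval fixtures —
sizes chosen so the full suite runs in seconds while leaving Monte Carlo
standard errors around $1.5 \times 10^{-3}$, small enough that a systematic
model error of half a percent would fail the 3-SE bound. Mass conservation
in unit-bin resampling is enforced to $10^{-9}$ relative by explicit
renormalisation after linear interpolation of the density. Interpolation
uses full double precision; degenerate brackets (ratio equal to an anchor)
return the anchor value directly rather than dividing by a zero anchor
spacing. `runmed` windows are forced odd and capped at track length.

## Limitations

* The model assumes uniform, independent cut positions; sequence-biased
  scission and enzymatic end-repair artefacts are out of scope.
* FFPE samples systematically under-amplify relative to their size
  profiles (strand breaks, crosslinks); estimates for FFPE are upper
  bounds.
* The calculator's accuracy degrades when the sample's distribution shape
  differs qualitatively from the bracketing references (e.g. a nucleosome
  ladder queried against sonication-shaped references).
* Peak calling on sparse fragment sets is sensitive to the baseline
  window; genome-scale tracks are the intended regime for the 1 kb
  default.
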