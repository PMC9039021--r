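---
title: "Rare-variant digital PCR: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant digital PCR: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredrop)
```

raredrop implements the computational side of a duplex digital PCR
(dPCR) assay for a rare somatic variant in low-input cell-free DNA
(cfDNA) — the motivating application is histone H3 K27M testing in
cerebrospinal fluid (CSF), where the mutant allele is read on the FAM
channel and the wild-type allele on HEX. This vignette explains the
statistical models the package implements, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the problem left genuine freedom.

## Partition statistics and quantification

A dPCR well distributes template over $N$ partitions. Under random
loading the copy number per partition is Poisson with mean $\lambda$,
so the probability that a partition is positive is $1 - e^{-\lambda}$
and the natural estimator from $n_+$ positive partitions is

$$\hat\lambda = -\ln\!\left(1 - \frac{n_+}{N}\right),
\qquad
\hat c = \frac{\hat\lambda}{v_p}\cdot \mathrm{VPF},$$

with $v_p$ the partition volume and VPF the Volume Precision Factor, a
multiplicative correction for chamber-volume variation on nanoplate
platforms (1.0 on droplet platforms). `estimate_lambda()` attaches a
95% confidence interval by computing a Clopper–Pearson (exact
binomial) interval on the positive fraction and mapping both ends
through the same log transform. The exact interval was chosen over a
Wald or Wilson interval because the assay routinely operates at very
small positive fractions (a handful of positives among 20,000
partitions), where normal-theory intervals misbehave; the price is
mild conservatism (empirical coverage slightly above the nominal
95%), which the test suite measures by simulation. A fully positive
well is reported as a saturation *error*, not an infinite
concentration: nothing quantitative can be said beyond "above range".

Replicates are merged by **summing partition counts before
estimation** (`merge_replicates()`), never by averaging per-well
estimates; under the Poisson model partitions of the same platform
are exchangeable across wells, and pooling is both unbiased and the
variance-optimal use of the counts. Pooling wells classified under
different platform profiles is refused.

The variant allele frequency is the mutant share of total template,
$\mathrm{VAF} = c_\text{mut} / (c_\text{mut} + c_\text{wt})$,
reported in percent. Because both channels share the partition volume
and VPF, the VAF can equivalently be computed from the two $\lambda$
estimates.

Back-calculation to the starting sample (`back_calculate()`) undoes
the wet-lab scale factors: multiply by the pre-dPCR dilution factor
(2 for the protocol's 1:1 dilution of the preamplification product),
divide by the preamplification factor, and rescale by the
reaction-to-template volume ratio. The volume basis of the reported
"copies/µl in the starting sample" is a configuration choice (the
`volume_ratio` argument); the default reports per µl of
reaction-equivalent template, and users tracking extract volumes pass
the appropriate ratio.

## Thresholds, classification and sample calling

Thresholds are assay inputs, set manually per platform exactly as in
routine practice — 2000/1500 RFU (FAM/HEX) on the droplet platform
profile, 40/20 RFU on the nanoplate profile — and the package
deliberately does no automatic threshold learning. Classification is
boundary-inclusive: an amplitude equal to the threshold is positive.

Sample calling (`call_sample()`) operates on exactly two technical
replicates and a partition-count parameter `min_count` (default 50):

* **positive**: at least `min_count` FAM positives in the duplicate
  total *and* FAM signal in both replicates;
* **ambiguous**: the FAM total reaches `min_count` but is confined to
  one replicate, or FAM positives exist (below `min_count`) without
  wild-type support (HEX total at or below `min_count`);
* **negative**: FAM total below `min_count` with HEX total strictly
  above `min_count`;
* **non_informative**: no FAM signal and HEX total at or below
  `min_count` — the well carries too little amplifiable template for a
  trustworthy negative.

Two readings of the positivity rule are defensible — the 50-droplet
criterion applied to the duplicate total or to each replicate
separately. The default applies it to the total (the negative rule is
explicitly phrased on the duplicate total, and symmetry argues for
reading the positive rule the same way) while requiring per-replicate
reproducibility at the ≥1-droplet level; the stricter per-replicate
reading is available via `positive_rule = "per_replicate"`. A well
with some FAM signal but neither 50 droplets nor wild-type support is
mapped to **ambiguous**: such wells cannot distinguish a weak true
signal from probe-degradation artifacts. The rule set is total — every
count configuration yields exactly one verdict — and this totality is
property-tested.

The informativeness filter (`informativeness_filter()`) excludes
isolates whose 150 bp amplifiable-fragment concentration is exactly
zero: without fragments of at least amplicon length the assay cannot
produce signal, and a negative result from such an isolate would be
vacuous. Zero is the only exclusion criterion; a missing measurement
is an error, not a silent exclusion.

## The threshold-gated preamplification model

Low-input cfDNA work preamplifies the target region for a small number
of cycles before dPCR. The package models the detectable output as

$$n = f(k)\, k\, A, \qquad
f(k) = \begin{cases} 0 & k < h \\ 1 & k \ge h \end{cases}$$

where $k$ is the template copy number entering preamplification, $A$
the amplification factor (absorbing cycle number and per-cycle
efficiency; $A = e^{tv}$ in rate–time form, with $t$ and $v$ not
separately identifiable and therefore never stored separately), and
$h$ a detection threshold below which the reaction fails outright.
`fit_amp_factor()` estimates $A$ by least squares through the origin
(the model has no intercept by construction); a single calibration
observation reduces to the ratio $n/k$ — 1574 positive droplets from
65 copies give $A = 24.2$. Predictions are rounded to whole
partitions; with $A = 24.2$ the model predicts 1210, 605 and 290
droplets at $k = 50$, 25 and 12.

$h$ has no empirically fixed value — the calibration point is an
operating point, not a threshold — so the default is $h = 0$ (no
gating) with $h$ exposed as a user parameter.

`censor_artifacts()` encodes the practical artifact rule: an observed
count far below the model prediction (default: under 1% of it) is
replaced by zero, since solitary positives in a reaction expected to
produce a thousand are probe-degradation artifacts, not template. The
1% cutoff is this package's quantification of a judgement that is
otherwise made qualitatively; it is configurable.

`fit_cycle_trend()` fits the exponential dependence of output on cycle
number by linear regression of log output on cycles, returning the
per-cycle growth multiplier and $R^2$ (computed directly from residual
and total sums of squares). Non-positive outputs cannot enter the log
fit and are dropped with a warning; a constant series is reported as
growth 1 with $R^2 = 1$ (the degenerate trend fits exactly).

## Low-copy sampling model

When a few dozen template molecules are pipetted into a reaction, the
number of mutant copies captured is binomial,
$X \sim \mathrm{Bin}(k, f)$ with $f$ the VAF.
`capture_probability()` returns $P(X \ge m)$ ($m = 1$ by default: a
single captured copy is in principle detectable after
preamplification). Below 100 total copies the exact tail is always
used; from 100 copies on, the default switches to the Gaussian
(de Moivre–Laplace) normal approximation with continuity correction,
the regime where the normal limit is conventionally invoked. The
exact mode remains available at any $k$ and is the recommendation for
library use.

A note on the approximation's accuracy, measured in the test suite:
with continuity correction at $k = 100$ the absolute error is below
$10^{-3}$ whenever the expected mutant count $kf$ is 10 or more, but
grows to about 0.014 at the skewed edge ($f = 0.05$, $m = 1$) and to
about 0.027 in the worst case over all thresholds $m$. This is the
ordinary skewness-driven failure of the normal limit at small $kf$,
not an implementation artifact; the tests assert these honest bounds
rather than a uniform 0.01.

`expected_positive_droplets_after_preamp()` composes the two models by
exact enumeration: binomial sampling of mutant copies followed by the
gated preamplification prediction, reporting the full droplet-count
distribution, its mean, and the probability that the ≥50-droplet
positivity rule would be met. `min_input_for_detection()` inverts the
capture probability by upward scan, a design tool for choosing input
amounts at a given VAF.

## Limit of detection

`make_dilution_series()` builds the standard geometric input-mass
ladder (default: ten two-fold dilutions from 600 pg). `call_lod()`
applies the hard count rule: the LoD is the smallest input mass
affording at least 50 positive partitions in at least one channel,
duplicates summed — the same boundary-inclusive convention as sample
calling, which is assumed to carry over since nothing suggests a
different one. No probit/LoD95 regression is attempted; the rule is
deliberately a hard threshold. When no point qualifies the result is
`NA` with a message, not an arbitrary mass.

Mass is converted to haploid genome equivalents at 3.3 pg per haploid
genome, the standard value for human DNA (9 pg ≈ 3 genomes); the
parameter is exposed because reasonable conventions range from 3.0 to
3.5 pg.

## Cross-platform agreement

`bland_altman()` implements the Bland–Altman comparison on
$\log_{10}$ copies/µl: per-pair differences (second platform minus
first, the orientation configurable by swapping inputs), their mean
(bias), sample SD ($n-1$ denominator; the convention is unstated in
most reports and the sample SD is the defensible default), and limits
of agreement at bias ± 1.96 SD. `pair_measurements()` applies the
exclusion rules first: unpaired keys (measured on one platform only)
and pairs containing a zero (no log) are dropped and reported.
Outliers are pairs deviating from the bias by more than 1.96 SD, with
an epsilon guard so that numerically constant differences are never
flagged. Swapping the platforms negates the bias and limits and
preserves the SD and outlier set, which is property-tested, as is the
~95% within-limits fraction on normally dispersed synthetic pairs.

## Cohort summaries

`summarize_cohort()` and `route_comparison()` summarize the 150 bp
amplifiable-fragment concentration of a CSF cfDNA cohort: median and
range over all isolates or informative isolates only, and by
collection-route group, with lumbar punctures (LP) in one group and
ventricular collections (intraoperative and ventricular-access-device)
pooled in the other. Every isolate row is one observation — patients
contributing several isolates contribute several observations, which
is what makes repeat-isolate designs comparable across patients — and
even-sized groups use the midpoint of the two central values. The
packaged example cohort (`csf_cohort()`, 21 isolates from 18
patients) reproduces medians of 35 copies/µl (all isolates), 81
(informative only), 3 (lumbar) and 94.5 (ventricular).

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates droplet-level data with known ground
truth through the same causal chain the analysis assumes:

1. **Loading**: each replicate draws mutant and wild-type copies from
   Poisson distributions with mean concentration × volume — the
   molecular sampling noise that dominates low-input work.
2. **Preamplification**: each molecule is amplified by the Bernoulli
   branching process of `simulate_preamp()`. The analysis-side model
   treats amplification as deterministic ($n = kA$); the simulator is
   deliberately stochastic so that low-copy dropout and
   replicate-to-replicate variability are represented.
3. **Partitioning**: per-partition occupancy is Poisson with
   $\lambda$ = post-preamplification copies / partitions,
   independently per allele; double-positive partitions arise from
   co-occupancy alone, with no coupling term (the standard independent
   loading assumption).
4. **Amplitudes**: negative and positive clouds are Gaussian per
   channel; a configurable fraction of positive partitions is drawn
   uniformly between (negative mean + 2 sd) and (positive mean − 2 sd)
   to emulate sub-threshold "rain"; empty-of-mutant partitions fire
   FAM at a small spurious-artifact rate (probe degradation), and
   wild-type partitions may cross-fire FAM at a cross-hybridization
   rate (non-specific probe annealing, the dominant failure mode at
   excessive probe concentrations).

Default conditions emulate the assay's documented low-VAF operating
point: 65 template copies/µl total at 14% VAF, 1 µl loaded, 8
preamplification cycles at duplication probability 0.49 per cycle
(mean factor $1.49^8 \approx 24.3$, matching the calibrated
amplification factor), duplicate 20,000-partition wells of 0.85 nL
(droplet geometry; the nanoplate profile uses 8,500 × 1.34 nL). Cloud
defaults (FAM negative 500 ± 150, positive 5000 ± 400; HEX negative
400 ± 120, positive 4000 ± 300 RFU) place the 2000/1500 RFU thresholds
cleanly between clouds; rain fraction 0.02 and artifact rate
5 × 10⁻⁵ (≈ one spurious droplet per 20,000-partition well) give the
solitary-artifact phenomenology seen in clean wild-type samples, and
cross-hybridization defaults to zero, its optimized-protocol level.
No amplitude distributions are documented for the real instruments;
these are free simulator parameters chosen once for plausibility.

What the simulator does **not** model: PCR chemistry kinetics,
droplet coalescence or volume variation, optical crosstalk between
channels, inhibitors, or allele-specific amplification bias. Passing
tests therefore demonstrate the pipeline's statistical correctness
under the model's own assumptions — Poisson loading, independent
partitioning, parametric amplitude clouds — not robustness to every
failure mode of real instruments.

## Numerical and testing choices

Degenerate inputs are errors with named conditions rather than silent
sentinels: saturated wells, zero-template VAF, empty wells, mixed
platforms in a pooled estimate. Rounding happens only where the
quantity is physically integer (predicted droplets, genome
equivalents). All simulation is seed-controlled and the simulator is
bit-reproducible for a given seed and configuration.

Test problem sizes are chosen so the full suite runs in seconds:
estimator calibration uses 200 simulated 20,000-partition wells at
$\lambda = 0.1$; the specificity property uses 500 seeded mutant-free
experiments of duplicate 2,000-partition wells (no positive call may
ever occur); VAF invariance under unbiased preamplification uses 40
paired seeds of duplicate 20,000-partition wells at the default
operating point, compared at 3 standard errors. Monte-Carlo
tolerances are always derived from the empirical standard error of
the quantity under test, not tuned constants.
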