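---
title: "Models and methods behind synergyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synergyscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscreen)
library(dplyr)
```

synergyscreen analyses two-arm (drug versus vehicle) replicated 384-well
perturbagen viability screens and their companion assays: synergy scoring
by the coefficient of drug interaction (CDI), extracellular-flux
stress-test phenotyping, and DNA-content cell-cycle analysis.  This
vignette explains the models, the normalization chain, the tunable
parameters and the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The screen model and the normalization chain

Every well's expected raw count is multiplicative:

$$E[\mathrm{count}] = \beta \cdot \pi_p \cdot \epsilon_w \cdot v_{\mathrm{mimic}} \cdot v_{\mathrm{drug}} \cdot I$$

with baseline $\beta$ (cells/well), a log-normal plate effect $\pi_p$, a
deterministic edge-ring multiplier $\epsilon_w$, the perturbagen's own
viability effect $v_{\mathrm{mimic}}$, the drug effect
$v_{\mathrm{drug}}$ (1 in the vehicle arm), and the interaction $I$ —
exactly the CDI that downstream estimation should recover ($I = 1$ means
Bliss-style multiplicative independence).  Per-well noise is log-normal
with mean 1.

Normalization happens per plate: every well is divided by the mean of
that plate's negative-control (scrambled mimic) wells, which cancels
$\beta$, $\pi_p$ and — because the scrambled control on a drug-arm plate
is drug-treated too — $v_{\mathrm{drug}}$.  Two consequences drive the
design:

* the **drug effect must be estimated separately**, as the ratio of
  drug-arm to vehicle-arm negative-control raw means
  (`estimate_drug_effect()`).  The hit ratio is then
  `drug/vehicle x drug_effect`, i.e. combined viability relative to the
  *untreated* control: a mimic with no effect and no interaction sits at
  $v_{\mathrm{drug}}$ (0.8 at an IC20 dose), and the 0.70 hit threshold
  reads as "a further 10% drop beyond the drug alone".
  `aggregate_and_ratio()` defaults to `drug_effect = 1` so it can also be
  used as a plain plate-relative ratio.
* the **CDI point estimate is free of the drug effect**:
  $\widehat{CDI} = AB/(A \cdot B)$ with $AB$ = drug-arm value
  $\times \hat B$ and $B = \hat B$, so $\hat B$ cancels and the estimate
  is the plate-relative drug/vehicle ratio itself.  Estimation error in
  $\hat B$ therefore moves hit ratios but never CDIs.

The hit threshold is boundary-inclusive (ratio $\le$ 0.70 is a hit), and
the strong-synergy bin likewise includes its boundary (CDI $\le$ 0.7);
the packaged worked example contains a 0.70 row among its selected hits,
which is what motivated the inclusive convention.  Both cuts are
configurable.

Stratification applies four annotation rules to preliminary hits:
abundance (> 4 reads per million in either condition), shared
family/cluster with another preliminary hit, literature-reported drug
regulation, and cancer-pathway involvement.  The sources the rules came
from list them without connectives; abundance reads as a quality gate
and the rest as biological evidence, so the default logic is
`rule1 AND (rule2 OR rule3 OR rule4)`, with conjunctive (`"all"`) and
disjunctive (`"any"`) combinations exposed because neither is asserted
to be "the" original setting.

Quality control computes a per-plate Z' factor,
$1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{pos}-\mu_{neg}|$, on normalized
values; plates with Z' < 0 are flagged but never dropped (no Z' cutoff
is claimed by the screens this models), and replicate agreement is
summarized by Spearman rank correlation over shared mimics.

## CDI significance

Replicate-level CDIs (replicates paired by index across arms) feed a
two-sided one-sample t-test against 1.  With typical $n = 3$ replicate
structure this is the simplest test available; it is slightly
anticonservative because a ratio of log-normal means is right-skewed
(measured type-I at CV 10%: ~4–7% across seeds, inside the binomial 95%
band around 5%).  Mimics with fewer than 2 paired replicates or zero
replicate variance get `NA` p-values with a warning rather than a
fabricated number.

The packaged 12-row secondary-screen example prints $A$, $AB$ and the
CDI but not the drug-alone viability $B$.  `recompute_published_cdi()`
back-calculates $B = AB/(A \cdot CDI)$ per row and re-derives each row's
CDI using the *leave-one-out* mean of the other rows' implied $B$, so
the recomputation never consumes the row's own printed CDI.  The implied
$B$ values agree to SD 0.011 — consistent with pure printed-rounding
wobble around a single screen-wide $B \approx 0.74$ — and the
recomputed CDIs match the printed ones to 2 decimals for the rows whose
inputs carry enough printed precision.

## What the generator emulates, and what it does not

Defaults are the modelled study's conditions: a 2063-mimic library, two
replicate plates per arm, $v_{\mathrm{drug}} = 0.8$, a lethal positive
control at 0.1 of baseline.  Noise defaults (well CV 10%, plate SD 0.05
on the log scale) are not published quantities; they were fixed once as
ordinary HTS magnitudes that make replicate Spearman correlations in the
0.6–0.8 range plausible.  The edge-ring multiplier defaults to 1 (off)
but is exposed because edge evaporation is a standard artefact worth
stress-testing.

The generator does *not* emulate: spatial gradients beyond the edge
ring, batch drift between replicate days, transfection-efficiency
variation, image-segmentation errors, or count/viability nonlinearity.
Passing recovery tests therefore demonstrate estimator correctness under
the declared noise model, not robustness to every real-screen pathology
(B-score/median-polish spatial correction is deliberately out of scope).

One calibration property deserves a caveat: the per-plate
negative-control mean (16 wells at CV 10% → 2.5% error) is shared by
every mimic on the plate, so the *mean* CDI of a 500-mimic null screen
carries a common component with SD ≈ 0.014 across seeds.  The estimator
is unbiased (grand mean 1.003 over a 12-seed sweep), but any single
seed can land up to ±0.03 from 1.

## Flux stress-test parameters

Traces are segmented at the three injection times into four phases
(half-open intervals: a point exactly at an injection belongs to the
following phase).  Parameter definitions follow the kit-report
conventions — last baseline point before the first injection, extrema
after each injection:

* glycolysis test (ECAR, glucose → oligomycin → 2-DG): non-glycolytic =
  baseline last; glycolysis = post-glucose max − non-glycolytic;
  capacity = post-oligomycin max − non-glycolytic; reserve = capacity −
  glycolysis.
* mitochondrial test (OCR, oligomycin → FCCP → rotenone/antimycin A):
  non-mito = post-rot/AA min; ATP-linked = baseline last −
  post-oligomycin min; proton leak = post-oligomycin min − non-mito;
  basal = ATP-linked + leak (the identity is built in, so it holds to
  machine precision by construction); maximal = post-FCCP max −
  non-mito; spare = maximal − basal; coupling efficiency = ATP-linked /
  basal.

Under multiplicative noise the extremum statistics are upward-biased
(the max of three noisy points overshoots the plateau by roughly
$0.85\sigma$), which is why the point statistics are configurable: mean
statistics give unbiased Monte-Carlo recovery (measured +0.1% at CV 5%
versus +6% for the extrema) and are what the simulation-recovery tests
use; the defaults stay at the kit convention for comparability with
vendor reports.  Negative derived rates (e.g. a reserve below zero when
capacity falls under glycolysis) are reported and flagged, never
clamped — clamping would hide degenerate traces.

Viability normalization divides every rate by a per-condition viability
denominator from a companion assay; ratio quantities (coupling
efficiency) are unchanged.  The bioenergetic phenogram classifies each
condition against a reference condition's baseline OCR/ECAR with
$\ge$ boundaries (the reference itself is "energetic"); the quadrant
cutoffs are the reference's own values because no absolute cutoffs are
published for these axes.

## Cell-cycle mixture model

DNA-content distributions are fitted with a three-component mixture: a
Gaussian G0/G1 peak, a Gaussian G2/M peak constrained to 1.8–2.2 times
the G1 mean, and a uniform S-phase component spanning the interval
between the two peak means, estimated by EM from a density-mode start.
This "pragmatic" family was chosen over a Dean–Jett–Fox polynomial S
because the synthetic generator draws from the same family, making
parameter recovery exactly testable (grid recovery at 20 000 events,
CV 3%: max per-phase error < 0.01, asserted < 0.03).  The trade-off is
honest: agreement here validates the fitting machinery, not the
biological adequacy of a uniform S on real cytometry data.

Numerical choices: events outside 0.3–2.8× the initial G1 peak estimate
are discarded as debris/doublets before fitting; the G1 peak start comes
from the dominant density mode, demoted to the mode at half its position
when a credible half-position companion exists (dominant-G2/M samples);
component SDs are floored at $10^{-4}$ of their means; weights are
renormalized each E-step and pinned to sum exactly to 1 at the end.
Samples with no visible G2/M peak, or whose G2/M:G1 ratio sticks at a
constraint bound, are flagged rather than rejected.  Fractions are of
post-filter events.  Group comparisons use per-phase Welch t-tests on
replicate-level fractions, reported in percentage points.

## Generic comparisons and the pipeline

Wherever a two-group comparison has no named test, the package uses a
two-sided Welch t-test (unequal variances; typical $n = 3$ gives no
basis for assuming homogeneity) with significance stars at the
conventional 0.05/0.01/0.001/0.0001 bounds, each labelled bound
inclusive.  No multiple-testing correction is applied by default,
matching per-comparison reporting practice; `p.adjust` is one line away
for screen-wide use.

`run_pipeline()` chains the stages on synthetic data with subsystem
seeds derived from one root seed at fixed offsets (screen: seed, flux:
seed + 1000, cell cycle: seed + 2000), writes every table as TSV with
fixed `%.10g` numeric formatting, and records MD5 checksums in a
manifest; two runs with the same configuration are byte-identical.
Default problem sizes for the bundled simulation study (300-mimic
screens for recovery, 500 for null calibration, 20 000-event DNA
samples, 1000-trace identity sweeps) were chosen so a full run completes
in well under a minute on a laptop while keeping Monte-Carlo error far
below every asserted tolerance.

## Known limitations

* Single-dose design: no dose–response surfaces, no Loewe/HSA models —
  the CDI is the only interaction statistic.
* The drug-effect estimate is screen-wide, not plate-pair-matched; with
  strong plate effects and few plates it is the dominant error source
  for hit ratios (never for CDIs).
* The cell-cycle model ignores sub-G1 debris structure, aneuploidy and
  doublet modelling beyond the hard gate.
* Vendor-native file formats (plate-reader, flux-analyzer, FCS binary)
  are out of scope; all I/O is documented plain CSV.
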