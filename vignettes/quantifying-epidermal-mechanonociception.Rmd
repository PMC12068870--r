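---
title: "Quantifying epidermal mechanosensation and nociceptive sensitization"
author: "epinoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epidermal mechanosensation and nociceptive sensitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinoci)
```

# Scope and data model

`epinoci` quantifies three experimental readouts used to study how
*Drosophila* larval epidermal cells sense mechanical stimuli and
potentiate nociception:

1. **Behavior ethograms** — annotated event tables (one row per scored
   behavior interval such as a roll, c-bend, hunch, freeze, or backing
   bout) around an optogenetic, thermogenetic, or mechanical stimulus
   epoch.
2. **Two-stimulus sensitization** — binary roll responses to two
   successive noxious stimuli separated by a recovery interval, across
   genotypes (the screen setting) or across intervals (the recovery
   kinetics setting).
3. **Calcium traces** — per-ROI fluorescence time series (GCaMP
   intensity or Fura-2 340/380 ratio) with stimulus timing and, for
   store-operated calcium entry (SOCE) assays, named perfusion phases.

The pipeline starts at extracted annotations and traces: video scoring,
ROI segmentation, and motion/bleaching correction are upstream of this
package and out of scope. Behavior labels are free strings matched
case-insensitively after trimming; no ontology is enforced, and
annotations are treated as ground truth.

All times are stored in seconds. Frame-based input columns are an input
dialect only, converted on read as `seconds = frames / fps` (exact for
integer frames); mixing figure-style seconds with acquisition-style
frames in one internal representation invites unit bugs.

# Interval conventions

Analysis windows and ethogram bins are half-open `[a, b)`. An event
counts toward a window iff the intersection has positive length; a
zero-duration point event counts iff its timestamp lies in the window.
This rule is deterministic for frame-aligned annotations: an event ending
exactly where a bin starts belongs to the earlier bin only, and an event
spanning a bin edge contributes to both bins. Default windows around a
stimulus epoch are 10 s pre, the stimulus itself, and 10 s post,
matching the usual scoring scheme; mechanical assays score rolling in the
10 s after stimulus removal. Whether the post window should instead run
to the end of the recording is not standardized; the 10-s default is
configurable (`post_length`).

Two subtleties are worth making explicit:

* **Latency** is measured to the first event *initiated* at or after the
  reference time: an event that began before stimulus onset and persists
  into it counts for `responded()` but is excluded from
  `latency_to_first()`, because a latency only makes sense for a
  behavior the stimulus started.
* **Cumulative response curves** use the first *overlap* time (clamped
  to the window start), so their terminal value equals
  `response_probability()` exactly — an invariant the tests enforce.

# Sensitization statistics and the recovery model

For responder counts to two successive stimuli, with probabilities
`P1 = rollers1/n1` and `P2 = rollers2/n2`:

* potentiation index `PI = (P2 − P1)/P1`, undefined when `P1 = 0`
  (division by zero has no principled standardization, so such genotypes
  carry an NA index, are excluded from screen statistics, and are never
  hits);
* enhancement `E = P2 − P1`, the quantity whose decay over the recovery
  interval `t` is modeled as `E(t) = a·exp(b·t)` with time constant
  `τ = −1/b`.

The fit is plain nonlinear least squares (`minpack.lm::nlsLM`) with a
deterministic initialization: an ordinary least-squares line through
`(t, log y)` over the positive values supplies both the starting rate
(slope) and starting amplitude (exponentiated intercept), with the
fallback `a0 = max(y)`, `b0 = −1/max(t)` when fewer than two positive
points exist. Taking *both* starting values from the log-linear fit
matters: it is exact on noiseless data, so the optimizer starts at the
optimum and exact recovery holds over the full parameter range, including
series sampled many time constants past onset where an amplitude started
at `max(y)` strands the optimizer on a plateau of negligible residuals.
Goodness of fit is `R² = 1 − SS_res/SS_tot`, and fits with `R² > 0.9`
are flagged `reliable`, the conventional screening gate for these decay
fits. Degenerate inputs are reported rather than mis-fit: a constant
positive series returns `b = 0`, `τ = ∞`, unreliable; non-convergence
returns the initialization with `reliable = FALSE` and a diagnostic;
fewer than 3 points or an all-non-positive series is an error.

Enhancement curves compute `P1` within each interval group by default;
a pooled-`P1` mode is provided for designs where one experiment family
shares a baseline. Which convention the original recovery analyses used
is not stated; both are exposed and the default is the more conservative
per-interval choice.

## Sampling variability of the fitted time constant

At the experimental scale — about 30 larvae per recovery interval over
six intervals, baseline response probability ~0.25 and initial
enhancement ~0.4 — each enhancement point carries a binomial standard
error of roughly 0.12, comparable to the signal itself over most of the
interval range. The fitted `τ` is therefore an extremely noisy statistic
at this sample size: its sampling distribution is far wider than ±25% of
the truth, as the acceptance script's estimator-recovery stage reports
(and as an independent check with `stats::nls` initialized at the true
parameters reproduces). The estimator is nonetheless centred correctly —
the median fitted `τ` across replicates sits close to the generating
value, and the noiseless fit is exact to machine precision — so the
package treats single-experiment `τ` values as order-of-magnitude
estimates and the `R² > 0.9` gate as the reliability filter.

# Screen standardization

Screen z-scores use the population SD (divisor *n*) across all defined
indices in the input, including the control — the natural choice when
each genotype contributes one index and the screen distribution itself is
the null reference. Whether the original screen standardized against the
full distribution or against control replicates is unstated, so a
`reference` argument provides the control-replicate mode; the default is
the full distribution. The hit rule is strictly `|z| > 2`: an outlier
landing exactly at 2 is not a hit. With one genuine hit among ~20
genotypes the self-normalized SD is inflated by the hit itself, which
slightly suppresses background false positives below the naive
`n · P(|Z| > 2) ≈ 0.9`; the false-positive check in the acceptance
stage therefore uses screens with no planted effect.

# Calcium-trace metrics

* **Baseline** `F₀` is the mean of the last `baseline_frames` samples
  strictly before stimulus onset: 10 frames for axon-terminal and fillet
  imaging, 5 for dissociated-cell imaging (the fillet subsection does not
  state its own count; 10 is the default and it is configurable).
  `F₀ ≤ 0` is an error, not a silent NaN factory.
* **Normalization** is `F/F₀`, with `ΔF/F₀ = F/F₀ − 1`. Percent
  increase is `100·(F_max/F₀ − 1)` for both GCaMP and Fura-2 ratio
  traces — one formula unifies the 10%/5%/15% responder criteria.
* **AUC** integrates `ΔF/F₀` by the trapezoidal rule on the actual
  sample times (non-uniform sampling is accepted), over the stimulus
  window by default, with window endpoints snapped to enclosed samples
  and no extrapolation.
* **Responder thresholds** are strict (`>`), so a peak of exactly +10%
  under the ">10%" rule is a non-responder. The comparison carries a
  1e-9 absolute guard on the percent scale so that a peak mathematically
  equal to the threshold can never classify as a responder through
  floating-point roundoff (10⁻⁹ of a percent is far below any imaging
  noise floor).
* **Response duration** has no published criterion; the convention here
  is total time with `ΔF/F₀` above the assay's responder threshold, with
  crossings located by linear interpolation between samples. It is
  configurable and recorded in every run report.
* **Viability gates**: cells must respond to a terminal ionomycin
  perfusion — >10% peak increase over baseline (GCaMP) or a peak more
  than 10 baseline SDs above the baseline mean (Fura-2 ratio). Gated-out
  cells are never responders.
* **SOCE phases** (`zero_ca`, `ca_readdition`, `ionomycin`) are explicit
  input metadata, not inferred from the trace: perfusion timing is an
  experimental fact the analyst knows. Phase windows must be disjoint.
  A cell is store-dominant iff its store-release AUC strictly exceeds its
  re-entry AUC.
* **Recruitment**: a cell's stretch threshold is the smallest magnitude
  evoking a response; cumulative fraction at magnitude *m* counts
  thresholds ≤ *m*; the newly recruited fraction is its increment. The
  threshold histogram sums to the overall responsive fraction by
  construction, and the tests enforce it.

# Synthetic-data generators

The generators encode the statistical structure the analyses assume, with
defaults at the regimes the assays operate in:

* behavior cohorts: per-behavior Bernoulli response (e.g. roll
  probability 0.73 for epidermal optogenetic stimulation, 1.0 for direct
  nociceptor stimulation), exponential latency and bout duration.
  Exponential forms are conventions for skewed positive distributions,
  not claims about the true ones, which are unpublished;
* two-stimulus experiments: `responded2 ~ Bernoulli(P1 + E0·exp(−t/τ))`
  with `τ = 337` s, `E0 = 0.4`, `P1 = 0.25` as the canonical regime;
* screens: background indices `Normal(μ₀, SD)` with planted additive
  effects;
* traces: `F(t) = F₀·(1 + A·(1 − e^{−s/τ_rise})·e^{−s/τ_decay}) + ε`,
  `s = t − onset`, Gaussian noise; the closed-form peak
  (`transient_peak()`) serves as an oracle. SOCE mode emits
  store-release, re-addition, and ionomycin bumps in annotated phases;
* stretch cohorts: categorical thresholds over the tested magnitudes
  plus "never", e.g. masses (0.18, 0.10, 0.13, 0.10, never 0.49) at 654
  cells for the dissociated-preparation regime.

Randomness is controlled by a single integer seed expanded into one
substream seed per trial/cell through a prefix-stable sequence, so
enlarging a cohort never perturbs the units already generated, and every
generator is a pure function of (parameters, seed).

What the generators deliberately do **not** emulate: correlated behavior
within larvae, annotation noise, photobleaching and motion artifacts,
non-exponential latency tails, channel biophysics, or between-preparation
variability. Passing estimator-recovery tests therefore demonstrates that
the analysis code inverts its own generative assumptions correctly — not
that those assumptions capture every feature of real recordings.

# Problem sizes and numerical choices

The test-suite simulations use the assay-scale sizes the package targets:
cohorts of up to 20 trials for oracle-equivalence sweeps (100 seeds),
5000 trials for probability recovery, 200 replicates of six-interval
sensitization experiments, 100 seeded screens of 20 genotypes, 654-cell
stretch cohorts, and trace grids of a few thousand samples. Tolerances:
exact arithmetic where the quantity is a count ratio; 1e-6 relative for
noiseless fit recovery; 1e-9 for z-score standardization and AUC
linearity; 0.5% for trapezoid-vs-analytic agreement at ≥10 Hz sampling;
3 binomial SEs for fraction recovery. Interval-overlap arithmetic uses
plain comparisons — no epsilon — because annotation times arrive as
decimal text and frame conversions are exact divisions; the only
floating-point guard in the package is the responder-threshold one
described above.

# Limitations

* Trial-level two-stimulus data are treated as independent Bernoulli
  draws; no within-larva correlation model is fitted.
* The decay fit is unweighted least squares on enhancement points; no
  binomial weighting or likelihood-based alternative is provided, to
  keep the statistic identical to the conventional curve-fit procedure.
* The screen provides no multiple-testing correction beyond `|z| > 2` —
  by design, since the statistic feeds a candidate-selection step, not a
  confirmatory claim.
* Fitted time constants from single experiments at ~30 trials/interval
  have very wide sampling distributions (see above); comparisons between
  conditions should rely on replicated estimates or on the enhancement
  curves themselves.
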