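---
title: "Detecting the ventilatory anaerobic threshold by structural-change segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the ventilatory anaerobic threshold by structural-change segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atseg)
```

## The problem

The anaerobic threshold (AT) is the exercise intensity at which anaerobic
metabolism starts contributing alongside aerobic metabolism. It is the
standard prescription target for safe training loads in cardiac
rehabilitation. Non-invasively it is read from expired-gas channels during a
ramp ergometer test: below the threshold, minute ventilation (VE) and CO2
output (VCO2) track load roughly linearly; above it, buffering of lactic
acid releases excess CO2 and both channels steepen. The conventional
V-slope reading — an examiner eyeballing the knee of the VCO2-versus-VO2
plot — is subjective, and inter-examiner reliability is known to be
mediocre. `atseg` replaces the eyeball with a segmented-regression break
search that returns a point estimate *and* a confidence interval, in watts.

## The model

After preprocessing (10-s bin means, then a centred 3-point moving
average), a channel $y_t$ on the loaded phase of the test is modelled as
piecewise linear in time with $m$ unknown break dates:

$$y_t = a_j + b_j\,t + \varepsilon_t,\qquad t \in (i_{j-1}, i_j],\quad j = 1,\dots,m+1,$$

with i.i.d. homoskedastic errors. Everything about the fit is exact, not
heuristic:

* **Segment-RSS table.** The OLS residual sum of squares of every
  admissible segment $i..j$ is computed in closed form from running
  cross-products (a per-segment QR route exists as a cross-check). A
  segment must contain at least $h_{abs} = \lceil h \cdot n\rceil$
  observations, default $h = 0.15$ — the conventional minimum-segment
  fraction of this method family; the source study does not report one.
* **Optimal partition.** A Bellman recursion over the table returns the
  global minimum-RSS segmentation for each $m$; ties are broken by the
  lexicographically smallest break vector so results are reproducible.
  The test suite proves global optimality against exhaustive enumeration
  on all small problems.
* **Model selection.** $m$ minimises
  $\mathrm{BIC}(m) = n\log(\mathrm{RSS}_m/n) + k_m\log n$ with
  $k_m = (m+1)p + m + 1$ (segment coefficients, break dates, error
  variance). The RSS curve is monotone non-increasing in $m$ by
  construction, so it cannot select a model; it is reported for diagnostic
  plots only, and selection is by BIC alone. Ties go to the smaller $m$.
* **Break-date confidence intervals.** Each break date is asymptotically
  distributed as the argmax of a two-sided Brownian motion with triangular
  drift, scaled by $\hat\sigma^2/(\Delta\beta' Q \Delta\beta)$, where
  $\Delta\beta$ is the coefficient change across the break, $Q$ the local
  regressor second-moment matrix over the two adjacent segments, and
  $\hat\sigma^2$ the pooled residual variance. The limit CDF has a closed
  form (`pbreakdate()`; its 97.5% quantile is 11.03) and is inverted
  numerically. Interval endpoints are rounded outward to observation
  indices, then converted to time and watts — rounding before conversion,
  so the reported watt range is a protocol-grid range.

### From break to threshold

The design regresses the channel on *time* with an intercept and trend per
segment ($p = 2$; intercept-only is available), which matches the visibly
piecewise-linear trends of smoothed ventilation data. The analysis window
is the loaded phase — warm-up start (180 s) through ramp end (930 s) — since
rest and cool-down carry no threshold information.

Segmentation typically returns 3–4 breaks, only one of which is the
threshold. The AT is taken to be the ramp-phase break with the **largest
positive slope increase**, the direct formalisation of the defining
"nonlinear increase". Two refinements:

* A break within one tread (30 s) of the ramp start is protocol-induced
  (the warm-up plateau ends there) and is excluded from candidacy, though
  it is still reported in the candidate table.
* A break date is the last observation of its segment, so the threshold
  *time* is taken as the midpoint between that bin and the next — on
  noise-free data this recovers the exact knee time regardless of which of
  the two straddling bins the fit ends on.

If no break is selected, or no ramp-phase break has a positive slope
change, the result is the data outcome "no AT detected", not an error.

## The ramp protocol and watt conversion

The default protocol is 3 min rest, 3 min warm-up at 20 W, +10 W every
30 s for 9 min 30 s (peak 210 W), 3 min cool-down — 18 min 30 s in total at
50 rpm, with a termination criterion of HRmax = 220 − age. `time_to_watts()`
maps times to the stepped load (the first tread is 30 W); all watt outputs
therefore live on the 10-W protocol grid. Published per-subject tables
contain half-grid values such as 105 W; no rounding rule on a 10-W
staircase can produce them, so exact parity with those entries is not
claimed.

## The V-slope baseline

`vslope_at()` is the algorithmic analogue of the manual reading: an
exhaustive search over split points of the time-ordered (VO2, VCO2) plot,
both limbs fitted by OLS, keeping the minimum-RSS split whose upper limb
is strictly steeper. Steepness is compared on standardised data with a
slack of $10^{-6}$ so a straight line never yields a spurious knee; each
limb needs at least 5 points (the study gives no limb constraint). The
knee is the intersection of the fitted limbs; if that falls outside the
observed VO2 range it is flagged and the split boundary point is used.
The AT in watts is the test time of the data point nearest the knee — the
study does not state how examiner readings were converted to watts, so
this convention is the package's own. Manual examiner values are *not*
claimed to be reproduced; examiner subjectivity is precisely the problem
the segmentation route avoids. `right_shift_flag()` reports the fraction
of points below the VCO2 = VO2 diagonal, the classic signature of traces
on which apparatus V-slope detection fails.

## Agreement and reliability statistics

Per-subject AT tables (structural-change 95% CI and median, apparatus AT,
V-slope AT, all in watts) are compared with:

* `count_ci_agreement()` — subjects whose comparator AT lies in the
  structural-change CI. Containment is **endpoint-inclusive**, the only
  self-consistent rule that reproduces the published counts; subjects whose
  apparatus could not detect a threshold are excluded from the denominator.
* `count_equal()` — exact watt equality between two methods.
* `column_summary()` — mean and SD with an explicit divisor, because the
  published summary rows mix conventions (the apparatus column matches the
  sample divisor $n-1$; the structural-change and V-slope columns match the
  population divisor $n$).
* `icc2k()` — two-way random-effects ICC from the mean-square
  decomposition; `icc` is the average-measures ICC(2,k). The lower
  confidence bound uses the Shrout–Fleiss F-based construction with
  Satterthwaite degrees of freedom on the single-measure coefficient,
  stepped up by Spearman–Brown. `alpha` is one-sided (default 0.1: a 90%
  lower limit, the reliability floor recommended for judging whether a
  manual method is acceptable).

## The synthetic generator

`synthetic_config()` + `generate_breaths()` emulate a breath-by-breath
metabolic cart on the default protocol: breath intervals of 3 ± 1 s
(uniform jitter, a typical adult exercise respiratory rate), channels
piecewise linear in time — rest level, warm-up level, ramp rising at the
per-watt slope times the ramp rate (1/3 W/s), a steeper slope beyond the
threshold onset, linear cool-down decay — plus independent Gaussian noise
per breath. Defaults describe a healthy ~70 kg young adult: VE 10 L/min at
warm-up rising 0.25 then 0.55 L/min/W with breath noise SD 2.0 L/min; VCO2
0.13 then 0.20 ml/kg/min/W (SD 0.8); VO2 a single 0.143 ml/kg/min/W slope
(SD 1.0), so the respiratory quotient rises after the threshold. The VE
noise level was calibrated so that the full pipeline recovers the true
threshold within 10 W in at least 90% of subjects (97% of 200 in the
packaged run); per-breath SDs of this size shrink to about a third after
10-s binning and 3-point smoothing, which is the realistic post-averaging
noise scale.

What the generator deliberately does **not** model: VO2/VCO2 on-kinetics
(first-order lags at phase transitions), breath-amplitude autocorrelation,
the respiratory compensation point as a second break, cardiovascular drift,
or CO2-store dynamics. Passing the recovery tests therefore shows the
detector handles piecewise-linear-plus-noise signals of realistic magnitude;
it does not certify performance on pathological gas-exchange patterns.

## Numerical choices and degenerate inputs

* Segment RSS values are clamped at zero (exact interpolation produces
  tiny negative rounding residue); a zero RSS maps to BIC $-\infty$, and
  the smallest such $m$ wins, which is what makes noise-free recovery exact.
* Rank-deficient segment designs raise an error naming the segment.
* DP ties are resolved at a relative tolerance of $10^{-8}$ toward the
  lexicographically smallest break vector.
* A break with numerically zero coefficient change has an unidentified
  interval: the CI is clamped to the neighbouring break positions with a
  warning.
* Empty interior bins are linearly interpolated and flagged; more than two
  consecutive empty bins is treated as a data gap and refused.
* Moving-average edges keep shortened windows so series length is
  preserved; outputs carry a `smoothed` attribute.

## Problem sizes in the packaged runs

The test suite and the acceptance script use: exhaustive-enumeration
equivalence on series up to n = 18 with up to 3 breaks; 1000 Monte-Carlo
replicates of a single-break model (n = 100, mean shift equal to the noise
SD — the moderate-signal regime the asymptotic interval is derived for) for
CI coverage, observed ≈ 0.93 against the nominal 0.95; and 200 synthetic
subjects for threshold recovery. These sizes give stable estimates while
keeping a full run in seconds.

## Known limitations

* Exact numeric parity with any particular apparatus trace is not
  attainable from published material alone: the minimum-segment fraction,
  design matrix and BIC convention behind the original analysis are not
  reported. The defaults here are stated above precisely so results are
  reproducible going forward.
* The CI construction assumes homoskedastic errors; ventilation noise
  grows somewhat with intensity, so late-ramp intervals may be slightly
  optimistic.
* Half-grid published table entries (e.g. 105 W) cannot arise from the
  10-W staircase conversion and are reproduced only to within one tread.
* The AT-break selection rule (largest positive slope increase in the
  ramp) is a design choice; all candidate breaks are always reported so a
  different rule can be applied downstream.
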