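---
title: "Modelling noise-masked symmetry detection with symtvd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling noise-masked symmetry detection with symtvd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symtvd)
```

## The task and the model

The modelled task is yes/no detection of mirror symmetry: on each trial the
observer sees either a symmetric random-dot target superimposed on a
random-dot masker, or a density-matched non-symmetric control superimposed
on the same masker, viewed through eight 1.2° apertures on a 6° circle.
Two factors manipulate knowledge of the symmetry axis: *cueing* (the axis
orientation is indicated before the trial, or one of four orientations is
possible) and *axial salience* (the aperture ring either includes the axis
region or is rotated 22.5° so a blank arc of 3π/4 − 1.2 ≈ 1.16° surrounds
every candidate axis).

`symtvd` implements a two-stage density-domain account of this task.

**Perception stage.** For sparse binary patterns the linear drive of an
axis-tuned symmetry processor is proportional to dot density (each added
dot adds the same expected number of mirror-pair correspondences), so
excitation is `Se·D`. The channel response applies an expansive exponent
`p` and divisive inhibition. With the inhibitory exponent fixed at the
conventional `q = 2`, the external-noise variance (quadratic in masker
density) and the masker's divisive term merge, and the internal-noise
variance is absorbed into the additive constant, giving

$$R(D_t, D_b) = \frac{(S_{et} D_t + S_{eb} D_b)^p}
{(S_{it} D_t)^2 + (S_{ib} D_b)^2 + z'}$$

after which the response-scale noise SD is 1 by construction. This
*quadrature* grouping of the denominator is the package's canonical form.
Supporting evidence that it is the right reading: the asymptotic TvD
log-log slope it implies is `q/p = 2/p`, which for the bundled observers'
`p = 2.17–2.91` spans 0.69–0.92 — exactly the empirically reported slope
band (0.70–0.86). The alternative grouping
`(S_it·D_t + S_ib·D_b)^2 + z'` is retained behind
`channel_params(..., grouping = "linear")` for sensitivity analysis only.

**Decision stage.** The observer monitors `m` channels — one when cued,
four (one per candidate axis orientation) when not — and uses their
maximum. Two classical order-statistic facts enter: the mean of the max of
`m` matched channels is approximated by a fourth-power (Minkowski) sum,
and the SD of the max of four i.i.d. Gaussians is 0.70 times the
single-channel SD (the conventional rounded value 0.71 is used for γ, as
printed in the source analyses; `max_gaussian_sd_ratio()` computes the
exact 0.7012 by quadrature). Channels not tuned to the presented axis see
the whole display as a non-symmetric texture, so in the target interval
they take the control-style response at the same total density. Threshold
is the smallest `D_t` with `d' = 1`, solved by coarse bracketing plus
bisection on log density (bracket `[1e-6, 1]`, relative tolerance `1e-6`,
lower crossing kept on ties; unreachable criteria raise an error or are
flagged `NA` under `on_fail = "na"`).

## Parameters that matter

| parameter | meaning | units | default / range |
|---|---|---|---|
| `S_et` (4 values) | excitatory sensitivity to the symmetric component, per cue × salience | response per unit density | anchor 1000 at (cued, high) |
| `S_eb` | excitatory sensitivity to non-symmetric dots | same | free; poorly constrained (bundled sets span 0.10–270) |
| `S_it` (2 values) | target self-inhibition weight, per salience | same | free |
| `S_ib` | masker inhibition weight (absorbs external-noise variance) | same | free |
| `z'` | additive constant (absorbs internal-noise variance) | response² | free, searched `1e-4`–`1e4` |
| `p` | excitatory exponent | – | free in `[1, 5]`; bundled sets 2.17–2.91 |
| `q` | inhibitory exponent | – | fixed 2 |
| `m, n, γ` | monitored/responding channels, max-SD factor | – | cued (1, 1, 1); non-cued (4, 1, 0.71) |

Nine parameters are free per observer; `S_et(cued, high) = 1000` anchors
the response scale (only ratios of sensitivities are identifiable once the
noise SD is normalised).

## Properties of the model worth knowing

**Sub-unit TvD slopes.** Because `p > q = 2` for fitted observers, the
high-density limb rises with slope ≈ `2/p < 1`, against the unit slope
predicted by weight-of-evidence/signal-to-noise accounts
(`snr_predicted_slope()`, `compare_fixed_slopes()`).

**Double corners.** The three denominator terms (`z'`, masker inhibition,
target self-inhibition) can dominate in succession, producing two separate
slope increases. `double_corner_params()` ships an illustration set
(`S_et = 1000, S_eb = 5, S_it = 550, S_ib = 2000, z' = 0.04, p = 1.8`):
the first corner is the `z'` → external-noise transition near
`D_b = 1e-4`; the second is self-inhibition-driven — with `p < 2` the
target's own inhibition outgrows its excitation, steepening the curve
sharply before the threshold diverges (just beyond the recommended grid).
`find_tvd_corners()` detects the two slope-increase locations by
run-segmentation of the discrete slope increments.

**Component ablations.** Removing `z'` lowers only the low-density limb;
removing `S_it` alters only the high-density limb
(`tvd_curve(..., ablate =)`). Both behaviours are asserted in the test
suite on the illustration set, and the weaker one-sided claims on the
bundled observer CC.

**Uncertainty vs γ.** A counter-intuitive consequence of the reconstructed
decision stage: at fixed sensitivities, switching from cued (`m = 1,
γ = 1`) to non-cued (`m = 4, γ = 0.71`) *lowers* the threshold whenever
the control response is negligible, because dividing by γ < 1 helps while
the fourth-power pooling penalty vanishes as `R_c → 0`. With `γ = 1` the
pooling-only ordering (non-cued ≥ cued) holds. The observed 2–4-fold
cueing effect is therefore carried almost entirely by the fitted `S_et`
cue differences — which is precisely the substantive claim the nested
model comparison (`compare_nested()`) tests: collapsing `S_et` across cue
conditions (two fewer parameters) significantly worsens the fit whenever a
genuine cue effect is present.

**An anomalous bundled observer.** Under the canonical reconstruction the
LY parameter set (noise sensitivity `S_eb = 270` almost equal to its
non-cued low-salience target sensitivity 268) yields a masker-induced
facilitation dip of up to ~0.14 log units in two conditions and *no*
reachable `d' = 1` threshold in the non-cued low condition (maximum
attainable `d'` ≈ 0.53). The other three observers are monotone in all
conditions. The tests assert this computed behaviour rather than assuming
monotonicity everywhere.

## The synthetic-data generator

`generate_design()` reproduces the experiment's structure: the 2 × 2
cue × salience design, masker densities 0 and `10^-3.5 … 10^-1` in
half-log steps (covering "0 to 10%"), and per block 7–9 target densities
in 0.15-log steps centred on the generating model's threshold, as a
constant-stimulus method requires. Unreachable cells are flagged and
skipped. `simulate_observer()` produces binomial yes/no responses with a
per-block criterion midway between the two stimulus classes' expected
decision statistics, an optional lapse rate (default 0), and uniformly
random axis orientation per trial (carried for schema fidelity only — the
density-domain model is axis-blind by design).

**Decision rule choice (a deliberate deviation).** Two simulator rules are
provided. The default, `decision_rule = "gaussian"`, draws the decision
statistic as Gaussian with mean equal to the fourth-power pooled response
and SD γ — the exact distributional assumption under which the model's
`d'` and thresholds are defined — so simulated percent correct at the
model threshold equals Φ(d′/2) and the simulate → fit → recover loop
closes (recovery RMSE < 0.05 log units at 500 trials/level).
`decision_rule = "max"` draws the `m` channels as unit-SD Gaussians and
takes their maximum (criterion from Monte-Carlo expected maxima). The max
rule was the original design intention, but it is *not* consistent with
the fourth-power approximation at low response levels: for a max-of-4
observer with near-zero control response the approximation places
threshold at `R_t = γ = 0.71` while the true max rule needs
`R_t ≈ 1.59` (the approximation ignores the elevated mean of the noise
max, ≈ 1.03). That systematic ~0.16 log bias in non-cued conditions would
defeat any recovery criterion, so the approximation-consistent rule is the
default and the max rule is the instrument for *measuring* the
approximation error (`pooling_approximation_report()`).

**What a green test does and does not establish.** The generator emulates
the design's structure and binomial response noise under the generating
model; it does not emulate human lapses/sequential effects (unless a lapse
rate is set), criterion drift, learning, image-level variability
(rendering lives in the stimulus module and is validated separately via
reverse-mapping counts), or the true max-rule decision noise (unless
selected). Loop closure therefore establishes pipeline correctness —
thresholds and parameters are recoverable from finite binomial data when
the model is true — not the model's empirical adequacy for human data.

## Fitting choices

*Psychometric stage.* Maximum-likelihood Weibull on log10 target density
with guess rate 0.5 and a small fixed lapse (default 0.01, capped at
0.03). The threshold is read off at the percent-correct level
corresponding to the d′ criterion under an unbiased yes/no mapping,
`P = Φ(d'/2)` (the source analyses never state their mapping; the 2AFC
convention `Φ(d'/√2)` is available via `mapping = "2afc"`). Standard
errors by parametric bootstrap, default 200 replicates.

*Model stage.* Least squares on log10 thresholds (matching how fit
quality is conventionally reported, in log units), Nelder-Mead from 20
random multi-starts (fixed seed) in log10 parameter space with box
constraints (sensitivities `≤ 1e4`–`1e5`, `p ∈ [1, 5]`,
`z' ∈ [1e-4, 1e4]`), followed by a restarted-simplex polish.
Threshold-unreachable data points incur a fixed penalty (25 per point)
rather than aborting the search. A curvature probe flags near-flat
objective directions (`identifiability_warning`); `S_eb` is the usual
culprit, consistent with its 0.10–270 spread across bundled observers.
Because parameters can trade off, *threshold-surface* recovery is the
recovery criterion, not parameter recovery. Noiseless refits reach
RMSE < 0.01; with 0.08 log threshold noise the fitted RMSE concentrates
near `0.08·sqrt((N − 9)/N)` ≈ 0.063 for N = 24 points, so the recovery
suite accepts a median in [0.05, 0.11].

*Nested comparison.* `F = ((SSE_r − SSE_f)/Δdf)/(SSE_f/(N − p_f))` with
`Δdf = 2` for the cue-collapse reduction, cross-checked against the
textbook regression F in the tests.

## Numerical and interface decisions

- Quadrature for order statistics uses `stats::integrate` on the
  order-statistic density (rel. tol 1e-10); Monte Carlo sizes default to
  10^6 with seeded common random numbers. The uncertainty intensity ratio
  uses a quantile construction (per-trial minimal sufficient shift) that
  makes the Monte-Carlo estimate exact for the drawn sample and monotone
  in the target level.
- The two-interval equating rule gives an intensity ratio of 1.586 at
  `m = 4, d' = 1`; the criterion-based yes/no rule (switchable) gives
  1.586 as well. The commonly quoted 1.7 is not reproduced exactly by
  either rule; the package reports what it computes.
- Densities are serialised in linear units only; log views are computed on
  demand so `D_b = 0` rows survive round-trips.
- Config and parameter files are JSON (a YAML reader is not part of the
  package's dependency footprint); fixed (non-free) values are marked
  `"fixed": true` in parameter files.
- Stimulus grids live at dot resolution (one cell per 4′ dot) because all
  density arithmetic operates on dot counts; sub-dot rasterisation would
  only matter for display-accurate rendering, which is out of scope.
  Reflection for the four canonical axes is exact on the centred lattice;
  the general rotation-and-round path documents that a rounded reflected
  pair may collide and is then dropped.
- The blank-arc width uses the arc approximation (inter-centre arc minus
  one aperture diameter = 1.156°), matching the quoted 1.16°; exact
  circle-circle intersection geometry would give a slightly different
  number and is deliberately not used.

## Known limitations

- The package fits and simulates the density-domain model only; no
  image-domain (spatial-filter) front end is provided, by design.
- Human threshold data are not bundled; the bundled parameter sets stand
  in for observers, and all empirical statements in this vignette are
  limited to what the tests and the acceptance script themselves compute.
- The fourth-power pooling approximation is known-bad at low response
  levels (see above); conclusions about non-cued conditions near zero
  masker density inherit that approximation from the model definition.
- `S_eb` is weakly identified by TvD surfaces alone; fitted values should
  be interpreted with the `identifiability_warning` in mind.
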