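---
title: "Methods: stationarity-gated VAR analysis of daily diary series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stationarity-gated VAR analysis of daily diary series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaryvar)
```

## The problem and the model

Daily diary studies in psychosomatic medicine yield, per patient, a short
multivariate time series: a handful of visual-analogue-scale (VAS) items in
[0, 100], recorded once per day over an inpatient stay of roughly 40–230
days, with occasional missing days. The scientific question is directional:
does difficulty tolerating aversive emotion *precede* eating-disorder
symptoms day over day, or follow them? Single-subject vector autoregression
is the standard instrument for that question. For each pairing of the focus
item with a symptom item, on a stationary window of `T_w` days,

$$y_t = \nu + A_1 y_{t-1} + \dots + A_k y_{t-k} + u_t, \qquad
  u_t \sim (0, \Sigma_u),$$

with `y_t` bivariate. Granger causality is then the joint test of the `k`
cause-lag coefficients in the effect equation; impulse responses and the
forecast error variance decomposition (FEVD) describe the system's reaction
to shocks; and the contemporaneous (same-day) association lives in the
off-diagonal of `Σ_u` and in the window's Pearson correlation.

The model's assumptions, stated bluntly: linearity of the day-over-day
dependence, (covariance-)stationarity on the analysis window, serially
uncorrelated innovations, and an equally spaced daily grid. Every one of
these is checked or enforced by the pipeline rather than presumed — that is
the main design idea of the package.

## The chain and its tunables

| Stage | Function | Key defaults |
|---|---|---|
| Imputation | `impute_missing()` | deterministic, ≤ 25% missing per item |
| Unit-root gate | `adf_test()` | constant-only, Schwert max lag, α = 0.05 |
| Window scan | `find_stationary_window()` | step 7 d, `T_min` 30 d |
| Lag selection | `select_lag_order()` | `p_max = min(10, ⌊T_w/10⌋)` |
| Diagnostic loop | `fit_with_adjustment()` | Portmanteau `h = min(16, ⌊T_eff/4⌋)` |
| Granger test | `granger_test()` | `F(k, 2·T_eff − 4k − 2)` |
| Dynamics | `compute_irf()`, `fevd()`, `bootstrap_irf_bands()` | H = 10 d, B = 1000, Hall |
| Trends / correlation | `linear_trend()`, `same_day_correlation()` | plain OLS inference |

All of these are collected in `pipeline_config()`; α = 0.05 is used
uniformly.

**Imputation.** Each missing cell of item *j* is replaced by the
least-squares prediction from a regression of *j* on the other same-day
items plus a linear day term, fitted on fully observed rows (with a
row-specific predictor subset when a predictor is itself missing that day,
and a day-only fallback for all-missing days). Predictions are clamped to
[0, 100]; observed cells are never touched. A seeded draw from the residual
distribution can be added (`add_noise = TRUE`), but the default is the
conditional mean: for a reproducible pipeline, determinism was judged more
valuable than restoring the imputed cells' variance, and the stochastic
variant remains one flag away. Preconditions — at least 10 complete rows and
at most 25% missing per item — keep the regression from degenerating into
extrapolation.

**Stationarity gate.** The augmented Dickey–Fuller regression
`Δx_t = φ x_{t−1} + Σ β_j Δx_{t−j} + μ (+ δt) + ε_t` is fitted with the
augmentation order chosen by minimum AIC over `0..max_lags` on a common
sample; `max_lags` follows the Schwert rule `⌊12 (T/100)^{1/4}⌋`. P-values
use the MacKinnon response-surface polynomials (the same published constants
other implementations embed), so rejection means stationarity at the stated
level. The deterministic-terms default is constant-only: under
stationarity, diary items have no a-priori deterministic trend, and a
trend-inclusive variant is available by flag for sensitivity analysis.
Constant series and series shorter than 16 usable points are refused as
degenerate rather than returning a number that means nothing.

**Window determination.** The workflow this automates traditionally
involves a human looking at the plot. To make it reproducible, the package
scans candidate windows whose start and end offsets move on a 7-day grid,
keeps those of at least `T_min = 30` days, and returns the *longest* window
on which both focus items reject the unit root, ties broken toward the
earliest start; the full stay is always tried first and wins when it
qualifies. Two properties follow by construction and are asserted in the
test suite: the returned window always passes the ADF gate, and raising
`T_min` can never lengthen the chosen window. One empirical caveat,
documented because it surprised us: a short random-walk prefix (up to ~2–3
weeks) embedded at the start of an otherwise long stationary window is often
statistically invisible to the ADF test, so the scan may trim only part of a
non-stationary adaptation phase. Per-patient manual overrides
(`window_overrides`) therefore take precedence over the scan.

**Lag selection and the diagnostic loop.** All candidate orders `1..p_max`
are fitted on the same effective sample (first `p_max` observations
reserved), and AIC, FPE, Hannan–Quinn and Schwarz are computed from the ML
residual covariance with their standard penalties. The consensus is the
majority order, ties resolved toward parsimony; the Schwarz choice can never
exceed the AIC choice (penalty ordering), which the suite asserts as an
invariant. Estimation then starts at the consensus order and, while the
adjusted (small-sample) multivariate Portmanteau test rejects white-noise
residuals or any companion eigenvalue modulus reaches 1, the order is
incremented up to `p_max`. The adjusted Portmanteau variant was chosen
because diary windows are short; every step of the loop is recorded in an
adjustment log so the re-estimation path is auditable. If no order passes,
the pair is excluded with that reason — mirroring how unanalysable diaries
are handled in practice — never silently dropped.

**Granger degrees of freedom.** The bivariate F reference is
`F(k, 2·T_eff − 4k − 2)` with `T_eff = T_w − k`. Conventions in the
literature sometimes state this formula with "T" meaning the raw window
length; reproducing the printed degrees of freedom of the worked examples
this package is validated against requires the effective-sample-size
reading, which is therefore used and pinned by eleven fixture rows in the
acceptance suite.

**Orthogonalisation and ordering.** Same-day correlation makes plain
impulse responses ambiguous, so orthogonalised responses `Θ_i = Φ_i P` use
the lower Cholesky factor of `Σ_u` under a variable ordering. The ordering
is chosen from the data where the data can speak: the variable that
Granger-causes the other (exactly one significant direction) is placed
first. When neither or both directions are significant the canonical item
order is used and a warning is raised, because the orthogonalised quantities
then rest on an arbitrary choice; reports flag which ordering produced every
orthogonalised number, and both plain and orthogonalised accumulated
responses are emitted rather than guessing which one a reader wants.

**Bootstrap bands.** Residual-based recursive bootstrap: centred residuals
resampled with replacement, series rebuilt from the fitted model with the
original first `k` values, re-estimation at the same order, IRF recomputed.
The default interval is Hall's bias-correcting percentile interval
`[2θ̂ − q*₁₋α/₂, 2θ̂ − q*α/₂]`; a plain percentile interval is available.
Note one deliberate subtlety: the plain percentile interval always contains
the point estimate, the Hall interval need not — the suite asserts
containment only for the percentile type. Replicates whose re-estimation
fails are dropped and counted, and more than 10% failures aborts the
computation instead of returning bands built on a biased subset. B defaults
to 1000; the number is not prescribed by any source and was set high enough
that band endpoints are stable to well under the visual resolution of an
IRF plot.

**Descriptives.** The standardised trend coefficient is computed as the
Pearson correlation between the series and the day index (the algebraic
identity for a standardised simple regression, asserted to 1e-12), with
plain OLS t inference on `T − 2` degrees of freedom. No serial-correlation
correction is applied by default, matching the convention of the table
layout it reproduces; users who want robustness can regress with their own
HAC machinery on the raw series. Trends use the full participation period;
same-day correlations use the VAR analysis window.

## What the synthetic generator emulates — and what it does not

`generate_diary()` simulates a stationary VAR(k) with Gaussian innovations
(200-step burn-in discarded), adds linear trends centred on the stay's
midpoint, maps each item affinely onto the VAS anchor (mean 50, SD 15 by
default — mid-scale with enough headroom that clipping stays rare), clips to
[0, 100], and deletes cells completely at random. The anchor defaults are a
judgement call of what a realistic diary looks like: means near mid-scale
and day-to-day dispersion wide enough to be informative but narrow enough
that floor/ceiling contact is the exception; a warning fires when clipping
touches more than 5% of cells, the regime where the linear-VAR reading of
the data starts to fail. The marginal SD is anchored through the theoretical
Yule–Walker covariance (companion-form Lyapunov equation), so the mapping is
exact, not estimated; the generator returns that covariance as part of the
ground truth and the suite checks the simulated lag-1 cross-covariance
against it.

The scenario suite (`make_benchmark_suite()`) states the regimes the
pipeline must tell apart: no coupling; contemporaneous-only correlation
(Σ off-diagonal 0.5); unidirectional coupling (`A[2,1] = 0.4`);
bidirectional coupling; trend plus coupling; a 40-day random-walk adaptation
prefix before a stationary phase; and short (39-day) and long (231-day)
stays spanning the observed participation range.

What a green test on synthetic data does **not** establish: robustness to
heavy-tailed or skewed responses, to measurement reactivity, to weekly
rhythms or therapy-event interventions, or to missingness that depends on
symptom state (the generator's missingness is MCAR). Gaussian innovations
and MCAR were chosen as the simplest mechanisms consistent with everything
the emulated design states; heavier-tailed innovations would be the first
extension for robustness work.

## Numerical choices and degenerate inputs

- Multivariate LS is solved by QR; rank deficiency (constant or collinear
  series) raises a classed error instead of producing unstable numbers.
- `Σ_u` uses the degrees-of-freedom-adjusted denominator `T_eff − Kk − 1`;
  per-coefficient t-ratios use the same denominator. Lag-selection criteria
  use the ML (unadjusted) covariance, as their penalty forms assume.
- Information-criterion ties, consensus ties, and window-length ties all
  break toward parsimony / the earliest start — deterministically.
- All randomness (imputation noise, generator, bootstrap) is scoped under
  explicit seeds and restores the caller's RNG state; identical inputs and
  seeds give byte-identical reports.
- Errors are classed conditions (`diaryvar_*_error`) so pipelines can
  distinguish validation, exclusion and hard failure — the CLI maps these to
  exit codes 1/2/3.

## Known limitations

- Only bivariate causal systems: the F-reference degrees of freedom are
  bivariate-specific, and the orthogonalisation logic orders two variables.
- No cointegration/VECM path: a pair that is jointly non-stationary is
  excluded, not differenced or error-corrected.
- The window scan optimises window *length*, not evidence strength; two
  windows of equal length are distinguished only by start day.
- OLS trend inference ignores serial correlation; standardised trend
  coefficients on autocorrelated series have optimistic p-values.
- The ADF gate has limited power against short non-stationary prefixes (see
  above) and against near-unit-root stationarity generally.
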