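---
title: "Coercively adjusted autoregression: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coercively adjusted autoregression: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caar)
```

## The forecasting problem

Single-channel epilepsy EEG segments are nonlinear, nonperiodic, and live
close to (or beyond) the unit-root boundary of autoregressive dynamics.
Classical AR(p) forecasting

$$x_t = c + \sum_{i=1}^{p} \varphi_i x_{t-i} + \varepsilon_t$$

estimates the coefficients $\varphi_i$ by Yule-Walker or least squares and
assumes a stationary, linear generating process. Near $|\varphi| = 1$ the
finite-sample behaviour of $\hat\varphi$ is poor: the limiting law changes
character at the unit root, and the Yule-Walker estimator in particular is
biased toward stationarity exactly where EEG-like signals live.

The coercively adjusted autoregression (CA-AR) gives up on estimating the
coefficient *magnitudes* entirely. Every coefficient is coerced to
$\pi_{t,i} \in \{-1, +1\}$ with the first lag pinned at $\pi_{t,1} = +1$:

$$x_t = c + \sum_{i=1}^{p} \pi_{t,i}\, x_{t-i} + \varepsilon_t .$$

The time subscript matters: the sign pattern is re-selected at every
forecast origin, so the model tracks regime changes with a memory of only
a few samples.

## How the signs are chosen

The coercion and the least-squares principle do not by themselves pin
down a selection algorithm. This package operationalizes them as an
**exhaustive least-squares sign search**, the minimal procedure
consistent with the model statement:

* at forecast origin $t$, form the $W$ most recent one-step pairs
  (targets $x_s$ with regressors $x_{s-1},\dots,x_{s-p}$,
  $s = t-W,\dots,t-1$);
* for each of the $2^{p-1}$ admissible sign vectors, the least-squares
  intercept has the closed form
  $\hat c(\pi) = \frac1W \sum_s \bigl(x_s - \sum_i \pi_i x_{s-i}\bigr)$;
* the candidate minimizing the residual sum of squares wins, with ties
  broken to the lexicographically smaller vector (+1 before −1, lag 2
  most significant), so runs are bit-reproducible.

The fit window defaults to $W = p$, so that an order-5 forecast of
sample 481 draws on no more than samples 476–480 for its regressors; no
single windowing convention is canonical for this model family, so $W$
is an explicit parameter. The intercept is re-estimated jointly with the
signs at every origin: $c$ is part of the model and fixing it at zero
would be an extra assumption, while re-estimating it buys translation
equivariance (adding a constant to the
series shifts every forecast by exactly that constant). The price is a
forecast-variance inflation of $\sigma^2 / W$, visible in the head-to-head
experiment below. A guard refuses $p > 20$ (over $5 \cdot 10^5$ candidates
per step) unless forced.

`select_signs()` is validated against an independent brute-force
enumeration (plain nested loops) for all $p \le 6$; noiseless paths
generated from the model itself (`gen_caar()`) are recovered exactly —
signs equal, $|\hat c - c| < 10^{-9}$, rolling RMSE below $10^{-9}$.
Identifiability fixtures use sign patterns with characteristic roots on
the unit circle (alternating patterns): strongly explosive patterns grow
so fast that double-precision cancellation, not the method, dominates the
residuals.

## Choosing the order: box-counting fractal dimension

The order $p$ is the only structural parameter. It is chosen as the
**round-up (ceiling) of the average box-counting slope of the
delay-coordinate phase space** of the designated *normal* signals — the
order must capture the baseline dynamics that abnormal activity departs
from; which signals count as normal is the caller's decision
(`select_order()` takes whatever collection it is given). The ceiling of
an exact integer is that integer (no bump).

Two box-counting flavours are implemented:

* **Curve counting** (`box_count_curve()`): the signal is the polyline
  $\{(t, x_t)\}$, $t$ in raw 1-based sample-index units and amplitude in
  raw signal units, linearly interpolated. For each grid size
  $\varepsilon$ the counter enumerates every cell touched by the
  interpolant (segment–cell intersection, not sample-point occupancy: the
  measured object is a curve).
* **Point counting** (`box_count_points()`): a delay-coordinate cloud
  $V_t = [x_t, x_{t-\tau}, \dots, x_{t-L\tau}]$ occupies the hypercubes
  containing at least one vector. Phase-space slopes may legitimately
  exceed 2.

Conventions that make the counts reproducible and testable:

* cells are **half-open** per axis, so every point belongs to exactly one
  cell; the grid is **anchored at the bounding-box minimum corner**
  (per-axis minima for point clouds), so counts are translation-stable;
* all coordinates are transformed to grid units
  ($u = (t - t_0)/\varepsilon$, $v = (x - x_0)/\varepsilon$) before
  counting, so cell boundaries are exact integers and the fast counter
  agrees *exactly* with a dense-sampling oracle — an equality the test
  suite asserts on every instance up to 200 samples;
* indices are clamped to the bounding box, because interpolation at a
  clipped piece boundary can overshoot the exact extreme by one ulp.

The default grid ladder is $0.1 \cdot 2^k$, $k = 0..16$ — from 0.1 to
10000 in multiplications of 2 (6553.6 is the largest size not exceeding
10000). The ladder is absolute, which only makes sense against raw
units; `normalize = TRUE` rescales a curve into a 4096 × 4096 box for
unit-free use.

A box-count scan always shows saturation plateaus (every box occupied at
tiny $\varepsilon$ relative to the sampling; one box at huge
$\varepsilon$). The visual practice of reading "the slope of the linear
part" is formalized in `fit_dimension()` as the contiguous window of at
least 5 ladder points maximizing $R^2$, ties to the longer window and
then to smaller sizes. The policy can be overridden (`"full"` or an
explicit index pair).

Calibration fixtures pin the estimator down: a straight line must come
out near 1; i.i.d. uniform samples embedded in the plane near 2; and the
Weierstrass function $W(t) = \sum_k a^k \cos(b^k \pi t)$ (with
$a = 0.7$, $b = 3$) has closed-form graph dimension
$2 + \ln a / \ln b \approx 1.675$. The Weierstrass curve was chosen over
fractional Brownian motion because it is deterministic and its dimension
is exact; at 4096 samples the estimate lands within the documented
$\pm 0.2$ of theory, limited by the handful of ladder octaves between
the sampling scale and the curve span.

## Diagnostics

`real_cepstrum()` computes the *real* cepstrum — inverse DFT of the log
magnitude spectrum of the mean-removed signal. Only peak positions are
inspected, so phase (the complex cepstrum) is unnecessary. Spectral
magnitudes below $10^{-12}$ of the maximum are floored before the log;
no taper is applied by default (exposed as an option). A periodic
component of period $q$ produces peaks at quefrency $q$ *and all its
multiples* (rahmonics) — for exactly periodic fixtures those peaks have
equal height, so the reported fundamental is the smallest quefrency
attaining the band maximum (relative tolerance $10^{-6}$), not a bare
argmax. No universal significance rule exists for cepstral peaks; here a
peak counts as significant when it exceeds the median plus five MADs of the
in-band cepstrum: robust, scale-free, and calibrated in the test suite to
hold the false-positive rate on white noise below 5%. A single noisy
sinusoid is a weak cepstral target (one partial, no harmonic series);
the detector is designed for repeated-pattern signals such as impulse
trains and harmonic-rich waveforms.

`lag_pairs()` returns the lag-plot scatter and the biased
($1/n$-normalized) sample autocorrelation. `randomness_verdict()`
formalizes the by-eye lag-plot reading as an explicit test: "random" iff
$|\hat\rho_L| < 2/\sqrt{n}$ at every requested lag. This is an
operationalization, not a claim about the original visual procedure.

## The evaluation harness

All experiments are **rolling one-step forecasts**: sample $t$ is
predicted from observed values through $t - 1$, the origin advances, and
the RMSE aggregates the per-step errors. `caar_forecast()` also offers a
recursive mode that feeds its own predictions back when actuals are
unavailable.

Baselines:

* **Standard AR**, refit at every origin on the trailing window (default:
  all history to date). The default estimator is **Yule-Walker** — the
  estimator presented as standard for this model family — with
  conditional least squares available (`method = "ls"`). A refit that
  fails numerically yields `NaN` predictions rather than an error, so
  comparisons over many replicates keep running.
* **Nearest-neighbour analogue forecasting** (`nn_forecast()`): the
  trailing window of length $m$ is matched against every historical
  window inside a training span that grows by one sample per step; the
  best match's successor is the prediction, ties to the earliest match.
  Nearest-neighbour forecasters differ in the neighbour count and
  weighting; the simplest variant ($k = 1$, unweighted) is implemented.
  The window length defaults to the CA-AR order for a like-for-like
  regressor span.

`compare_models()` runs a list of model specifications over one split and
emits a fixed-column table (model, order, window, start, horizon, rmse).

## The synthetic generators and what the experiments show

`simulate_rc_process()` realizes the random-coefficient autoregression
$x_t = \sum_i \phi_{t,i} x_{t-i} + \varepsilon_t$ with
$\phi_{t,i} = \pm\theta$ drawn from the two-point law
($+\theta$ with probability $\alpha$), the recursion whose $\theta = 1$
solutions are the sign-flipped accumulated-noise generalizations of the
random walk. Direct computation from that law gives
$E(\phi) = \theta(2\alpha - 1)$ and
$\mathrm{Var}(\phi) = 4\alpha(1-\alpha)\theta^2$, which the simulator's
realized signs reproduce empirically. Signs can be drawn once per
realization (`sign_mode = "fixed"`) or i.i.d. at every step
(`"per_step"`); `first_sign_positive = TRUE` pins the lag-1 sign to +1.

The head-to-head experiment simulates 50 replicates at
$\theta = 1$, $p = 3$, noise sd 0.1, $n = 600$, with signs fixed over
time, the lag-1 sign positive, and $\alpha = 0.5$ (up and down jumps
equally likely) — the process class the CA-AR forecaster itself spans,
which is the point: on its own model class the method should dominate a
standard AR that must estimate magnitudes. Each replicate runs 100
rolling forecasts for CA-AR ($p = 3$, $W = 3$) and for a Yule-Walker AR(3)
refit each origin on all history. CA-AR wins the large majority of
replicates (the acceptance criterion asks for at least 40 of 50; at these
study seeds it scores 46). Two honest caveats, both reproducible from the
code:

* Against a **least-squares** AR baseline the dominance disappears: OLS
  is efficient on these nonstationary processes, recovers the ±1
  coefficients with error vanishing faster than $1/\sqrt{n}$, and does
  not pay CA-AR's $\sigma^2/W$ intercept-estimation premium. The
  advantage of coercion is specifically over the Yule-Walker estimator,
  whose stationarity bias is severe at the unit root. Both baselines are
  exposed.
* The all-plus sign pattern at $p = 3$ is explosive (growth
  $\approx 1.839^t$); by $n = 600$ sample magnitudes reach $10^{60}$ and
  beyond, where the additive noise is below double-precision resolution.
  Errors there are dominated by representable-precision effects for both
  forecasters (CA-AR's exact ±1 arithmetic still incurs the smaller
  error). RMSEs from such replicates are reported as computed.

What these generators deliberately do **not** emulate: real EEG
phenomenology — spike-wave morphology, 1/f spectra, artifacts,
nonstationary variance. Passing the synthetic experiments shows the
estimators and the search are correct and that coercion beats
magnitude-estimation on the matched model class; it does not certify
forecasting skill on clinical recordings, which require the external
corpus these tools are designed to read (`read_segment()`, one value per
line, optionally 173.61 Hz).

## Numerical choices and problem sizes

* Generators take explicit integer seeds and restore the caller's RNG
  state; every stochastic result is a pure function of its arguments.
* `gen_ar()` checks stationarity via the characteristic roots (refusing
  moduli $\le 1$ unless disabled), initializes at the process mean and
  discards a 500-sample burn-in by default.
* Spectral flooring at $10^{-12}$ of the peak; sign-search and
  window-fit tie-breaks are deterministic; box-count cell indices are
  computed in grid units and clamped to the bounding box.
* Default experiment sizes — 4096-sample curves, 20001-point clouds,
  5000-sample AR fits with 20 replicate seeds, 50 head-to-head
  replicates with 100-step horizons — were chosen so each calibration
  quantity's sampling error is small against its acceptance band while a
  full run of the suite stays in the tens of seconds.

## Known limitations

* The sign search is exponential in $p$ (guarded at $p = 20$); the
  method is intended for the small orders the fractal-dimension rule
  produces.
* The cepstrum detector needs a harmonic-rich signal; a lone noisy
  sinusoid near the detection floor can be missed.
* Curve box counting at sizes far below the sampling resolution measures
  the polyline (dimension 1), not the underlying continuous signal; the
  auto range fit usually excludes that regime but cannot manufacture
  octaves that the data does not span.
* With `per_step` signs and $\theta = 1$ at orders $p \ge 2$ the
  simulated process is explosive in distribution; long realizations
  overflow double precision. Use short lengths or `fixed` signs with
  unit-root patterns for long fixtures.
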