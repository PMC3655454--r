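# caar — coercively adjusted autoregression for nonperiodic time series

`caar` is an R package and command-line tool for forecasting nonlinear,
nonperiodic single-channel biomedical signals — the motivating case is
epilepsy EEG, where the dynamics sit at or beyond the unit-root boundary
and classical autoregressive coefficient estimates behave badly.

## The method

A standard AR(p) model

    x_t = c + φ₁ x_{t−1} + … + φ_p x_{t−p} + ε_t

estimates the coefficients φ by Yule-Walker or least squares. The
**coercively adjusted AR (CA-AR)** forecaster instead coerces every
coefficient to ±1, with the first lag pinned at +1:

    x_t = c + Σᵢ π_{t,i} · x_{t−i} + ε_t ,   π_{t,i} ∈ {−1, +1},  π_{t,1} = +1.

At every forecast origin the sign pattern and intercept are re-selected
by an exhaustive least-squares search over the 2^(p−1) admissible sign
vectors, scored on a short trailing window (default length p). The model
order p is chosen as the ceiling of the average **box-counting fractal
dimension** of the delay-coordinate phase space of the designated normal
signals. Cepstrum and lag-plot diagnostics characterize periodicity and
randomness before modelling; the evaluation harness runs rolling
one-step forecasts with RMSE against standard-AR and nearest-neighbour
baselines.

## Worked example

Simulate a ±1-coefficient process (the CA-AR model class), compare CA-AR
against a Yule-Walker AR(3) refit each origin and a nearest-neighbour
baseline over 100 rolling forecasts, and estimate a fractal dimension:

```r
library(caar)

cfg <- rc_sim_config(theta = 1, alpha = 0.5, order_p = 3, noise_sd = 0.1,
                     length = 600, seed = 42)
x <- simulate_rc_process(cfg, sign_mode = "fixed", first_sign_positive = TRUE)
attr(x, "signs")
#> [1]  1  1 -1

compare_models(x, list(list(model = "caar", p = 3),
                       list(model = "ar",   p = 3),
                       list(model = "nn",   m = 3)),
               start = 501, horizon = 100)
#>   model order window start horizon      rmse
#> 1  caar     3      3   501     100 0.1248668
#> 2    ar     3     NA   501     100 1.4310184
#> 3    nn    NA      3   501     100 1.1379637

box_count_curve(gen_weierstrass(0.7, 3, length = 4096), normalize = TRUE)
#> <caar_box_count> (curve) 17 sizes in [0.1, 6553.6]
#>   dimension 1.5291 (R^2 0.99998, fitted on sizes 8..12)
```

The generating process here has true signs (+1, +1, −1) held fixed and
noise sd 0.1: CA-AR re-discovers the signs at every origin and forecasts
with RMSE 0.125 — close to the noise floor — while the refit Yule-Walker
AR(3), biased toward stationarity on this unit-root-type process, is an
order of magnitude worse (1.43). The Weierstrass graph (a = 0.7, b = 3)
has closed-form dimension 2 + ln 0.7 / ln 3 ≈ 1.675; the box-counting
estimate over the default 0.1…10000 doubling ladder lands at 1.53,
within the estimator's documented ±0.2 calibration band.

The same workflow is scriptable from a shell via the installed `exec/caar`
entry point:

```sh
caar simulate --kind sine --period 50 --length 1000 --seed 1 --out s.txt
caar diagnose --in s.txt --cepstrum --lag 1,20 --out-prefix s
caar dimension --in s.txt --mode curve --normalize --out s_dim.csv
caar forecast --in s.txt --model caar --order 5 --start 901 --horizon 100 --out fc.csv
```

Every output file begins with `#` comment lines recording the tool
version, parameters and seed, so any run can be reproduced byte-for-byte
from its own header.

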