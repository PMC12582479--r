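# thermoload

Bayesian state–space decomposition of psychophysiological time series
recorded under repeated temperature steps.

## The problem

In climate-chamber protocols where participants shuttle between two
rooms held at different temperatures, every recorded signal — subjective
fatigue (VAS), mean skin temperature, heart rate, log HF and log LF/HF
of heart-rate variability — superimposes three processes: a slow drift
that happens simply because hours pass (present even in the control
condition), the immediate, transient response to each room change, and
the quantity of actual interest: a slowly accumulating
psychophysiological *load* specific to the temperature-step regime.
`thermoload` is for researchers in environmental physiology and
biostatistics who need to separate these components, compare conditions
by credible intervals, and forecast the response to further steps.

## The model

For condition $n$ at time point $t$ on the measurement grid
($a$ = control, $b, c, d$ = 5, 10, 15 °C steps):

```
y[t,a] = Base[t]                         + eps[t,a]
y[t,n] = Base[t] + Load[t,n] + Env[t,n]  + eps[t,n],   n in {b,c,d}
eps[t,n] ~ Normal(0, sigma_n)

Base[t] = 2 Base[t-1] - Base[t-2] + Normal(0, sigma_B)
Load[t,n] = 2 Load[t-1,n] - Load[t-2,n] + Cauchy(0, sigma_L)
Env[t,n] = -h * sum(Env[t-N+1 .. t-1, n]) + Normal(0, sigma_E)
```

Base and Load are second-order random walks (smooth local linear
trends; the Cauchy innovations let Load take occasional large steps);
Env is a damped zero-sum seasonal component whose period `N` is the
number of grid points per room cycle.  A prediction variant (Normal
Load innovations, `h = 1`) supports fitting the first three room cycles
and forecasting the fourth.  Inference is by a partially collapsed
blocked Gibbs sampler (joint Gaussian state draws; scale updates
slice-sampled against state-marginalized likelihoods), implemented in
RcppArmadillo.  Convergence is monitored with rank-normalized split
R-hat and bulk ESS.

The package also ships the measurement-protocol model (grids of 23
HRV, 34 skin-temperature and 31 VAS points per session), preprocessing
of raw streams (weighted mean skin temperature; Burg maximum-entropy
LF/HF band powers of the R-R tachogram with 30-s rest-window
exclusion), and a synthetic-data generator with known ground truth.

## Worked example

```r
library(thermoload)

grid  <- build_grid(default_protocol(), "hf")   # 23 points, period 6
truth <- generate_dataset("step_load", grid, seed = 1)
fit   <- thermoload(truth$y, chains = 4, warmup = 500, sampling = 500,
                    seed = 2)
print(fit)
#> Base/Load/Environment decomposition (cauchy Load noise)
#>   T = 23, period = 6, 4 chains x (500 warmup + 500 sampling)
#>   max R-hat 1.010, min bulk ESS 375 over 8 hyperparameters

summary(fit)[, c("parameter", "mean", "2.5%", "97.5%", "rhat", "ess")]
#>           parameter   mean    2.5%  97.5% rhat  ess
#>  sigma_obs[T_26-26] 0.0928 6.8e-02 0.1294    1 1614
#>  sigma_obs[T_26-31] 0.0677 1.1e-02 0.1266    1  440
#>  sigma_obs[T_26-36] 0.1106 5.4e-02 0.1760    1 1176
#>  sigma_obs[T_21-36] 0.0771 1.6e-02 0.1336    1  763
#>          sigma_base 0.0054 1.0e-04 0.0228    1  936
#>          sigma_load 0.0012 2.1e-05 0.0053    1  529
#>           sigma_env 0.0419 5.4e-03 0.0807    1  375
#>                   h 0.7956 7.2e-01 0.8644    1 1370

b <- credible_band(fit, "load", "T_26-31", level = 0.5)
c <- credible_band(fit, "load", "T_26-36", level = 0.5)
compare_conditions(b, c, at = 23)
#> [1] "separated"
```

The observation scales are recovered around their generating value
(0.1), the damping coefficient around 0.8, and the final-time Load
estimates (0.18, 1.79, 2.05 for the three step conditions) track the
simulated truth (0.14, 1.88, 2.16); the 50% credible intervals of the
5 °C and 10 °C-step Loads are disjoint at the final time point, so the
conditions are declared separated.  `plot(fit, "load")` draws the shaded 50%/95% Load bands per
condition, and `forecast_sections(y, split = 19)` fits the prediction
variant to the first three room cycles and reports held-out predictive
coverage for the fourth.

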