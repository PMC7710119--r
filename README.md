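# sbinn — systems-biology-informed neural networks in R

Kinetic models in systems biology are ODE systems
`dx/dt = f(x, t; p)` with many unknown parameters and few, noisy,
partially-observed measurements. **sbinn** trains a neural surrogate
`x_hat(t; theta)` of the full trajectory whose loss enforces both the
scattered observations and the ODE residuals at collocation points,

```
L(theta, p) = L_data(theta) + L_ode(theta, p) + L_aux(theta),
```

so that minimizing `L` by full-batch Adam *simultaneously* reconstructs the
hidden (unobserved) species, estimates the kinetic parameters `p`, and —
for forced systems — infers hidden exogenous drivers such as meals. The
surrogate's time derivative in `L_ode` is computed analytically through
every network layer. A Fisher-information toolkit (Cramér–Rao standard
deviations, parameter correlation matrices, null-eigenvector reports)
diagnoses which parameters the design can identify at all.

The package ships three benchmark systems with synthetic-data generators:

| system | states | parameters | observed | time |
|---|---|---|---|---|
| `glycolysis_model()` — yeast glycolytic oscillator | 7 | 14 | NADH, ATP | 0–10 min |
| `apoptosis_model()` — caspase cascade, survival/death bistability | 8 | 9 | effector caspase | 0–60 h |
| `ultradian_model()` — glucose–insulin with meal forcing | 6 | 20 | glucose | 0–1800 min |

Who it is for: modelers who have an ODE model and sparse time-series
observations and want joint state/parameter inference with an explicit
identifiability diagnosis, without adjoint solvers or MCMC.

## Worked example

Recover the decay rate of `dx/dt = -p x` from 50 noiseless observations,
with `p` unknown (true value 1):

```r
library(sbinn)

toy <- ode_system("toy", "x", "rate", p_nominal = 1.0, x0 = 1,
                  time_domain = c(0, 3), observable_indices = 1,
                  rhs = function(x, t, p) -p[1] * x,
                  output_magnitudes = 1,
                  jacobian = function(x, t, p)
                    list(Jx = matrix(-p[1], 1, 1), Jp = matrix(-x[1], 1, 1)))
dat <- make_dataset(toy, n = 50, noise_level = 0, seed = 1)
cfg <- sbinn_config(depth = 2, width = 16, features = c("t", "exp(-t)"),
                    t_scale = 3, output_scales = 1)
fit <- sbinn(toy, dat, config = cfg,
             schedule = sbinn_schedule(stage1 = 500, stage2 = 3000,
                                       n_ode = 100), seed = 1)
coef(fit)
#>    rate
#> 0.99904
```

The inferred rate is within 0.1% of the generating value. The same
interface drives the benchmarks; for example a desk-scale glycolysis run
and its identifiability report:

```r
sys <- glycolysis_model()
dat <- make_dataset(sys, n = 500, noise_level = 0, seed = 7)
cfg <- sbinn_config(depth = 3, width = 32,
                    features = c("t", paste0("sin(", 1:6, "t)")),
                    t_scale = 10, feature_scale = 10,
                    output_scales = sys$output_magnitudes)
w <- normalized_weights(sys, dat, cfg)
fit <- sbinn(sys, dat, config = cfg, w_data = w$w_data, w_ode = w$w_ode,
             w_aux = w$w_aux, schedule = sbinn_schedule(8000, 9000), seed = 7)
summary(fit)          # target vs inferred table with relative errors
predict(fit, seq(0, 10, 0.1))   # full-state reconstruction, incl. hidden species

fim(sys, n = 500, noise_level = 0.1)   # Cramer-Rao bounds, correlations,
                                       # null eigenvectors of the design
```

`run_case("glycolysis_noiseless")`, `run_case("apoptosis_survival")`,
`run_case("ultradian_hidden_test1")`, … execute the full benchmark
experiments end-to-end (data generation, training, FIM report, forecast)
at either the full benchmark schedules (`scaled = FALSE`) or desk-scale presets.
Parameter recovery accuracy depends strongly on the training budget; the
full benchmark schedules run to 10^5–10^6 Adam iterations, and the desk-scale
presets trade accuracy for minutes of runtime (see the methods vignette,
`vignettes/sbinn-methods.Rmd`).

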