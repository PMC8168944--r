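# cascadesim

Latent coupled-logistic disease progression modelling and in-silico
amyloid-lowering trial simulation.

## The problem

Alzheimer's disease unfolds over decades, but longitudinal cohorts observe
each person for only a few years, through heterogeneous instruments:
regional amyloid-PET and FDG-PET uptake, regional grey-matter density, and
neuropsychological scores.  Anti-amyloid trials keep failing in symptomatic
patients, and the key design questions — *when* must amyloid be lowered,
by *how much*, and with *how many* subjects per arm, to obtain a
statistically powered clinical effect? — cannot be answered by descriptive
progression models that lack a dynamical law.

`cascadesim` addresses this for modellers and trial statisticians.  It
compresses each data modality into a single interpretable severity
coordinate, learns the dynamical couplings between those coordinates from
short observation windows, reconstructs the full multi-decade disease
course, and then perturbs the dynamics to simulate intervention
strategies.

## The model

Each subject's measurements at a visit, grouped into M modality blocks
`x_m` (canonically amyloid `amy`, metabolism `met`, atrophy `atr`,
clinical `cli`), are noisy decodings of an M-dimensional latent state
`z(t)` of modality z-scores:

    x_m(t) ~ N( mu_m(z_m(t)),  sigma_m^2 ),      m = 1..M

Each z-score follows a coupled logistic ordinary differential equation,

    dz_m/dt = k_m z_m (1 - z_m)  +  sum_{j != m} alpha_mj z_j
            = (W z - V z^2)_m,

where `k_m` is the modality's intrinsic progression rate (1/year), the
couplings `alpha_mj` encode how pathology in one modality drives another
(the amyloid-cascade hypothesis corresponds to positive couplings flowing
out of `amy`), `W` carries the rates on its diagonal and the couplings
off-diagonal, and `V = diag(k)`.  All parameters — modality-wise
encoders and decoders, noise variances, rates and couplings — are
estimated jointly by stochastic variational inference with exact
reverse-mode gradients through a fixed-step RK4 integrator.

The fitted model supports:

* **Long-term trajectory synthesis** — a Gaussian mixture (AIC-selected
  over component count and covariance structure) over the latent states
  of dementia patients is sampled, each draw integrated forward and
  backward, and the ensemble anchored so that t = 0 is clinical
  conversion.
* **Staging** — a subject's time-shift `tau` is the grid time minimizing
  the L1 distance between their encoded z-scores and the reference
  trajectory, with any subset of modalities present.
* **Trial simulation** — an intervention multiplies the vector field by
  `Gamma = diag(gamma_1..gamma_M)` from the intervention start onward
  (`gamma_amy = 0` is 100% amyloid lowering, `0.5` is 50%); two-arm
  trials with Welch t-tests on decoded clinical endpoints at conversion
  map statistical power over intervention time, dose and sample size.

A fully seeded synthetic-cohort generator (`canonical_config()` /
`generate_cohort()`) emulates an ADNI-like amyloid-positive cohort with
known ground truth, so the entire pipeline is testable without any
controlled-access data.

## Worked example

```r
library(cascadesim)

gen   <- generate_cohort(canonical_config(seed = 1))   # 300 subjects
model <- fit_model(gen$cohort, gen$config$schema,
                   canonical_training_config(seed = 1))
model
#> <cascade_model> objective 2725.56
#> <cascade_dynamics> M = 4
#> rates k: amy=0.329, met=0.264, atr=0.245, cli=0.272
#> couplings: met<-amy: 0.0951, atr<-amy: 0.0536, cli<-amy: 0.00345, ...
#> noise sd per modality (standardized units): amy=0.159, met=0.102, ...

lat <- project_cohort(gen$cohort, model, group = "AD")
mix <- fit_latent_mixture(lat, seed = 2)
ens <- sample_ensemble(mix, 1000, model$dynamics, seed = 3)
ref <- build_reference(ens, anchor = "staging", model = model,
                       cohort = gen$cohort)

taus <- stage_cohort(gen$cohort, model, ref)
cor(gen$truth$true_tau, taus$tau, method = "spearman")
#> [1] 0.986

iv  <- intervention_spec(c(0, 1, 1, 1), start_time = -15)  # 100% lowering
d   <- trial_design(iv, n_per_arm = 100, replicates = 100, seed = 9)
run_trial(model, mix, ref, d)
#> <cascade_trial_result> n/arm = 100 , replicates = 100 , intervention from t = -15
#>  endpoint improvement_mean improvement_sd p_median power mc_se
#>     cli_0            0.301         0.0636 1.94e-06     1     0  ...
```

The fitted rates sit within ~10% of the generating values
(k = 0.35, 0.25, 0.25, 0.30), the recovered time-shifts track the true
per-subject disease ages at Spearman 0.99, and a complete amyloid arrest
15 years before conversion is detected with power ≈ 1 at 100 subjects
per arm, while the same intervention 5 years before conversion is
indistinguishable from placebo — the timing structure that motivates
pre-clinical intervention.

A command-line interface wrapping the same functions is installed at
`inst/cli/cascadesim` (subcommands `simulate-data`, `fit`, `trajectory`,
`stage`, `intervene`, `power`; every run writes a manifest with seed,
configuration hash and output checksums).

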