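# irdose

Dose-response modelling and laser-power optimization for infrared-laser
(IR-LEGO) induced single-cell gene activation.

## The problem

Pointing a 1,480-nm laser at one plant cell heats it enough to fire a
heat-shock promoter driving CRE recombinase; CRE excises a loxP cassette
and switches on a VENUS reporter — permanently, in that cell and its
descendants.  The laser power is a dose with competing risks: too low and
no recombination happens, too high and the reporter also fires in
neighbouring cells or the cell dies (PI staining).  Each trial yields one
of six categorical outcomes encoding four binary endpoints — `target`
(VENUS in the irradiated cell), `neighboring` (VENUS elsewhere), `local`
(either), `death` (any PI-positive cell).

`irdose` is for experimentalists and biostatisticians planning such
experiments.  It models each endpoint probability against laser power
`x` (mW) and normalized target-cell size `c` with four nested logistic
families

    simple        p = logit⁻¹(a·x + b)
    bounded       p = lim · logit⁻¹(a·x + b),           0 < lim ≤ 1
    size          p = logit⁻¹(a₁x + a₂c + a₃xc + b)
    bounded_size  p = lim(1 + a₄c) · logit⁻¹(a₁x + a₂c + a₃xc + b)

(the bounded families describe recombination that plateaus below 100%,
e.g. the ~40% ceiling of 60-s single-target induction), fits them by
maximum likelihood (`glm`) or by seeded, convergence-checked MCMC with
posterior-median point estimates, tests cell-size effects with standard
and deviance-based likelihood-ratio tests, and then optimizes the dose:

* condition 1 — maximize `P_target·(1 − P_neighboring)` (single-cell
  induction);
* condition 2 — maximize `P_local·(1 − P_death)` (local induction
  without death), with `P_local = P_t + P_n − P_t·P_n` composed under
  independence when not fitted directly;
* raising points — the power where a fitted curve first reaches 10%.

A synthetic-trial generator reproduces the published power-bin designs
and calibrated cell-size distribution so the whole pipeline can be
validated by parameter recovery.

## Worked example

Simulate a tenfold-inflated 60-s design, fit the plateaued target
endpoint by MCMC and the others by `glm`, then choose powers:

```r
library(irdose)
ds <- simulate_trials(replicate_design(60, inflate = 10),
                      default_truth(60), seed = 20260926)
ds
#> Irradiation trials: 1290 records
#>   power range: 5.5-20 mW; duration(s): 60 s
#> outcome
#> DEATH_AND_EXPRESSION        NEIGHBOR_ONLY                 NONE
#>                   59                  174                  754
#>  TARGET_AND_NEIGHBOR          TARGET_ONLY
#>                   98                  205

target <- fit_bounded_mcmc(ds, "target", "bounded",
                           config = sampler_config(seed = 1))
target
#> Posterior fit (bounded, endpoint target): 20000 draws over 4 chains
#>      median   rhat  ess
#> lim  0.4805 1.0064 1733
#> a    1.0595 1.0018 1668
#> b   -9.1275 1.0018 1697

cs <- curve_set(target$curve_at_medians,
                fit_logistic(ds, "neighboring")$curve,
                fit_logistic(ds, "death")$curve)
optimize_condition(cs, 1, c(5.5, 20))
#> Condition 1: optimal power 10.3 mW (score 0.3521) over [5.5, 20] mW
optimize_condition(cs, 2, c(5.5, 20))
#> Condition 2: optimal power 14.1 mW (score 0.8981) over [5.5, 20] mW
raising_point(target$curve_at_medians, 0.10, c(5.5, 20))
#> Raising point (target, 10%): 7.35 mW
```

The fitted plateau (`lim` ≈ 0.48) estimates the ceiling of single-cell
induction; condition 1 says 10.3 mW maximizes the chance (0.35) of
lighting up *only* the targeted cell, while pushing to 14.1 mW maximizes
local induction without death (0.90).  Note the observed `target`
endpoint sits slightly above the generating 0.40 plateau because the
categorical taxonomy merges death-plus-any-expression trials into one
category (see the methods vignette).

The built-in worked example from leaf tissue — 4 single-cell successes
in 20 mesophyll trials at the root-optimized condition:

```r
leaf <- leaf_fixture()
proportion_estimate(sum(endpoint_outcomes(leaf, "target")), n_trials(leaf))
#> leaf: 4/20 = 0.20 (95% CI 0.057-0.437)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/irdose.R` (subcommands `simulate | fit | optimize | lrt`).

## Documentation

See the methods vignette (`vignettes/dose-response-methods.Rmd`) for the
model derivations, prior and sampler choices, the independence
approximation behind the composite scores, what the synthetic generator
does and does not emulate, and known limitations.
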