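# binrefmi

Reference-based multiple imputation for longitudinal **binary** trial
outcomes with monotone missing data after treatment deviation.

## The problem

In a two-arm trial measuring a binary outcome at visits `1..J+1` (visit 1 =
baseline), patients who stop randomized treatment early typically contribute
no further outcomes. A treatment policy estimand — the odds ratio of the
final-visit outcome regardless of adherence — then rests on an untestable
assumption about the missing post-deviation data. Reference-based multiple
imputation makes that assumption explicit by borrowing the post-deviation
distribution from a reference arm: randomized-arm MAR, jump to reference
(J2R), copy reference (CR), copy increments in reference (CIR), or last mean
carried forward (LMCF).

`binrefmi` implements two imputation engines for the binary setting:

1. **MVN + adaptive rounding** (`impute_mvn_rounding()`): the 0/1 outcomes
   are treated as continuous, a per-arm multivariate normal is fitted
   Bayesianly (flat prior on the mean, Jeffreys prior on the covariance;
   data-augmentation MCMC under monotone missingness), each deviator's
   assumption-specific joint
   (mean per the option above; covariance `Σ_J2R` solving
   `Σ11 = A11`, `Σ21 Σ11⁻¹ = R21 R11⁻¹`,
   `Σ22 − Σ21 Σ11⁻¹ Σ12 = R22 − R21 R11⁻¹ R12`)
   is conditioned on the observed prefix and sampled, and continuous
   imputations are recoded by the adaptive-rounding threshold
   `c = ȳ − Φ⁻¹(ȳ)·sqrt(ȳ(1−ȳ))` computed per visit and imputation across
   both arms.
2. **Latent multivariate normal / multivariate probit** (`impute_latent()`):
   each outcome is the sign indicator of a unit-variance latent normal
   (`Z > 0 ⇔ Y = 0`); a per-arm Gibbs sampler with element-wise Metropolis
   updates of the unit-diagonal correlation matrix draws the latent-scale
   parameters, the reference-based joint is built on the latent scale, and
   latents are drawn sequentially over visits (truncated to the observed
   sign regions, decoded by the sign rule where missing).

Per-imputation log odds ratios are pooled by Rubin's rules
(`rubin_pool()` / `pool_imputations()`), with Barnard–Rubin degrees of
freedom, confidence intervals and the Monte-Carlo error of the pooled
estimate. A simulation laboratory (`scenario_preset()`, `run_scenario()`)
generates trials from a multivariate probit model, imposes MAR deviation by
logistic mechanisms, regenerates the post-deviation *truth* under any of the
five assumptions, and measures bias, empirical vs Rubin variance, coverage
and the information-anchored variance
`V_anchored = V_obs,MAR / V_full × V_full,ref`.

The MCMC cores are C++ (RcppArmadillo) with R reference engines that consume
the RNG stream identically — a seeded run is bit-identical across engines.

## A worked example

```r
library(binrefmi)

scn    <- scenario_preset(row = 1, followups = 1, missing = "30", truth = "CR")
data   <- generate_on_treatment(scn, seed = 1)      # 250/arm probit trial
d      <- impose_deviation(data, scn, seed = 2)     # ~39% active-arm deviation
masked <- mask_post_deviation(data, d)

stack  <- impute_latent(masked, "CR", K = 25,
                        config = sampler_config(n_draws = 25, burn_in = 500,
                                                thin = 100),
                        seed = 3)
pool_imputations(stack)
```

```
Pooled log-OR 0.2849 (SE 0.1971), OR 1.330 [0.902, 1.960], df 290.1, p 0.1494 (K = 25)
within 0.03268 | between 0.00593 | total 0.03885 | mc error 0.0154
```

The pooled log odds ratio (here 0.285, OR 1.33) is the treatment effect at
the final visit under copy-reference behaviour after deviation; `within` is
the average complete-data sampling variance, `between` the variance across
the 25 imputations, and their Rubin combination gives the interval and
p-value. Under CR the estimate is attenuated relative to an on-treatment
(MAR) analysis of the same data — the deviators' imputed outcomes follow the
reference arm — which is exactly what the assumption intends.

The same pipelines are scriptable:

```sh
inst/cli/binrefmi fixture  --name row1_single_30pct --seed 1 --output trial.csv
inst/cli/binrefmi impute   --input trial.csv --method latent --assumption J2R \
                           --K 50 --seed 1 --output-prefix run
inst/cli/binrefmi simulate --scenario inst/scenarios/row1_single_30pct.txt \
                           --output performance.csv
```

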