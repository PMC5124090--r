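# ipmdemog

Regional integrated population models (IPMs) for a short-lived migratory
songbird, in R.

Across Europe many Afro-Palaearctic migrant songbirds are declining in
some breeding regions while holding steady or increasing in others.
Deciding whether survival or productivity drives such divergence needs
the abundance trend and the demographic rates estimated jointly, because
no single monitoring scheme observes them all. This package is for
population ecologists who want that joint estimate and the analyses that
follow from it: which rates covary with annual growth, what combinations
of survival and productivity permit growth at all, and whether a
declining region would have recovered with another region's rates.

## The model

The female population in year *t* comprises surviving adults and
recruits (*N_t = N_a,t + N_r,t*), with

```
N_a,t ~ Binomial(N_{t-1}, phi_ad,t-1)
N_r,t ~ Poisson(N_{t-1} * 0.5 * F_{t-1} * rho_{t-1})
```

where productivity *F = B * phi_egg^ep * phi_chick^yp* (fledglings per
breeding attempt: brood size times daily nest survival through `ep` egg
days and `yp` chick days), 0.5 keeps the female half of production, and
`rho_t` is a recruitment scaling factor absorbing unmeasured first-year
survival, dispersal and multi-brooding. The observed index is log-normal
around the latent size, `log y_t ~ Normal(log N_t, sigma^2)`; years with
no survey are imputed by the process equations. Four data streams feed
one posterior, sampled with JAGS: the count series, a Cormack–Jolly–Seber
likelihood over capture histories from constant-effort ringing (time
varying survival, constant recapture probability), a Mayfield
exposure-day nest-survival likelihood, and zero-truncated-Poisson brood
sizes. Yearly `log rho_t` get an exchangeable hierarchical prior; the
methods vignette (`vignettes/ipm-methods.Rmd`) explains every prior,
convention and design choice.

Because the motivating monitoring datasets are proprietary, the package
ships a synthetic-data generator whose `"northwest-like"` and
`"southeast-like"` presets are centred on the published regional
posterior means (19 years, 150 nest records and 200 ringing releases per
year, one masked survey year); everything downstream is validated
against simulated data with known truth.

## Worked example

```r
library(ipmdemog)

sc  <- simulate_region(scenario_preset("northwest-like"), seed = 1)
fit <- fit_ipm(sc$data, fit_config(seed = 1))
glance(fit)
#> # A tibble: 1 x 8
#>   region    n_years n_chains n_draws max_rhat converged n_missing_years runtime_s
#>   <chr>       <int>    <int>   <int>    <dbl> <lgl>               <int>     <dbl>
#> 1 northwest      19        4    4000     1.08 TRUE                    1      58.3
```

The fit retains 4,000 posterior draws (4 chains of 20,000 iterations,
half discarded, thinned by 10) over the yearly rates, the latent
population and the derived growth rates; `max_rhat` is the split
Gelman–Rubin statistic, below the conventional 1.1. The correlation
analysis then asks which rates move with annual growth, per MCMC draw
across the 18 transitions:

```r
growth_rate_correlation(fit, "phi_ad")
#> # A tibble: 1 x 8
#>   rate   mean_r cri_low cri_high p_positive n_draws n_years n_degenerate
#>   <chr>   <dbl>   <dbl>    <dbl>      <dbl>   <int>   <int>        <int>
#> 1 phi_ad  0.237  -0.270    0.581      0.846    4000      18            0

growth_rate_correlation(fit, "fpba")
#> # A tibble: 1 x 8
#>   rate  mean_r cri_low cri_high p_positive n_draws n_years n_degenerate
#>   <chr>  <dbl>   <dbl>    <dbl>      <dbl>   <int>   <int>        <int>
#> 1 fpba   0.794   0.548    0.924          1    4000      18            0
```

In this realisation productivity is the clearer driver of growth
(posterior mean r of 0.79, probability of a positive correlation 1.00)
while the survival signal is present but uncertain (mean r 0.24,
p-positive 0.85) — the generating scenario builds yearly variation into
both rates, and which dominates a single 18-transition series varies by
realisation. The masked survey year's population is imputed by the process
model:

```r
impute_missing_counts(fit)
#> # A tibble: 1 x 6
#>    year  mean    sd  q2.5 median q97.5
#>   <int> <dbl> <dbl> <dbl>  <dbl> <dbl>
#> 1  2001 1704.  203. 1293.   1706 2108.
```

(the generating truth for 2001 in this scenario is N = 1883, inside the
interval at 0.9 posterior s.d. from the mean). Region comparisons, the growth-rate surface and the
counterfactual substitutions follow the same pattern:

```r
se_fit <- fit_ipm(simulate_region(scenario_preset("southeast-like"), seed = 2)$data,
                  fit_config(seed = 2))
cross_region_correlation(fit, se_fit, "phi_ad")   # regional synchrony in survival
surf <- growth_surface(fit, se_fit)               # lambda over (phi, FPBA), rho at grand mean
autoplot(surf)
sub <- substitute_trajectory(se_fit, fit, "productivity", from_year = 2003, seed = 1)
recovery_test(sub)                                # does the median index reach 1?
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ipm-demog` (subcommands `simulate`, `fit`, `analyze`,
`surface`, `substitute`, `report`), each writing machine-readable CSV or
JSON plus a run manifest with the seed and configuration hash.

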