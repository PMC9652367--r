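# bstar — Bayesian structured additive regression for spatial binary outcomes

`bstar` estimates household-level risk models for binary outcomes — the
motivating application is food insecurity across Ethiopian administrative
zones — where covariate effects may be nonlinear and residual risk varies
smoothly in space. It fits the generalized geo-additive mixed model

    logit(pi_i) = x_i' alpha + sum_j f_j(v_ij) + f_str(zone_i) + f_uns(zone_i)

by exact Gibbs sampling:

* **fixed effects** `alpha` for categorical covariates (head gender,
  marital status, residence, shock exposure, credit access, survey wave)
  with diffuse priors, reported as adjusted odds ratios;
* **nonlinear effects** `f_j` of continuous covariates (age, schooling,
  asset index, dependency ratio, family size) with second-order random-walk
  (RW2) priors on knot grids;
* **structured spatial effect** `f_str` with an intrinsic CAR (GMRF) prior
  on the zone adjacency graph, plus an **unstructured** i.i.d. zone effect
  `f_uns` (BYM-style decomposition);
* inverse-Gamma hyperpriors on all variances, Pólya-Gamma data augmentation
  for the logistic likelihood (no tuning parameters), and DIC for comparing
  the geo-additive model with a plain GLM.

It is aimed at biostatisticians and epidemiologists analysing household
surveys with a zone identifier and an adjacency structure. Because the
motivating microdata are restricted, the package ships a synthetic-data
generator with known ground truth (`generate_households()`), emulating the
Ethiopia Socioeconomic Survey structure (5262 households, 72 zones,
4 waves), plus the descriptive stage (contingency tables, prevalences,
chi-square and summary t-tests) used for Table-1-style reporting.

## Worked example

```r
library(bstar)

# a 6x6 zone lattice stands in for the zone contiguity graph
g     <- make_zone_lattice(6, 6)
truth <- default_truth(g, seed = 2)           # known generating parameters
d     <- generate_households(g, truth, n = 4000, seed = 2)

# descriptive stage
head(describe_households(d), 3)
#>   variable    level n_no n_yes pct_yes       test            p
#> 1      sex   female  786   416    34.6 chi-square 2.142123e-06
#> 2      sex     male 2038   760    27.2 chi-square 2.142123e-06
#> 3  marital divorced  227   123    35.1 chi-square 1.631772e-11

# geo-additive fit: 12000 iterations, 1000 retained draws
fit  <- run_chain(d, geoadd_spec(g), mcmc_config(seed = 5))
#> spatial effect ranges (posterior means): structured 2.994, unstructured 0.507
summ <- summarize_posterior(fit)
subset(summ, parameter %in% c("sexfemale", "shockno", "credityes"),
       select = c(parameter, mean, q2.5, q97.5, or))
#>   parameter       mean       q2.5      q97.5        or
#> 2 sexfemale  0.4565715  0.2769509  0.6166497 1.5786523
#> 8   shockno -1.3996496 -1.5647339 -1.2333932 0.2466834
#> 9 credityes -0.5536456 -0.7460998 -0.3684280 0.5748503
```

The posterior means sit close to the generating values (`log(1.60) = 0.47`
for a female-headed household, `log(0.23) = -1.47` for no shock,
`log(0.58) = -0.54` for credit access) and each 95% credible interval
covers its generating coefficient. The odds-ratio column is the
`exp`-transform reporting convention for the fixed-effect contrasts.

Model comparison against the linear, non-spatial GLM on the same data:

```r
compute_dic(fit)$dic                                   # 3917.358
compute_dic(run_chain(d, glm_spec(), mcmc_config(seed = 5)))$dic  # 4417.580
```

The geo-additive model's DIC is lower by ~500 — the nonlinear and spatial
structure present in the data is worth that much deviance. The fitted
nonlinear effects and zone effects export as plain tables:

```r
effect_curve(fit, "schooling")   # knot, mean, q2.5, q97.5 (log-odds scale)
zone_effect_table(fit)           # zone, str_mean, uns_mean, total, CI
```

A thin command-line pipeline over the same functions ships in
`inst/cli/bstar.R` (`simulate`, `describe`, `fit`, `summarize`).

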