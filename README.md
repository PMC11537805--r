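# xlinksel

Fitness-component analysis for two alleles at an X-linked locus in
multi-generation competition experiments.

## The problem

When two variants of an X-linked gene compete in a laboratory population
over many discrete generations, the allele-frequency trajectory blends
four things that single-generation assays cannot separate: viability and
fertility effects, each potentially different in hemizygous males and in
heterozygous vs homozygous females.  `xlinksel` implements the
deterministic selection model and the inference pipeline that pulls these
components apart from adult counts scored by a sex-linked visible marker.

The model tracks male frequencies $p_1, p_2$ and female genotype
frequencies $Q_{11}, Q_{12}, Q_{22}$ under six constant selection ratios —
fertility $\alpha$ (males), $\beta$, $\gamma$ (females) and viability
$\mu$ (males), $\nu$, $\epsilon$ (females) — via the recursion, on
$R_1 = p_1/p_2$, $R_2 = Q_{11}/Q_{12}$, $R_3 = Q_{22}/Q_{12}$:

$$R_1' = \frac{(2R_2\beta+1)\mu}{2R_3\gamma+1},\quad
  R_2' = \frac{(2R_2\beta+1)R_1\alpha\nu}{D},\quad
  R_3' = \frac{(2R_3\gamma+1)\epsilon}{D},$$

$D = 2R_1R_3\alpha\gamma + 2R_2\beta + R_1\alpha + 1$.  Inference is
two-stage: the viability ratios are identified in closed form from
generation-2 counts (one selective step from the reciprocal founding
crosses gives $R_1(2)=\mu$ and, per setup, $\nu$ or $\epsilon$), then the
fertility ratios are fitted by exhaustive grid search — a 201-point
log screen ($0.1$ to $10$) plus a 101-point fine grid ($0.5$ to $1.5$) per
parameter — maximising a composite binomial log-likelihood over the
scored generations {3, 8, 12, 20}, with profile-likelihood 95% intervals
(χ² drop rule).  Running two competitions against a common reference
allele yields the six sex-specific fitness differences between the two
variants.  A synthetic-data generator (binomial observation noise, or an
optional finite-population drift mode) makes the whole pipeline testable
without any external data.

For whom: population geneticists analysing allelic-competition
experiments with X-linked visible markers, and anyone needing a tested
reference implementation of X-linked two-allele selection recursions.

## Worked example

Simulate two competitions against a common reference allele A1 — one
against a fitter variant, one against a less-fit variant — then run the
full pipeline:

```r
library(xlinksel)

f_plus <- fitness_ratios(alpha = 1.2, beta = 1.1, gamma = 0.9,
                         mu = 1.1, nu = 1.2, epsilon = 0.8)
f_one  <- fitness_ratios(alpha = 0.8, beta = 1.1, gamma = 1.3,
                         mu = 0.9, nu = 1.2, epsilon = 0.8)
cts_plus <- generate_counts(
  experiment_design(seed = 71, census_min = 2000, census_max = 3000), f_plus)
cts_one  <- generate_counts(
  experiment_design(seed = 72, census_min = 2000, census_max = 3000), f_one)

fit_plus <- fit_fertility(cts_plus, estimate_viability(cts_plus))
print(fit_plus)
#> Fertility-ratio fit (composite binomial likelihood, grid search)
#>   viability plug-in: mu = 1.0790, nu = 1.0984, epsilon = 0.7754
#>   alpha = 1.300  [1.240, 1.390] (95% profile)
#>   beta  = 1.180  [1.140, 1.210] (95% profile)
#>   gamma = 0.950  [0.920, 0.990] (95% profile)
#>   lnL_max = -27863.6244 over generations {3, 8, 12, 20}, setups {I, II}
```

The viability plug-in line shows the generation-2 closed-form estimates
(true values 1.1, 1.2, 0.8); the fitted fertility ratios carry their
fine-grid profile intervals.  Deriving the variant-vs-variant differences
(positive = advantage of the "plus" variant):

```r
fit_one <- fit_fertility(cts_one, estimate_viability(cts_one))
fitness_difference_table(fit_plus, fit_one, cts_plus, cts_one)
#> # A tibble: 6 × 6
#>   component            type      increase  ci_lo   ci_hi   p_value
#>   <chr>                <chr>        <dbl>  <dbl>   <dbl>     <dbl>
#> 1 male_viability       viability  -0.192  NA     NA       8.22e-10
#> 2 het_female_viability viability   0.0848 NA     NA       3.05e- 2
#> 3 hom_female_viability viability   0.0739 NA     NA       7.59e- 1
#> 4 male_fertility       fertility  -0.566  -0.759 -0.494  NA
#> 5 het_female_fertility fertility  -0.103  -0.131 -0.0364 NA
#> 6 hom_female_fertility fertility  -0.556  -0.647 -0.371  NA
```

Viability rows carry Pearson χ² p-values from the generation-2 counts;
fertility rows carry intervals propagated from the two fits' profile CIs.
Here the "one" variant was simulated with the larger male fertility
($\alpha$ ratio 0.8 vs 1.2, so A1's advantage is smaller in the "plus"
competition), and the table recovers that as a negative male-fertility
increase; at this census (2000-3000 per sex) the estimates scatter around
the simulated truths by a few grid steps, driven mostly by the
generation-2 plug-in noise — see the vignette's limitations section.

Deterministic model predictions alone:

```r
trajectory("II", neutral_fitness(), 20)[20, c("p1", "Q11")]
#> # A tibble: 1 × 2
#>      p1   Q11
#>   <dbl> <dbl>
#> 1 0.667 0.444
neutral_equilibrium("II")
#>        p1       Q11
#> 0.6666667 0.4444444
```

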