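# mrkit

Two-sample Mendelian randomization (MR) from GWAS summary statistics,
built around a worked drug-target question: does genetically elevated
circulating interleukin-18 (IL18) increase susceptibility to
inflammatory bowel disease (IBD)?

MR treats SNPs as instrumental variables: because alleles are assigned
at random at conception, a variant that raises IL18 levels is a natural
randomized exposure, immune to the confounding and reverse causation of
observational biomarker studies. In the two-sample design the
SNP-exposure and SNP-outcome associations come from different GWAS
cohorts and only summary statistics are needed. For instrument *i*,

- Wald ratio: θ̂ᵢ = β̂_yᵢ / β̂_xᵢ (causal log-odds of outcome per SD of
  exposure), se(θ̂ᵢ) = se(β̂_yᵢ)/|β̂_xᵢ| (first order);
- fixed-effects IVW pooling: θ̂ = Σwᵢθ̂ᵢ / Σwᵢ with wᵢ = 1/se(θ̂ᵢ)²,
  se(θ̂) = (Σwᵢ)^(-1/2);
- heterogeneity: Cochran's Q = Σwᵢ(θ̂ᵢ − θ̂)² and I² = max(0, (Q−df)/Q).

Around that core the package provides allele harmonization (sign flips,
strand complements, palindromic-SNP handling), leave-one-out and
restricted-instrument sensitivity analyses, analytic power for binary
outcomes (Φ(√(N·R²·K(1−K))·|ln OR| − z)), Wakefield
approximate-Bayes-factor colocalization with PP0–PP4 posteriors, a
Bonferroni-controlled phenome-wide MR scan, and a synthetic
summary-statistics generator with known ground truth. It is intended
for epidemiologists and statistical geneticists running
summary-statistic MR analyses in R.

## Worked example

The package ships the three published IL18 instruments (rs385076 at
*NLRC4*, rs17229943 at *OCLN*, rs71478720 intronic in *IL18*) with their
effects on IL18 level (Finnish cytokine GWAS, N = 3,636) and on IBD
(12,882 cases / 21,770 controls):

```r
library(mrkit)
ex <- il18_ibd_example()
fit <- mr_analysis(ex$exposure, ex$outcome)
fit
#> Two-sample MR: IL18 level (SD) -> IBD
#> 3 instrument(s); fixed-effects IVW
#>   rs385076     OR 1.22 (1.07-1.40)  p = 0.004
#>   rs17229943   OR 1.24 (0.91-1.70)  p = 0.18
#>   rs71478720   OR 1.20 (1.04-1.38)  p = 0.012
#> Pooled: OR 1.21 (1.11-1.33)  p = 5.2e-05
#> Heterogeneity: Q = 0.05 on 2 df (p = 0.97), I2 = 0% (95% CI 0-90%)
```

Each SD of genetically predicted IL18 raises the odds of IBD by about
21% (the originally published figure, computed from unrounded GWAS
estimates, is 1.22 with 95% CI 1.11–1.34; reconstructing standard errors
from CIs printed to two decimals shifts the last digit). I² = 0%
indicates no detectable heterogeneity across the three instruments.
Restricting to the cis instrument inside the *IL18* gene — the variant
least likely to act through pleiotropic pathways — gives a near-identical
estimate:

```r
glance(mr_analysis(ex$exposure, ex$outcome, snps = "rs71478720"))
#>   or_point 1.20, ci_low 1.04, ci_high 1.38, pvalue 0.012
```

`tidy(fit)` returns the forest-plot table (per-SNP rows plus the pooled
summary with inverse-variance weight shares), `autoplot(fit)` draws the
forest plot, and

```r
mr_power_binary(25042, 34915, r2 = 0.038, or_alt = 1.2)
#> [1] 0.9901482
```

is the replication-stage power calculation: 99% power to detect a 20%
increase in odds per SD.

See the vignette (`vignettes/mendelian-randomization.Rmd`) for the full
account of the models, defaults, colocalization, the phenome-wide scan
and the synthetic-data generator.

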