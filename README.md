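# pcrit

Can the susceptibility alleles reported for a common, heritable disorder
under strong negative selection actually be *sustained* in the population?
`pcrit` answers that question quantitatively. It is aimed at statistical
and population geneticists working with case-control association catalogs
for disorders — schizophrenia is the packaged example — where patients'
reproductive fitness is sharply reduced, so every nuclear risk allele must
be maintained by mutation-selection balance.

## The criterion

For a disorder of prevalence $p$ whose affected population has mean
relative fitness $1 - s$, a nuclear susceptibility allele at a locus with
per-generation mutation rate $\mu$ can persist at mutation-selection
balance only if its case-control risk-allele frequency difference
$d = m_A - m_U$ satisfies

$$ 0 < d < \nu \equiv \frac{(1 - s p)\,\mu}{(1 - p)\,s p}. $$

This follows from the one-generation selection recurrence
$m_G' = (m_G - s_M\,p\,m_A)/(1 - s_M\,p)$: the per-generation loss
$p(1-p)\,d\,s_M/(1 - s_M p)$ must not exceed $\mu$, and a true
susceptibility allele has $s_M \ge s$. A variant with $d \ge \nu$ cannot
be causal at balance — it must be protective — and the package's
classifier maps where such variants sit relative to the criterion-meeting
ones, arm by chromosome arm. The same threshold sets the sample size an
association study needs:
$N \approx (z_{\alpha/2} + z_\beta)^2\,x(1-x)/d^2$ case-control pairs at
allele frequency $x$.

## Worked example

```r
library(pcrit)

th <- persistence_threshold("highest")  # mu = 1.48e-4
th
#> <persistence_threshold>
#>   nu = 0.0176 (full precision 0.01762193491)
#>   p  = 0.0129  s = 0.654  mu = 0.000148

summary <- read_catalog(pcrit_example_catalog()) |>
  summarize_catalog(th)
summary
#> <catalog_summary> nu = 0.0176
#>   64 variants: 21 meet the criterion (0 < d < nu) on 18 loci
#>   19 protective loci (d >= nu) on arms with no meeting variant
#>     10q: GWA_10q26.13
#>     11p: DRD4, GWA_11p14.1, TPH1
#>     ...
#>     1p: GRIK3, GSTM1, MHTFR, PDE4B
#>     2q: IL1B, ZNF804A

required_pairs(th)
#> # A tibble: 1 × 9
#>   n_pairs n_pairs_2sf z_alpha z_beta      alpha power     x      d form
#>     <dbl>       <dbl>   <dbl>  <dbl>      <dbl> <dbl> <dbl>  <dbl> <chr>
#> 1  28976.       29000    5.16  0.842 0.00000025   0.8   0.5 0.0176 collapsed
```

Reading the output: at the highest plausible nuclear mutation rate the
persistence threshold is $\nu = 0.0176$ (carried unrounded as 0.017622 —
the boundary variant with $d = 0.0176$ meets the criterion only for that
reason). Of the 64 catalog variants, 21 on 18 loci have $0 < d < \nu$;
the other 19 loci carry only threshold-exceeding (hence protective)
variants and sit on chromosome arms with no criterion-meeting variant at
all — four of them on 1p alone. Detecting a genuine susceptibility
variant with $d = \nu$ at genome-wide significance
($\alpha = 2.5 \times 10^{-7}$, power 0.8, worst-case $x = 0.5$) takes
about 29,000 case-control pairs; at the *average* mutation rate
($\nu = 1.76\times10^{-3}$) it takes 2.9 million, more than any feasible
design.

Other entry points: `tidy()`/`glance()` on every result object,
`autoplot()` for the catalog and recurrence trajectories,
`iterate_ngm()` (forward recurrence whose fixed point is $\nu$),
`mgm_carrier_step()`/`simulate_mgm()` (maternal-lineage carrier model
with heterozygote-advantage compensation), `maternal_excess_test()`
(exact binomial transmission test), and `generate_catalog()` /
`empirical_power()` for synthetic validation. The methods vignette
(`vignettes/persistence-criterion.Rmd`) documents the model, defaults
and design choices.

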