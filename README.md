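# thermadapt

Analysis toolkit for long-term thermal selection experiments in clonal
microbial populations — built around the kind of study in which a marine
diatom is propagated for hundreds of generations under control, moderate,
severe and fluctuating warming regimes, phenotyped for growth and
metabolic thermal responses, and pooled-resequenced to find the mutations
that fixed along the way.

The package provides four analysis layers plus a synthetic-data generator
with known planted truth, so every method can be validated end to end
without access to raw sequencing data.

## What it computes

**Thermal performance curves.** Rates (growth µ, gross photosynthesis
*P*, respiration *R*) are modelled with a modified Sharpe–Schoolfield
equation with a Boltzmann rise and a single high-temperature inactivation
term:

    ln b(T) = E_a (1/kT_c − 1/kT) + ln b(T_c) − ln(1 + e^{E_h (1/kT_h − 1/kT)})

with *k* = 8.62×10⁻⁵ eV K⁻¹ and reference temperature T_c = 18 °C. The
Boltzmann form admits a closed-form optimum,
T_opt = E_h·T_h / (E_h + k·T_h·ln(E_h/E_a − 1)), and fits are compared
via small-sample AICc with Akaike-weight model averaging
(`ss_log_rate()`, `compute_topt()`, `fit_tpc()`, `compare_models_aicc()`).

**Metabolic carbon budgets.** Photosynthesis–irradiance curves follow a
photoinhibition model NP(I) peaking at I_opt with dark respiration −*R*
at I = 0; gross photosynthesis is *P* = NP_max + *R*; O₂ fluxes convert
to carbon-specific rates through the C:N-derived assimilation quotient
M = n/(n+2); carbon-use efficiency is CUE = 1 − R/P; and Φ_PSII light
responses follow an exponential decay a·e^{I·b}
(`fit_pi_curve()`, `convert_rate_units()`, `carbon_use_efficiency()`,
`fit_phi_psii()`).

**Pooled-seq fixation calling.** VCF records are filtered with
bcftools-equivalent semantics (QUAL ≥ 35, DP ≥ 5, IDV ≥ 2 where defined,
SNVs only, 10 bp SnpGap around indels). Allele frequencies are read
proportions A/D with exact Clopper–Pearson binomial intervals, and
fixation in an evolved population is called by five auditable criteria:
ancestral depth ≥ 10; ancestral absence (A = 0, de novo) or
heterozygosity (A/D ∈ [0.3, 0.7], het-origin); evolved depth ≥ 5;
unanimous evolved reads (A/D = 1); and a filter pass in ≥ 1 population
(`filter_variants()`, `estimate_allele_frequency()`, `call_fixation()`,
`build_frequency_matrix()`, plus a minimal strand-aware codon-effect
annotator).

**Divergence statistics.** From the loci × samples frequency matrix:
squared-Euclidean distances, hierarchical AMOVA with permutation
significance, PERMANOVA and dispersion homogeneity (vegan-backed), PCA
(equivalent to principal coordinates on Euclidean distances, but with
per-locus loadings), top-loading→treatment association, and
score-weighted Kolmogorov–Smirnov term enrichment
(`amova()`, `permanova()`, `dispersion_test()`, `pca()`,
`top_loading_associations()`, `weighted_ks_enrichment()`).

**Synthetic data.** `sim_config()` + `simulate_pool_seq()` /
`simulate_tpc_data()` / `simulate_pi_curves()` / `simulate_growth_series()`
generate per-sample VCFs (written with `write_vcfs()`), rate tables and
growth series under a binomial read model A ~ Binomial(D, f(1−ε)+(1−f)ε)
with D ~ Poisson(λ), returning a truth table of planted fixations.

## Worked example

```r
library(thermadapt)

cfg <- sim_config(seed = 42)            # the default stated world
sim <- simulate_pool_seq(cfg)           # ancestor + 12 evolved pools
calls <- call_fixation(sim$records, "anc_t0")
table(calls$category)
#>    de_novo_fixed het_origin_fixed        not_fixed
#>               57              218            14125

evolved <- setdiff(sim$samples$sample, "anc_t0")
fm <- build_frequency_matrix(sim$records, evolved, fixed_only = TRUE,
                             calls = calls)       # 246 loci x 12 samples
treat <- sim$samples$treatment[match(colnames(fm), sim$samples$sample)]
amova(distance_matrix(fm), treat, n_perm = 999, seed = 1)
#> Analysis of molecular variance (squared Euclidean distances)
#>           component df        ss sigma2_raw sigma2 percent p_value
#>   among_populations  8  87.27238 10.9090478 10.909   97.93      NA
#>  between_treatments  3  34.80577  0.2309587  0.231    2.07    0.07
#>               total 11 122.07815 11.1400065 11.140  100.00      NA
```

The default generator plants the *same* thermal truth in every treatment
and fixes loci independently per population, so most variance sits among
populations and the between-treatment term is small and non-significant —
exactly what the statistics should report.

```r
d <- simulate_tpc_data(cfg)
fit_tpc(d$temp_c[d$treatment == "22C"], d$rate[d$treatment == "22C"])
#> Thermal performance curve fit (modified Sharpe-Schoolfield)
#>   n = 84 observations, RSS = 0.6883, AICc = -395.06
#>   Ea = 1.077 eV, Eh = 3.553 eV, Th = 303.23 K, ln b(Tc) = -0.595
#>   T_opt = 301.38 K (28.23 C)
```

The generating truth was Ea = 1.08 eV, Eh = 3.5 eV, Th = 303.15 K
(T_opt ≈ 28.2 °C): the fit recovers all of it through 10% multiplicative
noise. A P–I curve from the same configuration gives
`P = 11.52, R = 1.83, CUE = 0.841` (truth: NP_max = 10, R = 2).

A command-line interface covering the same pipeline lives at
`inst/cli/thermadapt.R` (subcommands `growth`, `tpc`, `metab`,
`variants`, `stats`; see the file header).

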