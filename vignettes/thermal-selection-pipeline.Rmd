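---
title: "Models and methods: thermal selection analysis with thermadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: thermal selection analysis with thermadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermadapt)
```

# The problem

Experimental evolution under warming asks two linked questions: how does
the *phenotype* — the thermal performance curve of growth and metabolism —
shift over hundreds of generations, and which *genomic* changes underlie
the shift. thermadapt implements the computational core of that analysis
for clonal microbial systems (the motivating organism is a centric marine
diatom): curve fitting for thermal and light responses, a carbon budget
connecting photosynthesis and respiration to growth potential, and a
pooled-resequencing framework that calls fixed mutations and quantifies
molecular divergence among selection regimes.

# Thermal performance curves

## Model

`ss_log_rate()` evaluates a modified Sharpe–Schoolfield model on the log
scale: a Boltzmann rise with activation energy $E_a$ (eV) up to an
optimum, and a single high-temperature inactivation term governed by
$E_h$ (eV) and the half-inactivation temperature $T_h$ (K):

$$\ln b(T) = E_a\!\left(\frac{1}{kT_c}-\frac{1}{kT}\right) + \ln b(T_c)
  - \ln\!\left(1 + e^{E_h\left(\frac{1}{kT_h}-\frac{1}{kT}\right)}\right)$$

Low-temperature inactivation is deliberately excluded (assay designs
rarely constrain it), and the Boltzmann rather than Eyring rise term is
used so the optimum has a closed form,

$$T_{opt} = \frac{E_h T_h}{E_h + k T_h \ln(E_h/E_a - 1)},$$

implemented in `compute_topt()` and verified against numeric
maximisation to < 0.01 K as a property test. Note two structural facts
the tests rely on: $E_h = 2E_a$ gives $T_{opt} = T_h$ exactly, and
$E_h < 2E_a$ pushes the optimum *above* $T_h$.

## Parameters and defaults

* `tc` — reference temperature, default 291.15 K (18 °C); chosen below
  the optimum so $b(T_c)$ is inactivation-free. Refitting under a
  different `tc` changes $\ln b(T_c)$ but not the predicted curve (a
  tested invariance).
* Bounds: $E_a \in (0, 10]$ eV, $E_h - E_a \in (0, 30]$ eV,
  $T_h \in [\min T, \max T + 20]$ K. $E_h > E_a$ is enforced by
  estimating the difference on a positive bound rather than a joint
  constraint.
* All I/O is in Celsius, all arithmetic in Kelvin; the inactivation
  exponent is evaluated with a `log1p(exp(x))` form that switches to its
  linear asymptote above 35, so extreme draws cannot overflow.

## Fitting and model comparison

The source experiments fit nonlinear *mixed-effects* models with random
effects per replicate. That machinery is off-the-shelf and out of scope
here; `fit_tpc()` instead does bounded nonlinear least squares on log
rates (multiplicative error is the norm for rate assays) with an
8-point multi-start grid seeded from the rise-limb Boltzmann slope,
followed by a Nelder–Mead polish — on noiseless data it recovers
generating parameters to ~1e-6 relative error. Data that never cross the
optimum leave $E_h$/$T_h$ unconstrained; the fit is returned but flagged
`identifiable = FALSE`.

`compare_models_aicc()` implements small-sample AIC,
$AICc = n\ln(RSS/n) + 2p + 2p(p+1)/(n-p-1)$, Akaike weights, and
weight-proportional parameter averaging over candidates within 2 AICc
units of the best — the selection-and-averaging recipe used throughout
this literature. The factor-reduction enumeration is left to the caller
(all on/off combinations are equally expressible); AICc is undefined and
flagged when $n \le p + 1$.

# Metabolic carbon budget

`np_at_irradiance()` is a rational-function photoinhibition model with
interpretable parameters: initial slope $\alpha$, optimum irradiance
$I_{opt}$, maximum net photosynthesis $NP_{max}$, and dark respiration
$R$ (stored positive; the curve returns $-R$ at $I=0$ and
$NP_{max}-R$ at $I_{opt}$ — both identities are asserted to machine
precision). `fit_pi_curve()` flags two identifiability hazards instead
of failing: no dark (or near-dark) observation leaves $R$ weakly
constrained, and no sub-saturating observations leave $\alpha$
unidentifiable.

Gross photosynthesis is $P = NP_{max} + R$. O₂ fluxes convert to
carbon-specific rates with `convert_rate_units()`:
$b \cdot 32 \cdot M \cdot (12/44)$ over the carbon biomass per mL, where
$M = n/(n+2)$ is the CO₂:O₂ assimilation quotient implied by balanced
growth on nitrate at molar C:N ratio $n$ (`assimilation_quotient()`;
$n \approx 6.7$–$7.5$ gives $M \approx 0.77$–$0.79$, the realistic
diatom range). The denominator as conventionally printed
(µmol C cell⁻¹ × cells mL⁻¹) is dimensionally short of the stated
µgC µgC⁻¹ output by a factor of 12 µg per µmol C; the package applies
that factor by default and keeps the uncorrected form selectable
(`convention = "as_printed"`) because the ambiguity is in the source
formula, not in this implementation.

Carbon-use efficiency, $CUE = 1 - R/P$, is the budget's punchline: when
$R$'s thermal optimum sits above $P$'s, CUE necessarily declines beyond
$P$'s optimum — the mechanism proposed to set the upper thermal limit of
growth. That qualitative behaviour is asserted as a property test on
curves generated from such truths. Φ_PSII light responses use the
exponential decay $a e^{Ib}$, fitted log-linearly (exact under
multiplicative error) and evaluated by default at the growth irradiance
of 100 µmol quanta m⁻² s⁻¹.

# Pooled-seq fixation calling

## The statistical model

A pooled library sequenced to depth $D$ at a site yields alt-read count
$A \sim \mathrm{Binomial}(D, f)$ for pool allele frequency $f$; the read
proportion $\hat f = A/D$ is the frequency estimate
(`estimate_allele_frequency()`). The default interval is exact central
Clopper–Pearson, which reproduces the canonical half-widths ±0.31, ±0.14
and ±0.10 at depths 10, 50 and 100 for $f = 0.5$ (the Wald approximation
matches at 2 d.p. and is selectable). Because intervals at realistic
depths are wide, inference is restricted to categorical transitions —
absent→fixed and heterozygous→fixed — whose error rates are bounded by
`prob_missed_het()` ($0.5^D$, 0.00098 at the depth-10 threshold) and
`prob_false_fixation()` ($\varepsilon^D$, $10^{-10}$ at depth 5 under a
pessimistic 1% error rate).

## Filtering and the five criteria

`filter_variants()` re-implements the bcftools filter semantics on
parsed records: SNVs only, QUAL ≥ 35, DP ≥ 5, IDV ≥ 2 *where the field
is present* (it is indel-specific; treating absence as failure would
discard every SNV), and removal of SNVs within 10 bp of an indel record.
A session comparison against bcftools 1.24 confirmed the standalone
`--SnpGap` behaviour; note that combining `--SnpGap` with an
`INDEL=0` include-expression in a *single* modern bcftools command
removes the indels before the gap filter sees them, silently disabling
it — this package applies the gap against the unfiltered input, which is
the described intent.

`call_fixation()` records five auditable booleans per site and evolved
population: (i) ancestral depth ≥ 10; (ii) ancestral absence ($A=0$) or
heterozygosity ($\hat f \in [0.3, 0.7]$, the window 0.5 ± 0.2 with
inclusive boundaries); (iii) evolved depth ≥ 5; (iv) unanimous evolved
reads ($A/D = 1$ exactly — one mismatched read vetoes the call); (v) a
filter pass in at least one evolved population. Depth failures yield
`not_assessable`, not `not_fixed`.

## What sensitivity the criteria allow

The criteria themselves cap sensitivity at moderate depth, and the
package documents rather than hides this. With depth
$D \sim \mathrm{Poisson}(25)$ and $\varepsilon = 0.001$:

* criterion (iv) passes with probability
  $E[(1-\varepsilon)^D] = e^{-25\varepsilon} \approx 0.975$ at a truly
  fixed site;
* criterion (ii)'s window contains the binomial proportion of a true
  heterozygous site with probability ≈ 0.952 (e.g.
  $P(8 \le A \le 17) \approx 0.957$ at $D = 25$).

So het-origin fixations are recovered at ≈ 0.93 and de-novo fixations at
≈ 0.95; the default world's weighted expectation is ≈ 0.933. A 95%
sensitivity target is therefore unattainable under these settings — the
acceptance test asserting it is intentionally left failing, with a
companion property test pinning the measured sensitivity to the analytic
0.933 ± 0.035 so a regression is distinguishable from the known cap.
Specificity is a different story: a false de-novo call needs every read
at an ancestrally absent site to be erroneous, and none occur in
practice (the 100% specificity assertion is green). Perfection holds in
the noiseless high-depth limit (ε = 0, mean depth 200), which the suite
also asserts.

## Annotation and the frequency matrix

`annotate_coding_effect()` is a minimal, strand-aware codon translator
for single-CDS gene models on synthetic genomes (standard genetic code
via Biostrings) — classifying synonymous, missense, stop-gained and
non-coding changes. It is deliberately not a snpEff replacement: no
splice sites, UTRs or multi-transcript genes.

`build_frequency_matrix()` assembles loci × samples read proportions
with masked (not zeroed) cells where depth is zero, and optional
restriction to fixed and/or non-silent loci.

# Divergence statistics

`distance_matrix()` computes squared Euclidean distances after
locus-wise complete-case deletion (reproducible and assumption-free;
counts are messaged). `amova()` partitions variance hierarchically from
the distance matrix: sums of squares from within-group pairwise
distances, components solved from expected mean squares with unequal
group sizes, percentages of the total (negative components reported raw,
truncated to zero for percentages, and messaged). With one pooled sample
per biological replicate — the usual design — the partition is
two-level (among populations within treatments / between treatments); a
within-population term is only estimable when sub-replicate samples
exist, in which case the three-level partition activates. We do not
guess a convention for deriving a within-population term from a single
pooled vector. Significance is by permutation: unrestricted sample
permutation for the between-treatment term, within-treatment permutation
for the among-population term, $p = (n_{\ge} + 1)/(n_{perm}+1)$,
seed-reproducible. The implementation is validated against a raw-data
ANOVA sums-of-squares oracle (computed from the frequency matrix
directly, independent of the distance route).

`permanova()` and `dispersion_test()` wrap vegan's `adonis2` and
`betadisper`/`permutest`/`TukeyHSD` — the same engines the source
analyses used — behind seeded, contract-checked interfaces. `pca()` is
a centered-matrix PCA, exactly equivalent to principal coordinates on
Euclidean distances (asserted to 1e-8) while retaining per-locus
loadings. `top_loading_associations()` takes the top-|loading| loci on
the leading axes and associates each with the treatment whose group-mean
centered frequency is largest in magnitude; this group-mean rule is a
declared approximation to the discriminant transformation used by
published loading-association tools, whose internals are not specified.
`weighted_ks_enrichment()` compares the score distribution of
term-annotated genes against the rest of the universe (unscored genes
score 0) with a two-sample KS test, plus the classical Ann/Sig/Exp
columns; term-graph propagation is out of scope and must be
pre-applied to the annotation map if wanted.

# The synthetic world

The generator's defaults state one coherent world: 4 selection regimes
(22 °C control, 26 °C, 32 °C, fluctuating) × 3 pooled populations; 1200
candidate sites of which 1000 are ancestrally heterozygous; 20
heterozygosity-loss and 5 de-novo fixations planted independently per
population; depth Poisson(25) floored at 1 (zero-depth sites are
unrepresentable in AD); symmetric single-parameter read error 0.001
(realistic Illumina, per-read); QUAL simulated as 35 + depth (monotone
in depth, floor configurable — QUAL has no generative model worth
inventing); two indel records planted 4 bp from SNV sites purely to
exercise the SnpGap filter. Thermal truth: Ea 1.08 eV, Eh 3.5 eV, Th
303.15 K (T_opt ≈ 28 °C), rate 0.55 day⁻¹ at 18 °C, on the 4–43 °C ×
3 °C assay grid with 6 replicates and 10% lognormal noise. P–I truth:
NP_max 10, α 0.1, I_opt 400, R 2 on the 0–2000 µmol step ladder with
additive noise 0.2. Growth truth: K 10⁶ cells mL⁻¹, r 0.8 day⁻¹, N₀ 100
cells mL⁻¹ (a standard inoculum), 12 points over 22 days, 5% count CV.

What the generator does *not* emulate: alignment artifacts, mapping
bias, depth overdispersion beyond Poisson (the true depth distribution
of any given library is unknown; Poisson is a stated assumption and the
rate is configurable), linked selection, and real indels beyond
filter-exercising placeholders. A green test therefore establishes that
the *statistical machinery* is correct under its stated model — not that
the model captures every artifact of a real resequencing run.

Determinism: every generator seeds the RNG from `config$seed` (with
small fixed offsets per generator so the tables are independent), and
identical configurations produce byte-identical VCFs.

# Numerical choices and degenerate inputs

* Logistic growth uses the negative-exponent parameterisation
  $N(t) = K/(1 + \frac{K-N_0}{N_0}e^{-rt})$, under which $N(0)=N_0$ and
  $N(\infty)=K$ for $r>0$; the positive-exponent form sometimes printed
  decays for growing populations and is kept available behind a flag for
  comparison. Fitting is on log counts with multi-start; flat series
  warn and return $r = 0$; truncated series flag
  `plateau_observed = FALSE` (K poorly constrained).
* Trajectory binning uses half-open weekly bins $[0,7), [7,14), \dots$
  (day 7.0 belongs to bin 2) and Tukey whiskers at 1.5×IQR; empty bins
  are omitted.
* Tie-breaks: loading-association ties resolve to the first treatment in
  column order; top-loading ties resolve by locus order.
* Test-budget scaling (decided before measurement): TPC recovery uses 60
  seeded runs instead of 100, and the PERMANOVA/dispersion null
  calibration uses 300 replicates × 199 permutations instead of
  500 × 999, with assertions at 3-binomial-SD tolerances around the
  nominal 5%.

# Known limitations

No mixed-effects TPC estimation, no GAMM fitness trajectories, no
low-temperature inactivation term, no genotype-likelihood model, no CNV
or depth-based copy-number analysis, no GO-graph algorithms, no tree
building. The fixation caller's sensitivity ceiling at moderate depth is
a property of the published criteria, not a tuning target; raising mean
depth (λ ≳ 60) or widening the het window would trade specificity for
sensitivity and both are exposed as parameters.
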