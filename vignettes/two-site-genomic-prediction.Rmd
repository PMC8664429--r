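---
title: "Genomic prediction and sparse testing across two sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction and sparse testing across two sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gptrial)
```

## The problem

Early-generation testing in a plant recurrent-selection program produces
hundreds of candidate genotypes whose progenies are evaluated in replicated
field trials at a small number of sites. Phenotyping every candidate at every
site is the largest cost of the cycle. Genomic prediction offers a way out:
calibrate a marker-based mixed model on the phenotyped fraction and predict
the merit of the rest, possibly borrowing information from a second,
cheaper-to-run site. `gptrial` implements this analysis end to end for the
canonical two-site case — a target site where selection decisions are made and
a second site whose data may (or may not, depending on the genetic correlation
between sites) improve predictions in the target — together with a simulator
that generates trials with known genetic truth, so every estimator in the
package can be exercised against data whose generating values are known.

## Models

All fits are plot-level linear mixed models estimated by REML.

**Single trial (Model 1).** For one site-by-year trial,

$$Y_{ijk} = \mu + r_i + b_{ij} + g_k + \varepsilon_{ijk},$$

with fixed intercept and replicate effects, random incomplete-block effects
$b \sim N(0, I\sigma^2_b)$ nested in replicates, random genotype effects
$g \sim N(0, M\sigma^2_g)$, and i.i.d. residuals. $M$ is the genotype
variance-covariance: the identity (for phenotype-only adjusted means), the
linear marker kernel $M = XX'/N$ with genotypes coded $-1/0/1$ (GBLUP), or a
Gaussian kernel $K(x_m, x_n) = \exp(-h\lVert x_m - x_n\rVert^2)$ (RKHS).

**Two sites with GxE (Model 2).** For the two sites of one year,

$$Y_{ijkl} = \mu + s_i + rs_{ij} + b(rs)_{ijk} + g_l + gs_{il} +
  \varepsilon_{ijkl},$$

adding a fixed site effect, replicates and blocks nested within sites, a
genotype main effect shared by both sites, site-specific genotype-by-site
interactions $gs \sim N(0,\,\mathrm{blockdiag}(M_{s_1}\sigma^2_{gs,s_1},
M_{s_2}\sigma^2_{gs,s_2}))$, and site-specific residual variances (the
residual covariance is the Kronecker product of an identity with the per-site
variance pair). Under GBLUP one shared kernel serves the main effect and both
interactions; under RKHS three kernels are built (complete data, and each
site separately) with independently estimated bandwidths.

**The REML engine.** `reml_fit()` maximises the restricted likelihood on
Henderson's mixed-model equations. Iterations start with a few EM steps
(which cannot leave the parameter space), switch to average-information (AI)
updates with step-halving, fall back to EM whenever an AI proposal is
rejected, and accelerate geometric EM trails with Aitken's $\Delta^2$
extrapolation — useful mainly when a component heads for the zero boundary.
Estimates are floored at $10^{-10}\times$ the phenotypic variance, so a "zero"
component is reported as a tiny positive number, matching how boundary
estimates are conventionally printed (e.g. "<0.001"). Convergence requires a
relative change below $10^{-8}$ in every component and a restricted-likelihood
change below $10^{-9}$ (500-iteration cap); the solver contains no
randomness, and the tests verify it against a direct grid search of the
restricted likelihood, against classical ANOVA estimators on balanced data,
and against `lme4` where the model permits.

**Numerical choices.** Aliased fixed-effect columns are dropped by pivoted QR
(reference-level constraint, recorded in the fit). Kernels that fail a
Cholesky get a ridge of $10^{-8}\times$ their mean diagonal. Genotypes present
in the kernel but absent from the data are predicted by the conditional
expectation $\hat u_{\mathrm{new}} = K_{\mathrm{new,obs}}
K_{\mathrm{obs,obs}}^{-1}\hat u_{\mathrm{obs}}$, which is the exact BLUP.

## Bandwidth of the Gaussian kernel

The RKHS bandwidth is chosen by maximising, over a 50-point log-spaced grid,
the profiled restricted likelihood of the one-random-effect model
$y = 1\mu + u + e$, $u \sim N(0, K_h\sigma^2_u)$ plus the log density of a
gamma prior (shape 3, scale 1.5). A subtlety deserves emphasis: the prior's
mode of 3 presupposes *median-standardised* squared distances. Raw marker
distances have medians of order $10^2$–$10^3$, putting all data-supported
bandwidths near $10^{-3}$, where a mode-3 prior would dominate the posterior
and recovery of a known bandwidth fails. `estimate_bandwidth()` therefore
standardises squared distances by their median, searches $h \in [10^{-3},
10^2]$ on that scale (ties break to the smaller $h$), and reports the raw
equivalent in the attribute `h_raw`. With a constant phenotype vector the
likelihood is flat and the prior mode $(3-1)\times 1.5 = 3$ is returned with
a warning. The point estimate is a MAP over the grid — deterministic and
cheap enough to re-estimate at every cross-validation cycle from the training
set's BLUP-adjusted phenotypes, which is how `run_cv()` uses it.

## Heritability

Trial-level repeatability uses the entry-mean form
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_\varepsilon/NR)$; the two-site
global heritability adds the mean interaction and mean residual variance,

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g +
  (\sigma^2_{gs,s_1} + \sigma^2_{gs,s_2})/NE +
  (\sigma^2_{\varepsilon,s_1} + \sigma^2_{\varepsilon,s_2})/NR}.$$

$NR$ and $NE$ — the harmonic mean numbers of plots and sites per genotype —
are computed from the actual design by `design_harmonic_means()`, never
hard-coded; the balanced two-site three-replicate lattice gives $NR = 6$,
$NE = 2$. The package ships the published variance-component table of a
two-site rice trial (`reference_variance_components()`) and the test suite
verifies that these printed inputs reproduce the printed heritabilities and
variance proportions. One cell (plant height, second year) computes to
0.62506 from the 2-dp-rounded inputs while the source prints 0.62 (its
printed SE is 0.03): rounding the inputs moves the ratio across the 0.625
boundary. The discrepancy is an input-rounding artifact, documented here and
asserted as such in the tests, not patched over.

## Cross-validation schemes

`make_partition()` implements four designs for predicting a 100-genotype
validation set in the target site, all with training size $s$:

* **SIN** — $s$ genotypes phenotyped in the target site only (Model 1);
* **BAL1** — the same $s$ genotypes phenotyped in both sites;
* **BAL2** — $s$ genotypes per site with a 50% overlap: $\lfloor s/2\rfloor$
  shared, the rest exclusive to one site, $2s - \lfloor s/2\rfloor$ distinct
  genotypes in total (on 334 genotypes with $s = 200$ this leaves exactly 34
  candidates, so the validation set shrinks to 34 with a warning);
* **IMB** — the whole population phenotyped in the other site, only $s$ in
  the target (the sparse-testing design).

The reference is the BLUP-adjusted mean ($\hat\mu + \hat g_k$, Model 1,
identity kernel) from the *complete* target-site data, computed once before
any masking. Predictive ability is the Pearson correlation between reference
and GEBVs over the validation set. The two-site GEBV is $\hat\mu + \hat
s_{\mathrm{target}} + \hat g_l$ plus, by default, the target-site interaction
BLUP $\hat{gs}_l$: the printed GEBV formula omits the interaction term, but
the genotype's site-specific merit is exactly what a breeder selecting for
the target site wants predicted, and the component flag
(`include_interaction`) lets either convention be used and is recorded in the
output. Iterations draw partitions from per-iteration seeds spawned by a
master seed (bit-reproducible); non-convergent iterations are excluded from
summaries and counted, never resampled; successive fits within a cell warm
start from the previous optimum, which changes nothing statistically (the
tests assert warm and cold fits agree) but roughly halves solver iterations.

## Eta-squared attribution

`fit_anova_eta2()` fits a fixed-effects ANOVA to per-iteration predictive
abilities (all factors categorical, including training size) and reports
$\eta^2 = SSq_{\mathrm{effect}}/SSq_{\mathrm{total}}$ per effect, with
sequential (type I) sums of squares in the declared factor order. In the
balanced tables `run_cv_grid()` produces, sequential and marginal sums of
squares coincide — the function asserts this by refitting with the factor
order reversed — so the ordering convention is immaterial where the package
uses it.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates (i) a $-1/0/1$ marker matrix with
per-marker allele frequencies drawn from a beta distribution, first-order
Gaussian-copula dependence along chromosomes standing in for linkage
disequilibrium, and marker-wise i.i.d. residual heterozygosity; (ii) true
genotypic values built from a shared marker-effect component plus independent
site-specific components, scaled so the between-site genetic correlation hits
$r_g$ and each site's genotypic variance hits the repeatability target
implied by `target_H2_trial`, the residual variance and the replicate count;
(iii) plot phenotypes over a 16-incomplete-block, 3-replicate lattice per
site, with random block assignment per replicate, and an optional second year
that reuses the genetics (zero generation effect, matching the temporal-check
finding that year, not generation, drives repeated-check differences) with
fresh noise and a site-wide shift.

Defaults state the world of the motivating trial: 334 genotypes, 992 SNPs on
12 chromosomes (rice), two sites with distinct means and residual variances
(site means 88 and 82 and residual variances 9 and 12, flowering-time-like in
days), three replicates, $r_g = 0.6$, per-site repeatability 0.8 — inside the
published ranges (trial repeatabilities 0.52–0.96, site correlations
0.13–0.62). Residual heterozygosity defaults to 0.05 and the adjacent-marker
copula correlation to 0.5; both are plausible for curated GBS data on
partially inbred material and neither is consequential downstream, since only
the coding and broad LD structure matter to the kernels.

The generator does **not** emulate: selection or drift across cycles (no
pedigree; heterozygosity is i.i.d., not Mendelian), spatial field trend
beyond block effects, genotype-by-year interaction, trait-specific error
distributions (all noise is Gaussian), or the male-sterility mating system of
the source population. A green simulation test therefore establishes that the
estimators recover the stated statistical structure — not that they would be
unbiased under field pathologies the generator never produces.

## Design choices made where the design was open

* **Plots per block** are `ceiling(n_genotypes / n_blocks)` (the source does
  not state them); 334 genotypes in 16 blocks leaves the last block short,
  which is logged and harmless since blocks enter only as a random effect.
* **Block assignment** is re-randomised per replicate, site and year — the
  lattice is represented exactly as the models treat it, with no alpha-design
  optimality machinery.
* **Year effects** default to a draw from $N(0, \sigma^2_{\varepsilon})$ per
  site for years after the first (the published site means shift by amounts
  of that order between years); set `year_shift` for a deterministic shift.
* **M0 bandwidth** (RKHS main effect): estimated from the across-site mean of
  the per-site adjusted phenotypes — the natural phenotype for a shared
  genotype effect; per-site kernels use their own site's adjusted phenotypes.
* **Outlier screening** replaces visual inspection with a deterministic rule:
  values outside median $\pm k\times$IQR per trait-site-year cell are set
  missing ($k = 3$ by default).
* **Null variance components**: a truly zero generating component is
  estimated on the boundary only about half the time (the classic 50:50
  boundary mixture), so "the estimate collapses" is asserted as a negligible
  share of phenotypic variance rather than literal equality with the floor.

## Known limitations

Model 2 is two-site by construction (the data model allows more sites; the
estimator does not). Standard errors of variance components and
heritabilities are not computed (the delta-method machinery was deliberately
left out of scope). The AI-REML solver is dense and in-memory: fine for
thousands of plots and ~1000 random-effect levels, not engineered for
populations an order of magnitude larger. RKHS bandwidth re-estimation at
every CV cycle is the dominant cost of RKHS cross-validation at scale.
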