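---
title: "Genomic and multi-omics BLUP for field trials: models and design choices"
author: "goblup package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and multi-omics BLUP for field trials: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goblup)
```

## The problem

Plant breeding programmes record yield and quality traits on replicated
field plots late in the cycle, while genotypes — and increasingly
high-dimensional omics layers such as leaf-tissue NMR metabolomic
intensities (MI) and near-infrared (NIR) absorbance spectra of malted
grain — are available much earlier and more cheaply.  `goblup` implements
the linear mixed models that turn these layers into predicted breeding
values: the genomic baseline (GBLUP) and a joint genomic-plus-omics
two-step model (GOBLUP) in which part of the genetic signal is mediated
by the omics features.

## The baseline mixed model

For one trait, the plot-level observation vector $y$ is modelled as

$$y = Xb + Z_g\,g + Z_l\,l + Z_{i_g}\,i_g + Z_{i_l}\,i_l + Z_s\,s\;(+\,Z_m m)\; + e$$

with a single fixed factor $b$ for the year-location-trial combination and
independent random terms:

* $g \sim N(0, G\sigma^2_g)$ — additive genomic values of the lines, with
  $G = QQ'/(2\sum_i p_i(1-p_i))$ the VanRaden relationship matrix built
  from dosages centered by twice the observed allele frequencies;
* $l \sim N(0, I\sigma^2_l)$ — genetic line effects not captured by the
  markers (epistasis, residual additive effects);
* $i_g$ — genomic-by-environment interaction, environment = year-location,
  with block-diagonal covariance $\mathrm{diag}(G,\dots,G)\,\sigma^2_{ig}$
  (one block per environment, zero covariance across environments);
* $i_l \sim N(0, I\sigma^2_{il})$ — line-by-environment interaction;
* $s \sim N(0, S\sigma^2_s)$ — spatial effect with
  $S = WW'/(\mathrm{tr}(WW')/n)$, where $W$ indicates for every plot its
  at most eight row/column-adjacent plots within the same trial
  (Chebyshev distance 1; the plot itself is excluded, and trials never
  share neighbours).  The trace normalization makes $\mathrm{tr}(S) = n$
  exactly, so the mean diagonal $d(S) = 1$;
* $m \sim N(0, I\sigma^2_m)$ — the micro-malting batch, included for the
  five malting traits (wort viscosity, beta-glucan, extract yield,
  filtering speed, wort colour) but not for grain yield or protein;
* $e \sim N(0, I\sigma^2_e)$.

The number of environments is whatever the data contain; nothing is
hard-coded.  Diagonal-zero adjacency was chosen for $W$ so that $S$
encodes pure neighbour similarity; trace normalization still yields a
unit mean diagonal.

## Omics kernels

Metabolomic intensities are used raw apart from column normalization
(each feature centered and scaled to sample variance one, zero-variance
columns dropped), giving the plot-level similarity
$Q_{MI} = M M'/q$ with $q$ the feature count; with sample-variance
scaling $\mathrm{tr}(Q_{MI}) = n-1$ exactly.

NIR spectra are first column-normalized and then differentiated with a
Savitzky-Golay filter (local least-squares polynomial fit; default window
11 points, polynomial order 2).  The derivative is taken with respect to
the sample index; the uniform 5 nm wavelength step makes this
proportional to d/dnm, and the constant factor is absorbed by the
subsequent scaling.  Edges are handled by fitting the boundary window and
evaluating its derivative at the edge points, so derivatives of
polynomials up to the fitted order are exact everywhere — this is the
property the unit tests pin down, and the filter parameters are plain
arguments, so no result depends on the defaults beyond that property.
The filter itself is delegated to `signal::sgolayfilt`, whose edge
handling satisfies this contract.

Because REML on the raw wavelength kernel converges poorly, the NIR
kernel is built from principal-component scores: eigendecomposition of
the feature correlation matrix, retaining the smallest number of
components $t$ whose cumulative explained variance reaches the target
(default 99%), and $Q_{NIR} = M_t M_t'/t$ with unstandardized scores.
On smooth spectra of the kind the generator produces, eight components
typically reach the target.

The stated preprocessing order (normalize, then derivative) is
implemented as the default; the reverse order is available by calling the
two functions in the other sequence, since each is a plain
`SpectraMatrix` transform.

## AI-REML

Variance components are estimated by maximizing the restricted
likelihood with average-information (AI) updates on the variance scale.
Numerical contract:

* the AI matrix $\tfrac12 W'PW$ (with $W$ the matrix of
  $V_k P y$ vectors) is PSD by construction; a relative ridge of $10^{-8}$
  stabilizes flat directions, and steps are capped so no component moves
  by more than tenfold in one iteration, then halved until the step is
  feasible and does not decrease the restricted log-likelihood;
* when no AI step is accepted, the EM update
  $\theta_k + (\theta_k^2/q_k)\,(y'PV_kPy - \mathrm{tr}(PV_k))$ is used —
  guaranteed uphill and (after clamping) feasible;
* components collapsing toward zero are pinned at
  $10^{-6}\,\mathrm{var}(y)$ and flagged as boundary components;
* convergence when the maximum relative parameter change falls below
  $10^{-8}$ or the log-likelihood change below $10^{-6}$; non-convergence
  is reported explicitly in the returned object, never silently;
* standard errors come from the inverse AI matrix at the optimum.

BLUPs are computed in the $V^{-1}$ form
$\hat u_k = \sigma^2_k K_k Z_k' P y$, which needs no kernel inverse and
therefore yields predictions for every kernel entity — in particular for
lines whose phenotypes are masked, through their genomic covariance with
the training lines.  Components may also be *held fixed* (including at
zero), which is how the equivalence "GOBLUP with zero omics variance
equals GBLUP" is both implemented and tested.

## Two-step GOBLUP

Step 1 adds to the baseline model a plot-level omics effect
$u \sim N(0, Q\,\sigma^2_u)$ (kernel $Q_{MI}$ or $Q_{NIR}$, identity
incidence over plots).  Step 2 refits the identical design (minus the
omics term) with the predicted $\hat u$ as the response, so the genomic
part of the omics signal is extracted as $\hat g_2$.  The combined
breeding value is $\hat g_1 + \hat g_2$: direct plus omics-mediated
genomic effect.

Step 2 uses the plot-level $\hat u$ (one record per observation); a
per-line aggregation is available as an option.  Adding a constant to
$\hat u$ is absorbed by the step-2 fixed effects, leaving $\hat g_2$
unchanged.  When $\hat\sigma^2_u$ collapses to the boundary, the fit is
reported as *failed* for that trait — the behaviour observed for traits
whose association with the omics layer is too weak to support the extra
variance component — and no combined breeding values are produced.
GOBLUP with the NIR kernel is refused for protein content (protein is
itself predicted from NIR spectra), overridable with `force = TRUE`.

## Heritability decomposition

With $d(\cdot)$ the mean diagonal of a kernel, the plot-level phenotypic
variance is assembled as

$$\hat\sigma^2_P = d(G)\hat\sigma^2_g + \hat\sigma^2_l +
  d(G)\hat\sigma^2_{ig} + \hat\sigma^2_{il} +
  (d(S)-\overline{S})\,\hat\sigma^2_s\;(+\,\hat\sigma^2_m)
  \;(+\,d(Q)\hat\sigma^2_u)\; + \hat\sigma^2_e,$$

and $\hat h^2 = d(G)\hat\sigma^2_g/\hat\sigma^2_P$.  For GOBLUP the total
heritability decomposes as $h^2 = h^2_d + c^2_m\,h^2_M$, where $h^2_d$ is
the step-1 direct heritability, $c^2_m = d(Q)\hat\sigma^2_u/\hat\sigma^2_{P,1}$
the omics variance ratio, and $h^2_M$ the step-2 heritability of the
omics-predicted component; the identity holds by construction.

Whether the genomic-by-environment term should carry the weight $d(G)$ or
1 is genuinely ambiguous in the field's reporting conventions; this
package uses $d(G)$ consistently for both the additive and interaction
terms and exposes `gxeDiagWeight = "one"` to reproduce the alternative
reading.  Presentation rounding is half-away-from-zero to two decimals
(`presentationRound`), matching how such tables are printed.

### Significance of feature heritabilities

Because $\hat h^2 \ge 0$ by construction, its null distribution under
$\sigma^2_g = 0$ is design-specific.  `h2SignificanceThreshold`
reconstructs it by simulation: phenotypes are drawn from the fitted null
model (all non-genomic components at their estimated variances on the
real design), the full model is refitted to each draw, and the empirical
$(1-\alpha)$ quantile of the refitted $\hat h^2$ is the significance
threshold (default 1,000 simulations; refit failures are counted and more
than 10% of them marks the threshold unreliable).

## Cross-validation and the LR ratios

Two schemes: **fivefold** (random near-equal partition of candidate
lines, stratified by breeding cycle so both cycles appear in every fold)
and **leave-one-breeding-cycle-out** (lines appearing in both cycles are
masked with their first cycle).  Control lines never enter validation
sets.  For each fold the variance components and BLUPs are refitted on
training observations only; for GOBLUP validation both the phenotypes and
the omics rows of masked plots are withheld (the omics kernel is
restricted to training plots), and an automated audit records per fold
that no masked plot or line reached any training design and that the
training omics kernel contains no masked plot.

Predictive ability is the Pearson correlation between masked lines'
GEBVs and their line-mean fixed-effect-corrected phenotypes
$y_c = y - X\hat b$ (whole-data fixed effects; GEBVs are per line, so
line-mean pairing is used).  The headline value is computed on the pooled
vector across folds; per-fold values are reported alongside.  Dispersion
is the regression slope $b_{w,p} = \mathrm{cov}(\hat g_w, \hat g_p)/
\mathrm{var}(\hat g_p)$ of whole-information on partial-information
GEBVs.  The LR-method accuracy ratios are correlations between GEBVs
under nested information states in the validation set — genomic only (g),
genomic+omics (gm), genomic+phenotypes (gp) and whole information (gmp) —
with values near one meaning the added information changes the ranking
little.

Standard errors are ordinary non-parametric bootstrap over validation
*lines* (the exchangeable unit), full sample size, 10,000 replicates by
default.  Models are compared by two-tailed paired t-tests on per-fold
predictive abilities at $\alpha = 0.01$ with a compact letter display
(letters are maximal cliques of the non-significance graph).  With fewer
than two paired units (leave-one-cycle-out with two cycles) the t-test is
reported as not applicable and a bootstrap interval for the pairwise
difference is substituted.

A fold whose GOBLUP training fit collapses at the omics boundary is
refitted with the omics variance fixed at zero — the degenerate model the
likelihood converged to — and flagged in the audit; a whole-data collapse
is an error by default (`allowDegenerate = TRUE` applies the same
fallback instead), mirroring the exclusion of such trait/model
combinations from validation reporting.

## The synthetic generator

`generateDataset` runs the analysis model forward so that every stage of
the package is testable without external data.  Its defaults describe a
two-cycle commercial spring-barley programme: 600 candidate lines over
two years and two locations, four trials per environment on a 10x14 grid,
two control lines replicated three times per trial, 8,198 SNPs with 0.3%
missingness, 30,468 metabolomic intensities and 141 NIR wavelengths
(950–1650 nm).  Key modelling choices:

* **Genotypes.** Candidate lines are F6-like selfed progeny of full-sib
  families (default ten sibs per cross, inbreeding coefficient 0.97,
  families never spanning cycles).  This supplies the within-programme
  relatedness that genomic prediction depends on and raises the mean
  diagonal of $G$ to about 1.8, as observed for inbred panels.  With
  `familySize = 1, inbreeding = 0` dosages are exactly Binomial(2, p)
  with per-SNP frequencies uniform on the configured interval — the
  setting used for the variance-recovery checks, where $\sigma^2_g$ is on
  the same scale as the realized additive variance.
* **Trait model.** Per trait, effects are drawn with the configured
  variances (the additive vector $g = Q\alpha$, Gaussian SNP effects, is
  rescaled so its realized variance matches exactly; the spatial vector
  is drawn with the layout's own $S$ kernel).  Default per-trait
  variances are calibrated to the magnitudes a malting-barley programme
  shows, with total phenotypic variances on the published scale.
* **Omics.** Features combine a moderate number of shared latent genetic
  factors (default 50) with independent noise so that per-feature
  heritabilities follow a configured mixture — by default 40% pure-noise
  features (empty spectral regions), and the rest mostly low with a small
  moderate-to-high tail up to 0.93.  Traits with a nonzero `omics`
  variance receive a plot-level contribution $M\beta$, creating a genuine
  omics-mediated genetic path.  NIR spectra are built from eight smooth
  basis curves (low-order polynomials plus Gaussian bumps) whose per-plot
  coefficients carry genetic and environmental parts; setting the NIR
  coefficient heritability range to zero produces the degenerate
  no-NIR-signal condition used to reproduce boundary collapse.
* **What is not emulated.** No linkage-disequilibrium map, no explicit
  pedigree across generations, no NMR peak chemistry, no scatter
  artefacts in the NIR spectra.  Passing tests therefore demonstrate the
  statistical machinery under the assumed covariance structure, not
  robustness to the measurement physics of real spectra.

The test suite and the acceptance script use scaled-down configurations
(40–300 lines, 100–400 SNPs, 2–300 omics features, one or two locations)
chosen so the full suite runs in a few minutes on one CPU while leaving
each check statistically informative; the defaults above remain the
reference conditions.

## Known limitations

* Univariate, dense-algebra REML: intended for up to a few thousand
  observations; no multi-trait models, no sparse machinery, no
  Bayesian samplers.
* The single-step joint omics likelihood is not implemented; only the
  two-step procedure with combined $\hat g_1 + \hat g_2$.
* Feature weighting inside the omics kernels assumes independence and
  equal heritability of features; a feature subset (e.g. only
  significantly heritable features, per the null-simulation threshold)
  can be supplied by subsetting the `SpectraMatrix` before kernel
  construction.
* Under a truly zero omics variance the boundary collapse of
  $\hat\sigma^2_u$ is a positive-probability event per dataset, not a
  certainty; tests of this behaviour scan several simulated datasets.

## A minimal run

```{r example, eval = FALSE}
cfg <- simConfig(nLines = 150, nSnps = 400, locations = c("LocA", "LocB"),
                 trialsPerEnv = 2, plotsGrid = c(6, 8), nMiFeatures = 300,
                 seed = 1)
ds <- generateDataset(cfg)
geno <- imputeMeanDosage(snpQC(ds$genotypes))
G <- vanRadenG(geno)
ph <- ds$phenotypes
S <- spatialKernel(data.frame(plot_id = ph$plot_id,
                              trial = paste(ph$year, ph$location, ph$trial),
                              row = ph$row, col = ph$col))
Q <- miKernel(normalizeColumns(ds$mi))
fit <- fitGoblup("GY", ph, G, S, Q)
h2Report(list(fitGblup("GY", ph, G, S), fit))
```
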