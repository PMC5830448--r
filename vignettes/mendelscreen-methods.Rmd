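---
title: "Detecting heritable methylation marks in multiplex families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heritable methylation marks in multiplex families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelscreen)
```

## The problem

Some DNA methylation marks behave like alleles: within a family they pass
from parent to child in a Mendelian pattern, even though no underlying
sequence variant is known. In multiplex (multiple-case) disease families
such heritable epimutations are candidate risk factors, but an
epigenome-wide screen cannot rely on bimodality alone — many CpG probes
are bimodal for purely technical or population reasons. The question the
package answers, probe by probe, is: *are these M-values bimodal in the
way a rare autosomal variant segregating through these pedigrees would
make them?*

## Models

At one CpG probe, let \(x_1,\dots,x_n\) be the M-values (log2 odds of
methylation, \(M = \log_2 \beta/(1-\beta)\)) of the typed family members
and \(y_i \in \{0,1\}\) a latent group membership with Gaussian
"penetrance" \(x_i \mid y_i \sim N(\mu_{y_i}, \sigma_{y_i}^2)\). Three
nested hypotheses are fitted by maximum likelihood:

* **Gaussian**: one component (\(\mu_0=\mu_1, \sigma_0=\sigma_1\));
  closed form.
* **Mixture**: \(y_i\) iid Bernoulli with *fixed* weights
  \((\alpha_0, \alpha_1) = (0.99, 0.01)\); only the component means and
  standard deviations are estimated, by EM.
* **Mendelian**: identical except that \(y\) is the carrier-status
  vector of a rare autosomal variant in the pedigrees, so the \(y_i\)
  are dependent within families. Fitted by a generalized EM whose
  E-step runs over whole families: for family \(f\) with typed carrier
  vector \(y^f\),
  \(P(y^f \mid x^f, \theta) \propto \prod_{i \in f}
  \phi(x_i \mid \mu_{y_i}, \sigma_{y_i}) \, P(y^f \mid \theta)\),
  and \(q_{i1} = \sum_{y^f : y_i = 1} P(y^f \mid x^f, \theta)\). The
  M-step is the usual weighted Gaussian update
  \(\mu_l = \sum_i w_{il} x_i\),
  \(\sigma_l = \sqrt{\sum_i w_{il}(x_i-\mu_l)^2}\) with
  \(w_{il} = q_{il}/\sum_j q_{jl}\).

The screening statistic is \(\Delta l = l_{\text{Mendel}} -
l_{\text{mix}}\): how Mendelian a probe is *over and above* how bimodal
it is. Both models have the same number of free parameters, so AIC and
BIC order them exactly as \(\Delta l\) does (the AIC difference is
\(2\Delta l\) with the \(2k - 2l\) convention), preferring the Mendelian
model whenever \(\Delta l > 0\).

## Segregation priors

\(P(y^f \mid \theta)\) comes from exact segregation analysis under the
rare-variant assumptions: no family has more than one carrier founder,
no founder is homozygous, and a heterozygous parent transmits to each
child independently with probability 1/2. Founder-origin configurations
get truncated-binomial weights \((1-\alpha_1)^F\) and
\(\alpha_1(1-\alpha_1)^{F-1}\), renormalised — the weighting is our
choice where only the restriction itself is forced; it keeps the founder
carrier marginal at \(\alpha_1\) to first order. Given the origin, the
carriers form a tree rooted at that founder (consanguineous pedigrees
are rejected rather than approximated, because a loop could create a
homozygote and make the single-origin model ill-defined), so each
family's joint prior is an exact downward tree recursion. Because the
prior depends only on pedigree structure and \(\alpha_1\) — never on
\(\mu,\sigma\) or the M-values — it is computed once per family over all
\(2^{|typed_f|}\) carrier vectors and reused across every probe and EM
iteration; `brute_force_prior()` is a deliberately independent
enumeration oracle used only for testing.

## Numerical choices

* EM convergence: relative log-likelihood change below `1e-8`, at most
  500 iterations; a variance floor `sigma_min = 1e-3` (M-value units)
  prevents the classic singular-likelihood collapse onto one point.
* Initialisation is deterministic: a 2-means split of the M-values
  (centres started at the extremes), both carrier orientations (rare
  group = upper or lower mode) tried, higher likelihood kept, ties
  resolved to "upper". The mixture optimum seeds the Mendelian fit.
* Because both likelihoods share one parameter space, `delta_l()`
  additionally re-runs the mixture EM from the Mendelian optimum and
  keeps the better mixture likelihood. Without this, a floor-variance
  spike found by one model but not the other can fake a positive
  (or negative) \(\Delta l\) on unimodal probes.
* Probes with fewer than 4 distinct values are skipped with a recorded
  reason; probe filtering (SNPs within 10 bp *inclusive*, sex
  chromosomes, detection failures under the exceeds-0.05 convention
  with a configurable aggregation policy) happens before screening.

## Carrier probabilities and association

After the screen, `carrier_posteriors()` evaluates each individual's
carrier probability at the plug-in Mendelian MLE — pedigree structure
and M-values only, never phenotypes. Untyped relatives are included by
extending the configuration sum to the extra member and marginalising
the rest exactly (`scope = "all_members"`, the default, since the
downstream survival model can use relatives with phenotype but no
array). `cox_lrt()` then tests disease association with age as the time
scale, Efron ties, a female-only risk set by default, and a
likelihood-ratio p-value. Under multiple-case ascertainment the hazard
ratio estimate is biased — it is reported but flagged — while the LRT
p-value keeps its null distribution; significance uses the Bonferroni
threshold `family_wise_alpha / k` for the `k` screened probes
(0.05/1000 = 5e-5 at the defaults).

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the structure the method assumes: 25
three-generation families with marry-in founders and roughly 210 typed
members (capped at 12 typed per family, since blood is rarely available
for everyone in a large family and the cap bounds the \(2^k\) prior
tables); a variant dropped from at most one carrier founder per family;
carrier-conditional M-values whose default modes (−3 and 0 M-units,
i.e. β ≈ 0.11 and 0.50, σ = 0.3) mirror the hypo/hemi-methylated
bimodal clusters typical of heritable 450K probes; and ascertained
phenotypes — female Weibull ages at onset (shape 3, scale 110: about a
20% cumulative risk by age 70), uniform censoring between 50 and 80,
and rejection sampling until each family has at least 2 affected
females. Mendelian and mixture sites share identical marginal
distributions by construction, so only family structure separates them.
Random streams for pedigree structure, variant drops, methylation noise
and phenotypes are separate, so one component can vary with the others
held fixed.

It does **not** emulate array technical noise, probe type differences,
normalisation artefacts, cell-composition variation, mQTL/LD
architecture, or parent-of-origin (imprinting) dynamics. Passing the
simulation studies therefore shows the estimator and tests are correct
under the model's own assumptions — not that real 450K data satisfy
those assumptions.

## Validation-study design choices

* **Parameter recovery** runs at a *common* simulated carrier frequency
  (0.3, with matching fit weights) rather than 0.01. With a rare
  variant a cohort carries only a handful of typed carriers, and no
  correct estimator can pin \(\mu_1, \sigma_1\) to ±0.1 from two or
  three observations; at frequency 0.3 the carrier component holds
  ~30 observations, so the study measures the EM, not binomial noise.
* **Posterior calibration** uses moderately separated components
  (means −3 and −1, σ = 0.6). At the default 10σ separation posteriors
  are all essentially 0 or 1 and the check is vacuous; at ~3σ the
  intermediate deciles are populated and calibration is actually
  tested. It runs at the unconditional rare frequency 0.01 —
  conditioning a drop on segregation would break calibration by design.
* **Type-I error of the Cox stage** refits the Mendelian model per null
  replicate and uses the fitted posteriors, mimicking the real
  pipeline; ascertainment is active (hazard ratio 1, families
  resampled to ≥2 affected females).
* **Ranking power** uses 20 Mendelian sites (drops conditioned on ≥2
  typed carriers, i.e. the variant actually segregates among sampled
  members) against 90 matched-marginal mixture and 90 Gaussian sites.
* Problem sizes in the test suite (replicate counts, 200-probe screens,
  10,000-individual calibration) are chosen to keep each study's Monte
  Carlo error well inside its acceptance band while remaining quick to
  run end to end.

## Known limitations

* Pedigrees with consanguinity loops are rejected, not approximated.
* \(\alpha_1\) is fixed, not estimated; two components only.
* The founder-configuration weighting under the ≤1-carrier restriction
  is a modelling choice (truncated binomial); alternatives would
  renormalise differently but agree as \(\alpha_1 \to 0\).
* Hazard-ratio magnitudes under ascertainment are biased by design and
  should never be interpreted; only the LRT p-values are meaningful.
* At the default cohort scale the association stage is powerful only
  when the causal variant is informative: with a rare variant (2–4
  typed carriers among ~90 females) the partial-likelihood information
  is a few units at most, so even a hazard ratio of 3 rarely clears a
  Bonferroni threshold. The Δl *screen* still ranks such sites highly —
  carrier detection and association power are different resources. In
  event-rich regimes (several events per family, ten-plus carriers) the
  LRT reaches far below 5e-5, as the test suite demonstrates.
* The per-probe fits assume complete M-value data for typed members;
  missing values must be handled upstream.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(seed = 1)          # 25 families, 200 sites
scr <- screen_sites(co$mat, co$ped, k = 20)
head(scr[, c("probe_id", "delta_l", "mu0", "mu1")])
res <- associate_screen(scr, co$mat, co$ped, co$phenotypes)
dplyr::filter(res, significant)
autoplot(scr)
```
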