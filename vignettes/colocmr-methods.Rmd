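---
title: "Methods: colocalisation-gated cis Mendelian randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalisation-gated cis Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocmr)
```

## The question the pipeline answers

Drug-target Mendelian randomisation (MR) asks whether genetic variation in
the gene encoding a drug target — here, variants in *GIP* and *GIPR* that
proxy glucose-dependent insulinotropic polypeptide signalling through their
association with type 2 diabetes liability — predicts downstream outcomes,
and whether those cis effects exceed what a general reduction in disease
liability would deliver. Because a cis region may harbour several causal
signals, MR at a gene region is only meaningful when the disease and the
outcome actually share a causal variant there. The pipeline therefore runs
in two stages: a Bayesian colocalisation screen gates each outcome, and only
colocalising outcomes proceed to instrument selection and MR.

## Colocalisation model

For each variant $i$ in a region we compute Wakefield's approximate Bayes
factor against the null from the trait's estimate $\hat\beta_i$ and standard
error $s_i$, under a $N(0, w)$ prior on the true effect. With
$V_i = s_i^2$, $r_i = w/(w+V_i)$ and $z_i = \hat\beta_i/s_i$,

$$\log \mathrm{ABF}_i = \tfrac12\left[\log(1-r_i) + r_i z_i^2\right].$$

Assuming at most one causal variant per trait in the region, the five causal
configurations — $H_0$ no association, $H_1$/$H_2$ one trait only, $H_3$
two distinct causal variants, $H_4$ one shared causal variant — have
unnormalised posterior weights

$$1,\quad p_1\sum_i B_{1i},\quad p_2\sum_i B_{2i},\quad
p_1 p_2 \Bigl(\sum_i B_{1i}\sum_j B_{2j} - \sum_i B_{1i}B_{2i}\Bigr),\quad
p_{12}\sum_i B_{1i}B_{2i},$$

where $B_{ti} = \mathrm{ABF}$ of variant $i$ for trait $t$ and
$(p_1, p_2, p_{12})$ are the per-variant priors. Colocalisation is declared
when $PP_4$ strictly exceeds 0.8. When the initial run instead favours
$H_3$, the outcome's most likely causal variant (argmax of its log ABF) and
every variant with $r^2 > 0.2$ against it are masked and the posterior is
recomputed; a $PP_4 > 0.8$ in this conditional run also passes the gate.
The same masking set defines the horizontal-pleiotropy filter applied to
the instruments.

Defaults and their rationale:

* priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the published defaults
  of the approximate-Bayes-factor colocalisation method; the analysis this
  package operationalises does not print its priors, so they are surfaced
  as configuration.
* prior effect variance $w = 0.2^2$ for quantitative traits (SD units) and
  $0.15^2$ for binary traits (log-odds) — likewise the method's published
  defaults. ABFs are invariant to rescaling a trait only if $w$ is rescaled
  with it; this is tested.
* the conditional re-run triggers whenever the initial run fails the gate
  *and* $H_3$ is the modal hypothesis. The source analysis says only that
  the re-run was performed "where colocalisation suggested separate causal
  variants"; modal-$H_3$ is the closest operational reading.
* "most likely causal SNP" is defined by ABF-argmax (ties broken by
  smallest position, then identifier, for deterministic output); whether
  the original analysis used ABF, p-value or external fine-mapping is not
  stated.

All Bayes-factor accumulation is in log space (log-sum-exp); the $H_3$
cross-term is a guarded log-subtraction clamped at zero so a single-variant
region yields exactly $PP_3 = 0$ rather than a small negative weight.

## Instrument selection

Cis instruments are variants inside a gene region (1-based inclusive
coordinates, zero flank by default — the strict "within the gene" reading;
a flank is configurable) satisfying, after harmonising the disease and
biomarker to a common effect allele:

1. disease association $p < 5\times10^{-6}$ (strict),
2. biomarker (HbA1c) association $p < 0.05$ (strict) with a
   direction-concordant effect — the glycaemic-control anchor that ties the
   diabetes-liability signal to target engagement,
3. greedy LD clumping at $r^2 > 0.1$: repeatedly retain the
   smallest-p unprocessed variant and discard everything in LD above the
   threshold with it,
4. the coloc-based pleiotropy filter described above.

The genome-wide comparator set applies filters 1–3 across all loci after
excluding the cis regions. Every filter records the variants it removed, so
the provenance trail reconciles exactly with candidates minus retained.
Concordance is evaluated after harmonisation (sign comparison is
meaningless otherwise), and clumping uses $r^2$ only, with no distance
window — the source analysis does not mention one.

## MR estimation and scales

Per-instrument Wald ratios $r_i = \hat\beta_{Y i}/\hat\beta_{X i}$ are
pooled by inverse-variance weighting with first-order weights
$w_i = \hat\beta_{X i}^2 / s_{Y i}^2$:

$$\hat\theta = \frac{\sum w_i r_i}{\sum w_i},\qquad
\mathrm{se}_{\text{fixed}} = \Bigl(\sum w_i\Bigr)^{-1/2},\qquad
Q = \sum_i w_i (r_i - \hat\theta)^2 .$$

"Random effects" is the multiplicative model:
$\mathrm{se} = \mathrm{se}_{\text{fixed}}\sqrt{\max(1, Q/(k-1))}$, which
inflates for heterogeneity but never deflates. Whether the original
analysis used multiplicative or additive (DerSimonian–Laird) random effects
is not stated; multiplicative is the standard summary-data implementation
and the one implemented here. The IVW estimate equals a weighted
least-squares regression of outcome on exposure betas through the origin,
which the test suite verifies against `lm()` to $10^{-10}$.

Estimates are computed per 1-unit higher disease log-odds and then
re-expressed **per halving of the odds**: multiply by $\ln 2$ and invert
the sign, so reported effects correspond to increased target signalling
(lower liability). This is the single place the sign convention lives; no
other module reasons about direction. The map is affine, so the p-value is
unchanged; for binary outcomes the rescaled log-OR and CI endpoints are
exponentiated. CIs use the normal 1.96 multiplier throughout, matching the
symmetric intervals the analysis format reports.

The cis-vs-genome-wide contrast is a two-sided z-test on the difference,
$z = (\hat\theta_{cis}-\hat\theta_{gw}) / \sqrt{se_{cis}^2+se_{gw}^2}$,
treating the two estimates as independent — an approximation justified by
excluding the cis regions from the comparator set. The sensitivity analysis
repeats IVW with the biomarker (HbA1c) as exposure; those estimates are
reported per 1 SD *lower* biomarker so that their direction matches the
per-halving convention, and the cross-exposure Pearson correlation is
computed on the oriented betas.

## The synthetic-data generator

No real GWAS data ship with the package; every test runs on summary
statistics the generator draws with the statistical structure the analysis
assumes:

* **LD**: first-order autoregressive correlation $R_{ij} = \rho^{|i-j|}$ by
  variant index — positive definite by construction, with one parameter
  ($\rho = 0.9$ in the 50-variant cis regions, $0.8$ in 20-variant
  background loci) controlling clumping and conditioning behaviour.
* **Marginal effects**: a sparse causal vector $b$ induces marginal
  expectation $R b$; estimates are drawn jointly from
  $N(Rb,\; S R S)$ with $S = \mathrm{diag}(se)$, so sampling noise is
  LD-correlated — without this, the $H_3$/$H_4$ distinction the gate rests
  on would be meaningless.
* **Standard errors**: $se = [2 n v(1-v)]^{-1/2}$ for quantitative traits
  in SD units and $se = [2 n v(1-v)\varphi(1-\varphi)]^{-1/2}$ for binary
  traits on the log-odds scale ($v$ = effect-allele frequency, $\varphi$ =
  case fraction) — the standard large-sample approximations.
* **Study conditions**: the default study uses a disease GWAS of
  $n = 898{,}130$ with case fraction 0.0825, a biomarker GWAS of
  $n = 344{,}182$, per-allele causal disease effects of 0.1 log-odds, a
  biomarker slope of 0.5 SD per log-odds, and an outcome panel (BMI, CRP,
  HDL-C, triacylglycerols shared at both gene regions; a binary CAD-like
  outcome shared at *GIP* only; an LDL-like outcome with distinct causal
  variants) whose per-log-odds slopes place the per-halving effects in the
  range reported for incretin-pathway drug-target analyses. Background
  loci carry a genome-wide glycaemic slope of 0.05 per log-odds. All seeds
  are explicit arguments; nothing touches global RNG state.

What the generator does **not** emulate: realistic human LD maps (the AR(1)
panel is a stand-in, not a claim about *GIP*/*GIPR* locus structure),
allele-frequency-dependent scaling of marginal per-allele effects (the
marginal expectation is taken as $Rb$ exactly), individual-level genotypes,
sample overlap between traits, and ancestry structure. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under these idealised conditions, not performance on any real
locus.

## Numerical and degenerate-input choices

* Posteriors normalise via log-sum-exp and must sum to 1 within $10^{-9}$.
* Conditional masking that removes every variant returns an explicit
  "undeterminable" result, never an exception; empty instrument sets are
  explicit objects that MR refuses with an instructive error.
* Boundary conventions are strict everywhere they are quoted strictly:
  $PP_4 = 0.8$ fails the gate, $r^2 = 0.2$ is not masked,
  $p = 5\times10^{-6}$ is not selected.
* Palindromic (A/T, C/G) variants are dropped in harmonisation when the
  minor-allele frequency exceeds 0.42 on either trait — a widely used
  heuristic; the band is configurable. Matching is by identifier, with
  position as a cross-check warning.
* Result tables serialise at full double precision (`%.17g`), so re-reading
  a report reproduces it bitwise; identical config + seed gives
  byte-identical outputs.

## Problem sizes used by the checks

The test suite and acceptance script size their simulations for a single
CPU: colocalisation calibration uses 200 replicates per scenario on a
50-variant panel at $n = 50{,}000$ and causal effect 0.15; IVW is checked
against the least-squares oracle on 1,000 random instrument sets;
replicate-averaged study estimates use 20 full pipeline runs; and the
end-to-end coverage check runs 200 complete pipeline replicates with
per-log-odds effect $\theta = -0.25$ at both gene regions, asking how often
the pooled per-halving 95% CI covers $-\theta\ln 2$.

## Known limitations

* The coverage check typically lands slightly below the nominal 95%
  (the acceptance script reports the realised value): clumped instruments
  retain residual LD up to $r^2 \approx 0.1$, and IVW weights treat them as
  independent; the multiplicative random-effects inflation only partly
  absorbs this. This mirrors the behaviour of the standard summary-data
  workflow the package implements.
* Single-causal-variant colocalisation only; multi-signal fine-mapping
  approaches are out of scope, as are MR-Egger, weighted-median and
  multivariable estimators, Steiger filtering, and winner's-curse
  correction (an F-statistic column is emitted for information only).
* The gate is stochastic near its threshold: an outcome whose true
  configuration is shared can still miss $PP_4 > 0.8$ in a given
  replicate, in which case it is (correctly, per the rule) not taken
  forward at that region.
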