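# colocmr

Colocalisation-gated cis Mendelian randomisation (MR) from GWAS summary
statistics, for drug-target genetic-evidence analyses.

The motivating use case: variants in the *GIP* and *GIPR* genes that
associate with type 2 diabetes liability proxy glucose-dependent
insulinotropic polypeptide (GIP) signalling, a drug target. The package
asks, for a panel of cardiometabolic outcomes, (i) whether the disease
association signal at each gene region **colocalises** with the outcome's
signal — i.e. whether they plausibly share a single causal variant — and,
only for outcomes that pass that gate, (ii) what the **cis MR estimate** of
genetically proxied target signalling is, expressed per halving of disease
odds, and (iii) whether it **exceeds the genome-wide estimate** expected
from reduced disease liability alone. It is aimed at genetic
epidemiologists who work with summary statistics and want the whole
screen-gate-estimate-contrast chain reproducible from one seeded config.

## The statistics at the core

**Colocalisation.** Per variant $i$ and trait, Wakefield's approximate
Bayes factor from estimate $\hat\beta_i$ and SE $s_i$ under a $N(0,w)$
effect prior: with $V_i = s_i^2$, $r_i = w/(w+V_i)$, $z_i = \hat\beta_i/s_i$,
$\log\mathrm{ABF}_i = \frac12[\log(1-r_i)+r_i z_i^2]$. Five-hypothesis
posterior (H0 none / H1, H2 one trait / H3 distinct variants / H4 shared
variant) with per-variant priors $p_1=p_2=10^{-4}$, $p_{12}=10^{-5}$;
gate: $PP_4 > 0.8$, with a conditional re-run (masking the outcome's lead
variant and everything at $r^2 > 0.2$ with it) when the initial run favours
H3.

**Instruments.** Within each gene region: disease $p < 5\times10^{-6}$,
HbA1c $p < 0.05$ with concordant direction, greedy clumping at
$r^2 > 0.1$, then a pleiotropy filter reusing the conditional-coloc mask.
A genome-wide comparator set applies the same filters outside the cis
regions.

**MR.** Wald ratios pooled by inverse-variance weighting
($w_i=\hat\beta_{Xi}^2/s_{Yi}^2$) with multiplicative random effects
($se \times \sqrt{\max(1, Q/(k-1))}$), then rescaled per halving of
disease odds ($\times\ln 2$, sign inverted; ORs for binary outcomes), and
contrasted against the genome-wide estimate with a two-sided z-test.

## Worked example

Everything below runs on synthetic data; `simulate_study()` draws GWAS
summary statistics for a disease (type 2 diabetes-like, n = 898,130), a
biomarker (HbA1c-like, n = 344,182) and six cardiometabolic outcomes over
two cis gene regions (50 variants, AR(1) LD) plus 30 background loci.

```r
library(colocmr)
study <- simulate_study(seed = 42)
cfg <- analysis_config(study$disease, study$biomarker, study$outcomes,
                       study$panel, study$regions, seed = 42)
report <- run_analysis(cfg)
report
#> <run_report> 14 coloc run(s), 18 MR row(s), 5 contrast(s); fingerprint 7f2cb0b6
```

Four quantitative outcomes colocalise at both regions, the binary
CAD-like outcome at *GIP* only, and the distinct-causal-variant LDL-like
outcome at neither (so it never reaches MR). The MR table (disease
exposure, per halving of disease odds; excerpt):

```r
report$mr[report$mr$exposure == "disease",
          c("outcome","source","k","beta","ci_low","ci_high","or")]
#>                    outcome     source  k    beta  ci_low ci_high    or
#>                        bmi     pooled  6 -0.1492 -0.1726 -0.1259    NA
#>                        crp     pooled  6 -0.1310 -0.1579 -0.1041    NA
#>            hdl_cholesterol     pooled  6  0.1426  0.1020  0.1832    NA
#>              triglycerides     pooled  6 -0.1432 -0.1679 -0.1185    NA
#>    coronary_artery_disease        GIP  3 -0.6403 -0.7476 -0.5331 0.527
#>    coronary_artery_disease genomewide 42 -0.0413 -0.0630 -0.0196 0.960
```

Read: halving the genetically proxied odds of disease via the cis variants
is associated with, e.g., 0.14 SD lower triacylglycerols (95% CI −0.17,
−0.12) and an odds ratio of 0.53 for the binary outcome — while the
genome-wide comparator (42 instruments across background loci) gives a
far smaller −0.04 SD. The contrast quantifies that gap:

```r
report$contrast
#>                   outcome   delta se_delta      z   pvalue
#>                       bmi -0.1140   0.0124  -9.18 4.47e-20
#>                       crp -0.0986   0.0142  -6.92 4.36e-12
#>           hdl_cholesterol  0.1088   0.0211   5.15 2.65e-07
#>             triglycerides -0.1046   0.0133  -7.86 3.94e-15
#>   coronary_artery_disease -0.5990   0.0558 -10.73 7.36e-27

report$cross_exposure_r     # HbA1c-exposure sensitivity vs main estimates
#> [1] 0.996
```

`render_forest_data(report)` returns the tidy table behind a forest plot
(estimates plus the genome-wide reference line), and
`write_report(report, "out/")` serialises every table, the instrument
provenance trails and the decision log at full precision.

A thin CLI covering `simulate` and `run` lives at
`inst/cli/colocmr.R` (installed under `system.file("cli", "colocmr.R",
package = "colocmr")`).

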