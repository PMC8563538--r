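#' Causal scenarios for summary-statistic simulation
#'
#' A scenario fixes the causal configuration of a two-trait region in the
#' vocabulary of the colocalisation hypotheses: `H0` no causal variant for
#' either trait, `H1`/`H2` one trait only, `H3` distinct causal variants,
#' `H4` a shared causal variant.
#'
#' @param hypothesis one of `"H0".."H4"`.
#' @param causal1,causal2 causal variant indices (into the panel) per trait.
#' @param beta1,beta2 per-allele causal effects on each trait's native scale
#'   (log-odds per allele for binary, SD units for quantitative), one per
#'   causal index.
#' @param n1,n2 GWAS sample sizes (>= 2).
#' @param type1,type2 `"quantitative"` or `"binary"`.
#' @param case_fraction1,case_fraction2 case fraction in (0,1) for binary
#'   traits.
#' @param trait1,trait2 trait names.
#' @param seed integer seed (NULL: current RNG stream).
#' @return a `scenario` object.
#' @export
scenario <- function(hypothesis = c("H4", "H0", "H1", "H2", "H3"),
                     causal1 = integer(), causal2 = integer(),
                     beta1 = numeric(), beta2 = numeric(),
                     n1 = 1e5, n2 = 1e5,
                     type1 = "quantitative", type2 = "quantitative",
                     case_fraction1 = NA, case_fraction2 = NA,
                     trait1 = "trait1", trait2 = "trait2", seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  causal1 <- as.integer(causal1); causal2 <- as.integer(causal2)
  ok <- switch(hypothesis,
    H0 = length(causal1) == 0 && length(causal2) == 0,
    H1 = length(causal1) > 0 && length(causal2) == 0,
    H2 = length(causal1) == 0 && length(causal2) > 0,
    H3 = length(causal1) > 0 && length(causal2) > 0 &&
         !any(causal1 %in% causal2),
    H4 = length(causal1) > 0 && identical(sort(causal1), sort(causal2)))
  if (!ok) abort("causal indices are inconsistent with hypothesis %s", hypothesis)
  if (length(beta1) != length(causal1) || length(beta2) != length(causal2))
    abort("one causal effect per causal index is required")
  if (!all(is.finite(c(beta1, beta2)))) abort("causal effects must be finite")
  if (n1 < 2 || n2 < 2) abort("sample sizes must be >= 2")
  structure(list(hypothesis = hypothesis,
                 causal1 = causal1, causal2 = causal2,
                 beta1 = beta1, beta2 = beta2, n1 = n1, n2 = n2,
                 type1 = type1, type2 = type2,
                 case_fraction1 = case_fraction1,
                 case_fraction2 = case_fraction2,
                 trait1 = trait1, trait2 = trait2, seed = seed),
            class = "scenario")
}

# Per-variant large-sample standard error of a marginal GWAS estimate.
# Quantitative traits (phenotype in SD units): se = 1/sqrt(2 n v (1 - v)).
# Binary traits (log-odds per allele):  se = 1/sqrt(2 n v (1-v) phi (1-phi)).
sumstats_se <- function(eaf, n, type, case_fraction = NA) {
  v <- 2 * n * eaf * (1 - eaf)
  if (type == "binary") {
    if (!is.finite(case_fraction) || case_fraction <= 0 || case_fraction >= 1)
      abort("case fraction must lie in (0, 1) for a binary trait")
    v <- v * case_fraction * (1 - case_fraction)
  }
  1 / sqrt(v)
}

#' Simulate one trait's marginal summary statistics over an LD panel
#'
#' The sparse causal effect vector `b` induces marginal effects with
#' expectation `R b`; estimates are drawn jointly from a multivariate normal
#' with covariance `S R S` where `S = diag(se)`, so sampling noise is
#' correlated across variants exactly as LD correlates the underlying
#' estimators. Standard errors follow the large-sample formulas in
#' [scenario()]'s documentation of trait scales.
#'
#' @param panel an `ld_panel`.
#' @param causal integer indices of causal variants (may be empty).
#' @param beta per-allele causal effects, one per index.
#' @param n sample size.
#' @param type `"quantitative"` or `"binary"`.
#' @param case_fraction case fraction for binary traits.
#' @param trait trait name.
#' @param seed integer seed (NULL: current RNG stream).
#' @return a `sumstats` object over the panel's variants.
#' @export
simulate_trait <- function(panel, causal = integer(), beta = numeric(),
                           n = 1e5, type = "quantitative",
                           case_fraction = NA, trait = "trait", seed = NULL) {
  m <- length(panel$variant_ids)
  if (length(causal) && (min(causal) < 1 || max(causal) > m))
    abort("causal indices must lie within the panel (1..%d)", m)
  if (n < 2) abort("sample size must be >= 2")
  b <- numeric(m); b[causal] <- beta
  se <- sumstats_se(panel$eaf, n, type, case_fraction)
  mu <- drop(panel$R %*% b)
  with_seed(seed, {
    L <- chol(panel$R)             # R = t(L) %*% L
    z <- drop(t(L) %*% stats::rnorm(m))
    bhat <- mu + se * z
    pv <- 2 * stats::pnorm(-abs(bhat / se))
    pv <- pmax(pv, .Machine$double.xmin)   # keep p in (0, 1]
    sumstats(data.frame(variant_id = panel$variant_ids, chr = panel$chr,
                        pos = panel$positions, ea = panel$ea, oa = panel$oa,
                        eaf = panel$eaf, beta = bhat, se = se, pvalue = pv,
                        n = n),
             trait = trait, trait_type = type)
  })
}

#' Simulate a two-trait region under a causal scenario
#'
#' Draws both traits' summary statistics over the same LD panel under the
#' scenario's causal configuration. Traits come from non-overlapping samples,
#' so their sampling noise is independent given the panel. The same scenario
#' and seed reproduce the output bit for bit.
#'
#' @param panel an `ld_panel`.
#' @param scen a [scenario()].
#' @return list with `sumstats` elements `trait1` and `trait2`.
#' @export
simulate_sumstats <- function(panel, scen) {
  stopifnot(inherits(scen, "scenario"))
  with_seed(scen$seed, {
    t1 <- simulate_trait(panel, scen$causal1, scen$beta1, scen$n1, scen$type1,
                         scen$case_fraction1, trait = scen$trait1, seed = NULL)
    t2 <- simulate_trait(panel, scen$causal2, scen$beta2, scen$n2, scen$type2,
                         scen$case_fraction2, trait = scen$trait2, seed = NULL)
    list(trait1 = t1, trait2 = t2)
  })
}

#' Simulate a disease / biomarker / outcome trio across independent loci
#'
#' Generates a block-diagonal genome of `n_loci` mutually independent AR(1)
#' loci. Each causal locus carries one causal variant whose per-allele
#' disease effect is `disease_effect`; the biomarker and outcome effects at
#' that variant are `biomarker_slope` and `outcome_slope` times the disease
#' effect, emulating traits downstream of the same liability signal. Each
#' locus is tagged with a region label (`locus_001`, ...) so gene-exclusion
#' filters can be tested.
#'
#' @param n_loci number of loci (>= 1).
#' @param n_variants variants per locus.
#' @param decay AR(1) adjacent-variant correlation.
#' @param causal_fraction fraction of loci carrying a causal variant.
#' @param disease_effect per-allele log-odds effect at causal variants.
#' @param biomarker_slope biomarker SD units per unit disease log-odds.
#' @param outcome_slope outcome effect per unit disease log-odds.
#' @param n_disease,n_biomarker,n_outcome GWAS sample sizes.
#' @param case_fraction disease case fraction.
#' @param outcome_type `"quantitative"` or `"binary"` outcome.
#' @param outcome_case_fraction case fraction for a binary outcome.
#' @param seed integer seed (NULL: current RNG stream).
#' @return list with elements `panel` (labelled block-diagonal `ld_panel`),
#'   `disease`, `biomarker`, `outcome` (`sumstats`) and `truth` (data.frame
#'   of causal variant ids and simulated effects).
#' @export
simulate_genomewide <- function(n_loci, n_variants = 20, decay = 0.8,
                                causal_fraction = 0.8, disease_effect = 0.1,
                                biomarker_slope = 0.5, outcome_slope = 0.05,
                                n_disease = 898130, case_fraction = 0.0825,
                                n_biomarker = 344182, n_outcome = 343992,
                                outcome_type = "quantitative",
                                outcome_case_fraction = NA, seed = NULL) {
  if (n_loci < 1) abort("n_loci must be >= 1")
  with_seed(seed, {
    chrs <- as.character(rep_len(setdiff(1:22, c(17, 19)), n_loci))
    panels <- lapply(seq_len(n_loci), function(i)
      make_ld_panel(n_variants, decay = decay, chr = chrs[i],
                    start = 1e6 + (i - 1) * 5e6, seed = NULL,
                    id_start = 1000000L + (i - 1L) * n_variants,
                    block = sprintf("locus_%03d", i)))
    panel <- bind_panels(panels)
    n_causal <- round(causal_fraction * n_loci)
    causal_loci <- sort(sample.int(n_loci, n_causal))
    causal_idx <- vapply(causal_loci, function(i)
      (i - 1L) * as.integer(n_variants) + sample.int(n_variants, 1L),
      integer(1))
    bd <- rep(disease_effect, length(causal_idx))
    disease <- simulate_trait(panel, causal_idx, bd, n_disease, "binary",
                              case_fraction, trait = "disease")
    biomarker <- simulate_trait(panel, causal_idx, biomarker_slope * bd,
                                n_biomarker, "quantitative",
                                trait = "biomarker")
    outcome <- simulate_trait(panel, causal_idx, outcome_slope * bd,
                              n_outcome, outcome_type, outcome_case_fraction,
                              trait = "outcome")
    truth <- data.frame(variant_id = panel$variant_ids[causal_idx],
                        block = panel$block[causal_idx],
                        beta_disease = bd,
                        beta_biomarker = biomarker_slope * bd,
                        beta_outcome = outcome_slope * bd)
    list(panel = panel, disease = disease, biomarker = biomarker,
         outcome = outcome, truth = truth)
  })
}

#' Simulate a full drug-target study
#'
#' Builds the complete synthetic dataset the pipeline analyses: two cis gene
#' regions (`GIP` on chromosome 17, `GIPR` on chromosome 19, 50 AR(1)
#' variants each by default) plus `n_bg_loci` independent background loci
#' providing genome-wide disease/biomarker signal, and one or more outcome
#' traits whose per-region causal configuration is controlled per outcome:
#'
#' * `"shared"` — the outcome's causal variant in that region is the disease
#'   causal variant, with effect `theta * disease_effect` (`theta` = outcome
#'   units per unit disease log-odds);
#' * `"distinct"` — the outcome has its own causal variant, chosen with
#'   r-squared below 0.05 to the disease causal variant;
#' * `"none"` — no outcome signal in the region.
#'
#' At background causal loci every outcome receives effect `theta_gw *
#' disease_effect`, the genome-wide liability slope against which the cis
#' estimates are contrasted.
#'
#' @param seed integer seed.
#' @param outcomes named list; each element a list with fields `type`
#'   (`"quantitative"`/`"binary"`), `n`, optional `case_fraction`, `scenario`
#'   (named character, one of shared/distinct/none per region), `theta`
#'   (named numeric per region), optional `distinct_effect` (per-allele
#'   outcome effect for distinct causal variants, default 0.03).
#' @param theta_gw genome-wide outcome-per-log-odds slope (an outcome config
#'   may override it with its own `theta_gw` field, e.g. to flip its sign
#'   for traits that improve with glycaemic control).
#' @param n_region_variants,region_decay cis-region panel settings.
#' @param n_bg_loci,bg_variants,bg_decay,bg_causal_fraction background locus
#'   settings.
#' @param disease_effect per-allele log-odds effect at causal variants.
#' @param biomarker_slope biomarker SD per unit disease log-odds.
#' @param n_disease,case_fraction,n_biomarker disease/biomarker GWAS sizes.
#' @return list with `panel`, `regions` (list of [region()]), `disease`,
#'   `biomarker`, `outcomes` (named list of `sumstats`) and `truth`.
#' @export
simulate_study <- function(seed = 1L,
                           outcomes = default_study_outcomes(),
                           theta_gw = 0.05,
                           n_region_variants = 50, region_decay = 0.9,
                           n_bg_loci = 30, bg_variants = 20, bg_decay = 0.8,
                           bg_causal_fraction = 0.8,
                           disease_effect = 0.1, biomarker_slope = 0.5,
                           n_disease = 898130, case_fraction = 0.0825,
                           n_biomarker = 344182) {
  region_defs <- list(
    GIP  = list(chr = "17", start = 47035000, id_start = 17000001L),
    GIPR = list(chr = "19", start = 45668000, id_start = 19000001L))
  with_seed(seed, {
    gene_panels <- lapply(names(region_defs), function(g) {
      rd <- region_defs[[g]]
      make_ld_panel(n_region_variants, decay = region_decay, chr = rd$chr,
                    start = rd$start, seed = NULL, id_start = rd$id_start,
                    block = g)
    })
    names(gene_panels) <- names(region_defs)
    chrs <- as.character(rep_len(setdiff(1:22, c(17, 19)), n_bg_loci))
    bg_panels <- lapply(seq_len(n_bg_loci), function(i)
      make_ld_panel(bg_variants, decay = bg_decay, chr = chrs[i],
                    start = 1e6 + (i - 1) * 5e6, seed = NULL,
                    id_start = 1000000L + (i - 1L) * bg_variants,
                    block = sprintf("locus_%03d", i)))
    panel <- bind_panels(c(gene_panels, bg_panels))

    regions <- lapply(names(region_defs), function(g) {
      p <- gene_panels[[g]]
      region(g, p$chr[1], min(p$positions), max(p$positions), flank = 0)
    })
    names(regions) <- names(region_defs)

    # disease causal variants: one per gene region, plus background loci
    gene_causal_local <- lapply(gene_panels, function(p)
      sample.int(n_region_variants, 1L))
    offset <- c(GIP = 0L, GIPR = as.integer(n_region_variants))
    gene_causal <- unlist(gene_causal_local) + offset[names(gene_panels)]
    n_bg_causal <- round(bg_causal_fraction * n_bg_loci)
    bg_causal_loci <- sort(sample.int(n_bg_loci, n_bg_causal))
    bg_causal <- 2L * as.integer(n_region_variants) +
      (bg_causal_loci - 1L) * as.integer(bg_variants) +
      vapply(bg_causal_loci, function(i) sample.int(bg_variants, 1L), integer(1))
    causal_idx <- c(gene_causal, bg_causal)
    bd <- rep(disease_effect, length(causal_idx))

    disease <- simulate_trait(panel, causal_idx, bd, n_disease, "binary",
                              case_fraction, trait = "t2d")
    biomarker <- simulate_trait(panel, causal_idx, biomarker_slope * bd,
                                n_biomarker, "quantitative", trait = "hba1c")

    out_list <- list(); truth_theta <- list()
    for (nm in names(outcomes)) {
      oc <- outcomes[[nm]]
      o_idx <- integer(); o_beta <- numeric()
      for (g in names(region_defs)) {
        scen_g <- oc$scenario[[g]]
        gi <- gene_causal[[g]]
        if (identical(scen_g, "shared")) {
          o_idx <- c(o_idx, gi)
          o_beta <- c(o_beta, oc$theta[[g]] * disease_effect)
        } else if (identical(scen_g, "distinct")) {
          cand <- which(panel$block == g &
                          panel$R[gi, ]^2 < 0.05)
          pick <- cand[sample.int(length(cand), 1L)]
          o_idx <- c(o_idx, pick)
          o_beta <- c(o_beta, oc$distinct_effect %||% 0.03)
        }
      }
      gw_slope <- oc$theta_gw %||% theta_gw
      o_idx <- c(o_idx, bg_causal)
      o_beta <- c(o_beta, rep(gw_slope * disease_effect, length(bg_causal)))
      out_list[[nm]] <- simulate_trait(panel, o_idx, o_beta, oc$n,
                                       oc$type, oc$case_fraction %||% NA,
                                       trait = nm)
      truth_theta[[nm]] <- oc$theta
    }
    truth <- list(disease_causal = panel$variant_ids[causal_idx],
                  gene_causal = stats::setNames(panel$variant_ids[gene_causal],
                                                names(gene_causal)),
                  disease_effect = disease_effect,
                  biomarker_slope = biomarker_slope,
                  theta = truth_theta, theta_gw = theta_gw)
    list(panel = panel, regions = regions, disease = disease,
         biomarker = biomarker, outcomes = out_list, truth = truth)
  })
}

#' Default outcome configurations for [simulate_study()]
#'
#' A cardiometabolic outcome panel covering every gate path the analysis
#' distinguishes: four quantitative traits (BMI, C-reactive protein,
#' HDL-cholesterol, triacylglycerols) sharing the disease causal variant at
#' both gene regions, a coronary-artery-disease-like binary trait sharing it
#' at GIP only, and an LDL-like quantitative trait with distinct causal
#' variants at both regions (which should fail the colocalisation gate).
#' Sample sizes mirror large published GWAS of these traits. `theta` is the
#' outcome effect per unit *higher* disease log-odds, so a positive `theta`
#' means the trait falls when the disease odds are halved; magnitudes are
#' set so the per-halving effects land where drug-target analyses of the
#' incretin pathway report them (about -0.17 SD for triacylglycerols,
#' -0.13 SD CRP, +0.19 SD HDL-C, -0.16 SD BMI, OR near 0.5 for CAD).
#'
#' @return named list of outcome configurations.
#' @export
default_study_outcomes <- function() {
  shared_both <- c(GIP = "shared", GIPR = "shared")
  list(
    bmi = list(
      type = "quantitative", n = 484680,
      scenario = shared_both, theta = c(GIP = 0.23, GIPR = 0.23)),
    crp = list(
      type = "quantitative", n = 343524,
      scenario = shared_both, theta = c(GIP = 0.19, GIPR = 0.19)),
    hdl_cholesterol = list(
      type = "quantitative", n = 315133,
      scenario = shared_both, theta = c(GIP = -0.27, GIPR = -0.27),
      theta_gw = -0.05),
    triglycerides = list(
      type = "quantitative", n = 343992,
      scenario = shared_both, theta = c(GIP = 0.25, GIPR = 0.25)),
    coronary_artery_disease = list(
      type = "binary", n = 184305, case_fraction = 0.33,
      scenario = c(GIP = "shared", GIPR = "none"),
      theta = c(GIP = 0.97, GIPR = 0)),
    ldl_cholesterol = list(
      type = "quantitative", n = 343621,
      scenario = c(GIP = "distinct", GIPR = "distinct"),
      theta = c(GIP = 0, GIPR = 0), distinct_effect = 0.03))
}

#' Write a scenario as a flat key-value config file
#'
#' @param scen a [scenario()].
#' @param path file path (YAML, flat keys).
#' @return the path, invisibly.
#' @export
write_scenario <- function(scen, path) {
  yaml::write_yaml(unclass(scen), path)
  invisible(path)
}

#' @rdname write_scenario
#' @param path file path.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scenario, x[!vapply(x, is.null, logical(1))])
}
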