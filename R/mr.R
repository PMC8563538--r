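#' Mendelian-randomisation estimates
#'
#' An `mr_estimate` stores the causal-effect estimate on the outcome scale
#' per unit of the exposure scale, its standard error, symmetric 95%% normal
#' CI, two-sided p-value, instrument count, Cochran heterogeneity statistic
#' `Q` (defined for >= 2 instruments), and descriptors of the exposure scale
#' (`per_logodds_exposure`, `per_halving_odds`, `per_sd_biomarker_lower`)
#' and outcome scale (`sd_units` or `log_or`).
#'
#' @name mr_estimate
NULL

new_mr_estimate <- function(beta, se, pvalue, n_instruments, Q = NA_real_,
                            scale = "per_logodds_exposure",
                            outcome_scale = "sd_units", method = "ivw",
                            or = NULL, or_ci = NULL) {
  structure(list(beta = beta, se = se,
                 ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                 pvalue = pvalue, n_instruments = n_instruments, Q = Q,
                 scale = scale, outcome_scale = outcome_scale,
                 method = method, or = or, or_ci = or_ci),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta %.4f (95%% CI %.4f, %.4f), se %.4f, p %.3g, k=%d%s [%s; outcome %s]\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$pvalue,
              x$n_instruments,
              if (is.finite(x$Q)) sprintf(", Q=%.2f", x$Q) else "",
              x$scale, x$outcome_scale))
  if (!is.null(x$or))
    cat(sprintf("  OR %.3f (95%% CI %.3f, %.3f)\n", x$or, x$or_ci[1], x$or_ci[2]))
  invisible(x)
}

#' Single-instrument Wald ratio
#'
#' First-order ratio estimate `by/bx` with standard error `se_y/|bx|`; the
#' second-order delta-method SE (adding the `by^2 se_x^2 / bx^4` term) is
#' available behind `second_order`.
#'
#' @param bx,se_x variant-exposure estimate and SE.
#' @param by,se_y variant-outcome estimate and SE.
#' @param second_order use the second-order delta-method SE.
#' @param outcome_scale `"sd_units"` or `"log_or"`.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(bx, se_x, by, se_y, second_order = FALSE,
                       outcome_scale = "sd_units") {
  if (bx == 0) abort("Wald ratio undefined for a null exposure association (bx = 0)")
  beta <- by / bx
  se <- if (second_order) sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
        else se_y / abs(bx)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(beta, se, p, 1L, scale = "per_logodds_exposure",
                  outcome_scale = outcome_scale, method = "wald_ratio")
}

#' Inverse-variance-weighted MR with multiplicative random effects
#'
#' Pools per-instrument Wald ratios `r_i = by_i / bx_i` with weights
#' `w_i = bx_i^2 / se_y_i^2` (the first-order inverse-variance weights):
#' `beta = sum(w r) / sum(w)`, fixed-effect `se = 1/sqrt(sum(w))`,
#' `Q = sum(w (r - beta)^2)`, and multiplicative random-effects
#' `se = fixed se * sqrt(max(1, Q/(k - 1)))` — the inflation never deflates.
#' CI and p-value use the normal approximation. This equals a
#' weighted-least-squares regression of `by` on `bx` through the origin.
#'
#' @param inst an `instrument_set` with outcome columns (see
#'   [attach_outcome()]), or a data.frame with columns `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param exposure which exposure columns to use: `"exposure"` (disease) or
#'   `"biomarker"` (sensitivity mode; requires `beta_biomarker`).
#' @param random_effects apply the multiplicative inflation (default TRUE).
#' @return an `mr_estimate`.
#' @export
ivw <- function(inst, exposure = c("exposure", "biomarker"),
                random_effects = TRUE) {
  exposure <- match.arg(exposure)
  if (nrow(inst) == 0)
    abort("cannot run IVW on an empty instrument set: no variants survived the selection filters")
  bx <- inst[[paste0("beta_", exposure)]]
  if (is.null(bx)) abort("instrument set lacks beta_%s", exposure)
  by <- inst$beta_outcome; se_y <- inst$se_outcome
  if (is.null(by) || is.null(se_y))
    abort("instrument set lacks outcome estimates; run attach_outcome() first")
  if (any(bx == 0)) abort("IVW requires nonzero exposure associations")

  k <- length(bx)
  r <- by / bx
  w <- bx^2 / se_y^2
  beta <- sum(w * r) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- if (k >= 2) sum(w * (r - beta)^2) else NA_real_
  infl <- if (random_effects && k >= 2) sqrt(max(1, Q / (k - 1))) else 1
  se <- se_fixed * infl
  p <- 2 * stats::pnorm(-abs(beta / se))
  scale <- if (exposure == "biomarker") "per_sd_biomarker" else "per_logodds_exposure"
  out_scale <- if (identical(attr(inst, "outcome_type"), "binary")) "log_or"
               else "sd_units"
  new_mr_estimate(beta, se, p, k, Q = Q, scale = scale,
                  outcome_scale = out_scale,
                  method = if (random_effects) "ivw_mre" else "ivw_fixed")
}

#' Re-express an estimate per halving of disease odds
#'
#' Converts an estimate on the per-1-unit-higher-log-odds exposure scale to
#' the effect of halving the disease odds (lowering the log-odds by
#' `log(2)`): beta, SE and CI are multiplied by `log(2)` and the sign is
#' inverted, so the reported direction corresponds to increased target
#' signalling / reduced disease liability. For binary outcomes the rescaled
#' log-OR and CI endpoints are additionally exponentiated to an odds ratio.
#' The p-value is unchanged (the map is affine). Applying the rescaling
#' twice is rejected via the scale descriptor.
#'
#' @param est an `mr_estimate` on scale `"per_logodds_exposure"`.
#' @return an `mr_estimate` on scale `"per_halving_odds"`.
#' @export
rescale_per_halving <- function(est) {
  if (!identical(est$scale, "per_logodds_exposure"))
    abort("rescale_per_halving expects scale 'per_logodds_exposure', got '%s'",
          est$scale)
  f <- -log(2)
  beta <- f * est$beta
  se <- abs(f) * est$se
  out <- new_mr_estimate(beta, se, est$pvalue, est$n_instruments, Q = est$Q,
                         scale = "per_halving_odds",
                         outcome_scale = est$outcome_scale,
                         method = est$method)
  if (identical(est$outcome_scale, "log_or")) {
    out$or <- exp(beta)
    out$or_ci <- exp(c(out$ci_low, out$ci_high))
  }
  out
}

#' Contrast a cis estimate against the genome-wide comparator
#'
#' Two-sided z-test of the difference between the cis and genome-wide
#' estimates: `delta = cis - gw`, `se = sqrt(se_cis^2 + se_gw^2)` (the two
#' estimates are treated as independent, justified by excluding the cis
#' regions from the comparator set), `z = delta/se`.
#'
#' @param cis,gw `mr_estimate`s on the same exposure and outcome scales.
#' @return list with `delta`, `se_delta`, `z`, `pvalue`.
#' @export
compare_estimates <- function(cis, gw) {
  if (!identical(cis$scale, gw$scale) ||
      !identical(cis$outcome_scale, gw$outcome_scale))
    abort("cannot compare estimates on different scales ('%s'/'%s' vs '%s'/'%s')",
          cis$scale, cis$outcome_scale, gw$scale, gw$outcome_scale)
  delta <- cis$beta - gw$beta
  se_delta <- sqrt(cis$se^2 + gw$se^2)
  z <- delta / se_delta
  list(delta = delta, se_delta = se_delta, z = z,
       pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Pearson correlation of MR estimates across exposure definitions
#'
#' Measures the concordance of two exposure definitions (e.g. disease
#' liability vs biomarker levels) by correlating the MR beta estimates over
#' the same outcomes, in the same order.
#'
#' @param estimates_a,estimates_b lists of `mr_estimate`s (or numeric beta
#'   vectors) of equal length >= 3.
#' @return Pearson correlation coefficient.
#' @export
cross_exposure_concordance <- function(estimates_a, estimates_b) {
  as_beta <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(e) e$beta, numeric(1))
  }
  a <- as_beta(estimates_a); b <- as_beta(estimates_b)
  if (length(a) != length(b)) abort("estimate vectors differ in length")
  if (length(a) < 3) abort("need at least 3 estimate pairs for a correlation")
  stats::cor(a, b, method = "pearson")
}
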