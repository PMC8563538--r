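#' Colocalisation priors
#'
#' Per-variant prior probabilities that a variant is causal for trait 1 only
#' (`p1`), trait 2 only (`p2`), or both (`p12`). Defaults are the published
#' defaults of the approximate-Bayes-factor colocalisation method.
#'
#' @param p1,p2,p12 priors; require `0 < p12 <= min(p1, p2)` and
#'   `p1 + p2 + p12 < 1`.
#' @return a `coloc_priors` object.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (!(p12 > 0 && p12 <= min(p1, p2))) abort("require 0 < p12 <= min(p1, p2)")
  if (p1 + p2 + p12 >= 1) abort("require p1 + p2 + p12 < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Single-variant log approximate Bayes factor
#'
#' Wakefield's approximate Bayes factor against the null for one variant,
#' from its estimate and standard error under a `N(0, w)` prior on the true
#' effect: with `V = se^2`, `r = w/(w + V)` and `z = beta/se`,
#' `log ABF = (log(1 - r) + r z^2) / 2`. The default prior effect variances
#' used throughout the package are `0.2^2` for quantitative traits (SD
#' units) and `0.15^2` for binary traits (log-odds scale).
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param w prior effect variance, > 0.
#' @return log approximate Bayes factor(s), same length as `beta`.
#' @examples
#' log_abf(0, 0.1, 0.04)     # 0.5 * log(0.2)
#' @export
log_abf <- function(beta, se, w) {
  if (!all(is.finite(beta)) || !all(is.finite(se)) || !is.finite(w))
    abort("log_abf requires finite inputs")
  if (any(se <= 0) || w <= 0) abort("log_abf requires se > 0 and w > 0")
  V <- se^2
  r <- w / (w + V)
  0.5 * (log1p(-r) + r * (beta / se)^2)
}

default_w <- function(trait_type) if (trait_type == "binary") 0.15^2 else 0.2^2

# Top variant by log ABF; ties broken by smallest position, then id.
top_by_labf <- function(labf, pos, ids) {
  o <- order(-labf, pos, ids)
  ids[o[1]]
}

new_coloc_result <- function(pp, labf1, labf2, top1, top2, ids, pos,
                             conditional = FALSE, masked = character(),
                             reference_variant = NA_character_,
                             undeterminable = FALSE) {
  structure(list(pp = pp, labf1 = labf1, labf2 = labf2,
                 top_variant1 = top1, top_variant2 = top2,
                 n_variants = length(ids), variant_ids = ids, positions = pos,
                 conditional = conditional, masked = masked,
                 reference_variant = reference_variant,
                 undeterminable = undeterminable),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  if (x$undeterminable) {
    cat("<coloc_result> undeterminable (all variants masked)\n")
    return(invisible(x))
  }
  cat(sprintf("<coloc_result>%s %d variants; PP0-PP4: %s\n",
              if (x$conditional) " [conditional]" else "",
              x$n_variants,
              paste(sprintf("%.3f", x$pp), collapse = " ")))
  invisible(x)
}

#' Five-hypothesis colocalisation posterior for a trait pair over a region
#'
#' Computes per-variant log approximate Bayes factors for each trait and the
#' posterior probabilities of the five causal configurations: H0 no causal
#' variant, H1/H2 causal for one trait only, H3 distinct causal variants,
#' H4 a shared causal variant. With per-variant log ABFs `L1`, `L2`, the
#' unnormalised posteriors are `1`, `p1 * sum(exp(L1))`, `p2 * sum(exp(L2))`,
#' `p1 p2 * (sum(exp(L1)) sum(exp(L2)) - sum(exp(L1 + L2)))` and
#' `p12 * sum(exp(L1 + L2))`; all accumulation is in log space and the H3
#' cross-term is a guarded log-subtraction so a single-variant region gives
#' exactly `PP3 = 0`.
#'
#' @param pair a [harmonise_pair()] result (trait 1 = column-`a` trait,
#'   trait 2 = column-`b` trait), typically restricted to a region first.
#' @param priors a [coloc_priors()].
#' @param w1,w2 prior effect variances; `NULL` uses the trait-type default
#'   (`0.2^2` quantitative, `0.15^2` binary).
#' @return a `coloc_result` with posteriors `pp` (PP0..PP4, summing to 1),
#'   per-variant log ABFs and each trait's top variant (argmax log ABF, ties
#'   to smallest position).
#' @export
coloc_posteriors <- function(pair, priors = coloc_priors(), w1 = NULL,
                             w2 = NULL) {
  if (nrow(pair) < 1) abort("colocalisation requires at least one shared variant")
  w1 <- w1 %||% default_w(attr(pair, "type_a") %||% "quantitative")
  w2 <- w2 %||% default_w(attr(pair, "type_b") %||% "quantitative")
  l1 <- log_abf(pair$beta_a, pair$se_a, w1)
  l2 <- log_abf(pair$beta_b, pair$se_b, w2)

  lS1 <- logsumexp(l1)
  lS2 <- logsumexp(l2)
  lS12 <- logsumexp(l1 + l2)

  lh <- c(H0 = 0,
          H1 = log(priors$p1) + lS1,
          H2 = log(priors$p2) + lS2,
          H3 = -Inf,
          H4 = log(priors$p12) + lS12)
  if (nrow(pair) > 1) {
    d <- lS12 - (lS1 + lS2)      # <= 0 analytically; clamp round-off
    if (d < 0)
      lh["H3"] <- log(priors$p1) + log(priors$p2) + lS1 + lS2 + log1mexp(d)
  }
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)

  ids <- pair$variant_id
  new_coloc_result(pp,
                   stats::setNames(l1, ids), stats::setNames(l2, ids),
                   top_by_labf(l1, pair$pos, ids),
                   top_by_labf(l2, pair$pos, ids),
                   ids, pair$pos)
}

#' Conditional colocalisation masking the outcome's lead signal
#'
#' Identifies the outcome's (trait 2's) most likely causal variant as the
#' argmax of its log approximate Bayes factor, removes it together with every
#' variant whose squared LD with it exceeds `r2_mask` (strictly; r-squared
#' equal to the threshold is retained), and re-runs the colocalisation
#' posterior on the remaining variants. If masking removes every variant the
#' result is flagged undeterminable rather than raising an error.
#'
#' @param pair a [harmonise_pair()] result over the region.
#' @param priors a [coloc_priors()].
#' @param w1,w2 prior effect variances (NULL: trait-type defaults).
#' @param panel an `ld_panel` containing the pair's variants.
#' @param r2_mask squared-LD masking threshold (default 0.2).
#' @return a `coloc_result` with `conditional = TRUE`, the masked variant
#'   identifiers and the reference (lead outcome) variant.
#' @export
conditional_coloc <- function(pair, priors = coloc_priors(), w1 = NULL,
                              w2 = NULL, panel, r2_mask = 0.2) {
  if (nrow(pair) < 1) abort("colocalisation requires at least one shared variant")
  w2v <- w2 %||% default_w(attr(pair, "type_b") %||% "quantitative")
  l2 <- log_abf(pair$beta_b, pair$se_b, w2v)
  top2 <- top_by_labf(l2, pair$pos, pair$variant_id)
  r2 <- panel_r2(panel, top2, pair$variant_id)
  masked <- pair$variant_id[pair$variant_id == top2 | r2 > r2_mask]
  keep <- !(pair$variant_id %in% masked)
  if (!any(keep)) {
    return(new_coloc_result(stats::setNames(rep(NA_real_, 5), paste0("PP", 0:4)),
                            numeric(), numeric(), NA_character_, NA_character_,
                            character(), numeric(), conditional = TRUE,
                            masked = masked, reference_variant = top2,
                            undeterminable = TRUE))
  }
  sub <- pair[keep, , drop = FALSE]
  attributes(sub)[c("trait_a", "trait_b", "type_a", "type_b")] <-
    attributes(pair)[c("trait_a", "trait_b", "type_a", "type_b")]
  class(sub) <- class(pair)
  res <- coloc_posteriors(sub, priors, w1, w2)
  res$conditional <- TRUE
  res$masked <- masked
  res$reference_variant <- top2
  res
}

#' Two-stage colocalisation decision
#'
#' Colocalisation is declared when the shared-causal posterior PP4 strictly
#' exceeds `pp_threshold` in the initial run, or — when the initial run
#' instead favoured distinct causal variants — when PP4 strictly exceeds the
#' threshold in the conditional re-run.
#'
#' @param initial `coloc_result` of the initial run.
#' @param conditional `coloc_result` of the conditional run, or `NULL`.
#' @param pp_threshold posterior-probability gate (default 0.8, strict).
#' @return list with `colocalises` (logical) and `evidence_path` (`"initial"`,
#'   `"conditional"` or `"none"`).
#' @export
coloc_decision <- function(initial, conditional = NULL, pp_threshold = 0.8) {
  pp4 <- unname(initial$pp["PP4"])
  if (isTRUE(pp4 > pp_threshold))
    return(list(colocalises = TRUE, evidence_path = "initial"))
  if (!is.null(conditional) && !conditional$undeterminable &&
      isTRUE(unname(conditional$pp["PP4"]) > pp_threshold))
    return(list(colocalises = TRUE, evidence_path = "conditional"))
  list(colocalises = FALSE, evidence_path = "none")
}

# Modal hypothesis label of a coloc result ("H0".."H4").
modal_hypothesis <- function(res) {
  if (res$undeterminable || anyNA(res$pp)) return(NA_character_)
  paste0("H", which.max(res$pp) - 1L)
}

#' Serialise colocalisation results to TSV
#'
#' One row per result: posteriors, top variants, variant counts and mask
#' size. An optional per-variant log-ABF table can be written alongside.
#'
#' @param results named list of `coloc_result` objects.
#' @param path output TSV path.
#' @param labf_path optional path for the per-variant log-ABF table.
#' @return `path`, invisibly.
#' @export
write_coloc_results <- function(results, path, labf_path = NULL) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(analysis = nm, run = if (r$conditional) "conditional" else "initial",
               PP0 = r$pp[1], PP1 = r$pp[2], PP2 = r$pp[3], PP3 = r$pp[4],
               PP4 = r$pp[5], top_variant_trait1 = r$top_variant1,
               top_variant_trait2 = r$top_variant2, n_variants = r$n_variants,
               n_masked = length(r$masked),
               undeterminable = r$undeterminable)
  })
  write_tsv_exact(do.call(rbind, rows), path)
  if (!is.null(labf_path)) {
    lab <- do.call(rbind, lapply(names(results), function(nm) {
      r <- results[[nm]]
      if (!r$n_variants) return(NULL)
      data.frame(analysis = nm, variant_id = r$variant_ids,
                 labf_trait1 = unname(r$labf1), labf_trait2 = unname(r$labf2))
    }))
    write_tsv_exact(lab, labf_path)
  }
  invisible(path)
}
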