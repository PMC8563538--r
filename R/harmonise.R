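#' Harmonise two traits' summary statistics to a shared effect allele
#'
#' Intersects two `sumstats` on variant identifier and re-expresses trait B's
#' estimates on trait A's effect allele before any joint analysis:
#'
#' * identical allele coding: kept unchanged;
#' * effect/other alleles swapped: B's beta is negated and its effect-allele
#'   frequency replaced by `1 - eaf`;
#' * alleles matching only after strand complement (with or without swap):
#'   complemented, then aligned as above;
#' * palindromic variants (A/T or C/G), whose strand cannot be resolved from
#'   alleles alone, are dropped whenever `min(eaf, 1 - eaf) >
#'   palindrome_eaf_band` on either trait;
#' * allele pairs irreconcilable after swap and complement are dropped.
#'
#' The action taken is recorded per variant. Position disagreements between
#' the two inputs are reported as a validation warning (matching is by
#' identifier; position and alleles are a cross-check).
#'
#' @param a,b `sumstats` objects. Output alleles follow `a`.
#' @param palindrome_eaf_band drop palindromic variants whose minor-allele
#'   frequency exceeds this value (default 0.42).
#' @return a `harmonised_pair`: data.frame with one row per shared retained
#'   variant (`variant_id, chr, pos, ea, oa, eaf_a, beta_a, se_a, pvalue_a,
#'   n_a, eaf_b, beta_b, se_b, pvalue_b, n_b, action`), with trait metadata
#'   in attributes.
#' @export
harmonise_pair <- function(a, b, palindrome_eaf_band = 0.42) {
  stopifnot(inherits(a, "sumstats"), inherits(b, "sumstats"))
  da <- a$data
  db <- b$data[match(da$variant_id, b$data$variant_id), , drop = FALSE]
  keep <- !is.na(db$variant_id)
  da <- da[keep, , drop = FALSE]; db <- db[keep, , drop = FALSE]

  if (nrow(da) && any(da$pos != db$pos | da$chr != db$chr))
    warning(sprintf("%d shared variant(s) disagree on position between traits '%s' and '%s'",
                    sum(da$pos != db$pos | da$chr != db$chr), a$trait, b$trait),
            call. = FALSE)

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal_a <- comp[da$ea] == da$oa              # palindromic in a's coding
  same  <- db$ea == da$ea & db$oa == da$oa
  swap  <- db$ea == da$oa & db$oa == da$ea
  csame <- unname(comp[db$ea]) == da$ea & unname(comp[db$oa]) == da$oa
  cswap <- unname(comp[db$ea]) == da$oa & unname(comp[db$oa]) == da$ea

  action <- rep("drop_irreconcilable", nrow(da))
  action[csame & !pal_a] <- "strand_flip"
  action[cswap & !pal_a] <- "strand_flip_allele_swap"
  action[swap]           <- "allele_swap"   # palindromic swap == complement
  action[same]           <- "none"

  maf <- function(f) pmin(f, 1 - f)
  amb <- pal_a & action != "drop_irreconcilable" &
    (maf(da$eaf) > palindrome_eaf_band | maf(db$eaf) > palindrome_eaf_band)
  action[amb] <- "drop_palindromic"

  flip <- action %in% c("allele_swap", "strand_flip_allele_swap")
  beta_b <- ifelse(flip, -db$beta, db$beta)
  eaf_b <- ifelse(flip, 1 - db$eaf, db$eaf)

  out <- data.frame(
    variant_id = da$variant_id, chr = da$chr, pos = da$pos,
    ea = da$ea, oa = da$oa,
    eaf_a = da$eaf, beta_a = da$beta, se_a = da$se, pvalue_a = da$pvalue,
    n_a = da$n,
    eaf_b = eaf_b, beta_b = beta_b, se_b = db$se, pvalue_b = db$pvalue,
    n_b = db$n,
    action = action, stringsAsFactors = FALSE)

  dropped <- startsWith(out$action, "drop")
  if (any(dropped))
    message(sprintf("harmonisation dropped %d variant(s): %s",
                    sum(dropped),
                    paste(sprintf("%s (%s)", out$variant_id[dropped],
                                  out$action[dropped]), collapse = ", ")))
  out <- out[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("harmonised_pair", "data.frame"),
            trait_a = a$trait, trait_b = b$trait,
            type_a = a$trait_type, type_b = b$trait_type,
            palindrome_eaf_band = palindrome_eaf_band)
}

#' @export
extract_region.harmonised_pair <- function(x, reg) {
  keep <- region_contains(reg, x$chr, x$pos)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_a", "trait_b", "type_a", "type_b",
                    "palindrome_eaf_band")] <-
    attributes(x)[c("trait_a", "trait_b", "type_a", "type_b",
                    "palindrome_eaf_band")]
  class(out) <- class(x)
  out
}

# Reconstruct the two sumstats halves of a harmonised pair (used when a
# pairwise operation is re-applied to its own output, e.g. idempotence).
pair_to_sumstats <- function(pair) {
  base <- pair[, c("variant_id", "chr", "pos", "ea", "oa")]
  list(
    a = sumstats(cbind(base, data.frame(eaf = pair$eaf_a, beta = pair$beta_a,
                                        se = pair$se_a, pvalue = pair$pvalue_a,
                                        n = pair$n_a)),
                 trait = attr(pair, "trait_a"), trait_type = attr(pair, "type_a")),
    b = sumstats(cbind(base, data.frame(eaf = pair$eaf_b, beta = pair$beta_b,
                                        se = pair$se_b, pvalue = pair$pvalue_b,
                                        n = pair$n_b)),
                 trait = attr(pair, "trait_b"), trait_type = attr(pair, "type_b")))
}
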