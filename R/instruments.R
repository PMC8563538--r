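#' Instrument sets
#'
#' An `instrument_set` is a data.frame of selected proxy variants with the
#' exposure (disease) and biomarker estimates harmonised to a common effect
#' allele, a region label per variant, and — once [attach_outcome()] has been
#' applied — the outcome estimates on the same allele. A provenance trail
#' records every filter applied and the variants it removed. An F-statistic
#' column `(beta/se)^2` is carried for information only.
#'
#' @name instrument_set
NULL

new_instrument_set <- function(df, provenance, exposure_scale, clump_r2) {
  structure(df, class = c("instrument_set", "data.frame"),
            provenance = provenance, exposure_scale = exposure_scale,
            clump_r2 = clump_r2)
}

set_attrs <- function(df, template, provenance = attr(template, "provenance")) {
  new_instrument_set(df, provenance, attr(template, "exposure_scale"),
                     attr(template, "clump_r2"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d variant(s), exposure scale '%s'\n",
              nrow(x), attr(x, "exposure_scale")))
  for (p in attr(x, "provenance"))
    cat(sprintf("  filter %-28s removed %d\n", p$filter, length(p$removed)))
  invisible(x)
}

#' Provenance trail of an instrument set
#'
#' @param inst an `instrument_set`.
#' @return list of `list(filter =, removed = <variant ids>)` in application
#'   order.
#' @export
provenance <- function(inst) attr(inst, "provenance")

#' Greedy LD clumping
#'
#' Repeatedly takes the unprocessed variant with the smallest p-value as
#' lead (ties broken by position, then identifier), retains it, and discards
#' every unprocessed variant whose squared LD with the lead strictly exceeds
#' `r2_threshold`.
#'
#' @param candidates data.frame with columns `variant_id`, `pvalue` and
#'   (for tie-breaking) `pos`.
#' @param panel an `ld_panel` containing every candidate.
#' @param r2_threshold squared-LD threshold (default 0.1, strict).
#' @return the retained subset of `candidates`, in lead-selection order.
#' @export
clump <- function(candidates, panel, r2_threshold = 0.1) {
  if (nrow(candidates) == 0) return(candidates)
  missing <- setdiff(candidates$variant_id, panel$variant_ids)
  if (length(missing))
    abort("clump candidate(s) missing from LD panel: %s",
          paste(missing, collapse = ", "))
  pos <- if ("pos" %in% names(candidates)) candidates$pos
         else panel$positions[match(candidates$variant_id, panel$variant_ids)]
  o <- order(candidates$pvalue, pos, candidates$variant_id)
  todo <- candidates$variant_id[o]
  keep <- character()
  while (length(todo)) {
    lead <- todo[1]
    keep <- c(keep, lead)
    r2 <- panel_r2(panel, lead, todo)
    todo <- todo[!(todo == lead | r2 > r2_threshold)]
  }
  out <- candidates[match(keep, candidates$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared filter cascade: p-thresholds, direction concordance, clumping.
# pair: harmonised disease (a) x biomarker (b) table with a block label.
apply_instrument_filters <- function(pair, p_exposure, p_biomarker, panel,
                                     r2_clump, provenance = list()) {
  step <- function(df, keep, name) {
    provenance[[length(provenance) + 1]] <<-
      list(filter = name, removed = df$variant_id[!keep])
    df[keep, , drop = FALSE]
  }
  cand <- step(pair, pair$pvalue_a < p_exposure, "exposure_p_threshold")
  cand <- step(cand, cand$pvalue_b < p_biomarker, "biomarker_p_threshold")
  cand <- step(cand, sign(cand$beta_a) == sign(cand$beta_b) &
                 cand$beta_a != 0 & cand$beta_b != 0, "direction_concordance")
  if (nrow(cand)) {
    kept <- clump(data.frame(variant_id = cand$variant_id,
                             pvalue = cand$pvalue_a, pos = cand$pos),
                  panel, r2_clump)
    cand <- step(cand, cand$variant_id %in% kept$variant_id,
                 sprintf("ld_clump_r2_%g", r2_clump))
  } else {
    provenance[[length(provenance) + 1]] <-
      list(filter = sprintf("ld_clump_r2_%g", r2_clump), removed = character())
  }
  list(df = cand, provenance = provenance)
}

instrument_df <- function(cand, block) {
  data.frame(variant_id = cand$variant_id, chr = cand$chr, pos = cand$pos,
             ea = cand$ea, oa = cand$oa, eaf = cand$eaf_a,
             beta_exposure = cand$beta_a, se_exposure = cand$se_a,
             pvalue_exposure = cand$pvalue_a,
             beta_biomarker = cand$beta_b, se_biomarker = cand$se_b,
             pvalue_biomarker = cand$pvalue_b,
             f_stat = (cand$beta_a / cand$se_a)^2,
             region = block, stringsAsFactors = FALSE)
}

#' Select cis instruments within a gene region
#'
#' Retains region variants associated with the disease below `p_exposure`
#' (strict) AND with the biomarker below `p_biomarker` (strict) AND with
#' direction-concordant effects on harmonised alleles (both raising or both
#' lowering), then applies greedy LD clumping at `r2_clump`. Every filter's
#' removals are recorded in the provenance trail. An empty final set is
#' returned as an explicit empty `instrument_set`.
#'
#' @param disease disease `sumstats` (the exposure; log-odds scale).
#' @param biomarker biomarker `sumstats` (e.g. HbA1c, SD units).
#' @param reg a [region()].
#' @param p_exposure,p_biomarker p-value thresholds (defaults `5e-6`, `0.05`).
#' @param panel an `ld_panel`.
#' @param r2_clump clumping threshold (default 0.1).
#' @param palindrome_eaf_band passed to [harmonise_pair()].
#' @return an `instrument_set` on the disease log-odds exposure scale.
#' @export
select_cis <- function(disease, biomarker, reg, p_exposure = 5e-6,
                       p_biomarker = 0.05, panel, r2_clump = 0.1,
                       palindrome_eaf_band = 0.42) {
  pair <- extract_region(harmonise_pair(disease, biomarker,
                                        palindrome_eaf_band), reg)
  prov <- list(list(filter = sprintf("cis_region_%s", reg$name),
                    removed = character()))
  res <- apply_instrument_filters(pair, p_exposure, p_biomarker, panel,
                                  r2_clump, prov)
  new_instrument_set(instrument_df(res$df, reg$name), res$provenance,
                     exposure_scale = "per_logodds_exposure", clump_r2 = r2_clump)
}

#' Select the genome-wide comparator instrument set
#'
#' Applies the same filter cascade as [select_cis()] genome-wide, after
#' removing every variant inside the excluded regions (flank included).
#'
#' @param disease,biomarker `sumstats`.
#' @param exclude list of [region()]s to exclude (e.g. the cis gene regions).
#' @param p_exposure,p_biomarker,panel,r2_clump,palindrome_eaf_band as in
#'   [select_cis()].
#' @return an `instrument_set` with per-variant region labels taken from the
#'   panel's block labels (chromosome if unlabelled).
#' @export
select_genomewide <- function(disease, biomarker, exclude = list(),
                              p_exposure = 5e-6, p_biomarker = 0.05, panel,
                              r2_clump = 0.1, palindrome_eaf_band = 0.42) {
  pair <- harmonise_pair(disease, biomarker, palindrome_eaf_band)
  inside <- rep(FALSE, nrow(pair))
  for (reg in exclude) inside <- inside | region_contains(reg, pair$chr, pair$pos)
  prov <- list(list(filter = "exclude_cis_regions",
                    removed = pair$variant_id[inside]))
  pair2 <- pair[!inside, , drop = FALSE]
  res <- apply_instrument_filters(pair2, p_exposure, p_biomarker, panel,
                                  r2_clump, prov)
  blk <- panel$block[match(res$df$variant_id, panel$variant_ids)]
  blk[is.na(blk)] <- res$df$chr[is.na(blk)]
  new_instrument_set(instrument_df(res$df, blk), res$provenance,
                     exposure_scale = "per_logodds_exposure", clump_r2 = r2_clump)
}

#' Attach harmonised outcome estimates to an instrument set
#'
#' Harmonises the outcome against the disease summary statistics and joins
#' the outcome estimates (on the instrument's effect allele) onto the
#' instrument set. Instruments absent from the outcome GWAS (or dropped in
#' harmonisation) are removed with a provenance record.
#'
#' @param inst an `instrument_set`.
#' @param disease the disease `sumstats` the instruments were selected from.
#' @param outcome outcome `sumstats`.
#' @param palindrome_eaf_band passed to [harmonise_pair()].
#' @return the `instrument_set` with `beta_outcome`, `se_outcome`,
#'   `pvalue_outcome` columns and an `outcome_type` attribute.
#' @export
attach_outcome <- function(inst, disease, outcome, palindrome_eaf_band = 0.42) {
  pair <- suppressMessages(harmonise_pair(disease, outcome, palindrome_eaf_band))
  m <- match(inst$variant_id, pair$variant_id)
  keep <- !is.na(m)
  prov <- c(attr(inst, "provenance"),
            list(list(filter = sprintf("outcome_missing_%s", outcome$trait),
                      removed = inst$variant_id[!keep])))
  df <- inst[keep, , drop = FALSE]
  mm <- m[keep]
  df$beta_outcome <- pair$beta_b[mm]
  df$se_outcome <- pair$se_b[mm]
  df$pvalue_outcome <- pair$pvalue_b[mm]
  rownames(df) <- NULL
  out <- new_instrument_set(as.data.frame(df), prov,
                            attr(inst, "exposure_scale"), attr(inst, "clump_r2"))
  attr(out, "outcome_type") <- outcome$trait_type
  attr(out, "outcome_trait") <- outcome$trait
  out
}

#' Remove instruments tagging the outcome's distinct causal signal
#'
#' When the initial colocalisation favoured distinct causal variants, the
#' conditional re-run identified the outcome's lead variant and the set of
#' variants in LD with it; instruments exhibiting potential horizontal
#' pleiotropy — squared LD strictly above `r2_mask` with that lead variant
#' (or the lead itself) — are removed, reusing exactly the conditional-run
#' masking rule. When no conditional run was performed (the pair
#' colocalised directly) the set is returned unchanged.
#'
#' @param inst an `instrument_set`.
#' @param outcome_coloc the `coloc_result` of the conditional run for this
#'   region/outcome, or `NULL` if none was triggered.
#' @param panel an `ld_panel`.
#' @param r2_mask squared-LD masking threshold (default 0.2).
#' @return the filtered `instrument_set` with the removal recorded in
#'   provenance.
#' @export
filter_pleiotropy <- function(inst, outcome_coloc = NULL, panel,
                              r2_mask = 0.2) {
  if (is.null(outcome_coloc) || !isTRUE(outcome_coloc$conditional) ||
      is.na(outcome_coloc$reference_variant))
    return(inst)
  ref <- outcome_coloc$reference_variant
  if (nrow(inst) == 0) remove <- logical(0)
  else {
    r2 <- panel_r2(panel, ref, inst$variant_id)
    remove <- inst$variant_id == ref | r2 > r2_mask
  }
  prov <- c(attr(inst, "provenance"),
            list(list(filter = sprintf("pleiotropy_mask_r2_%g", r2_mask),
                      removed = inst$variant_id[remove])))
  df <- inst[!remove, , drop = FALSE]
  rownames(df) <- NULL
  out <- new_instrument_set(as.data.frame(df), prov,
                            attr(inst, "exposure_scale"), attr(inst, "clump_r2"))
  attr(out, "outcome_type") <- attr(inst, "outcome_type")
  attr(out, "outcome_trait") <- attr(inst, "outcome_trait")
  out
}

#' Combine instrument sets from several regions
#'
#' @param ... `instrument_set` objects with identical columns (e.g. the two
#'   cis regions' sets) and disjoint variants.
#' @return pooled `instrument_set`; provenance trails are concatenated.
#' @export
pool_instruments <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  df <- do.call(rbind, lapply(sets, as.data.frame))
  rownames(df) <- NULL
  if (anyDuplicated(df$variant_id)) abort("pooled instrument sets overlap")
  out <- new_instrument_set(df, do.call(c, lapply(sets, attr, "provenance")),
                            attr(sets[[1]], "exposure_scale"),
                            attr(sets[[1]], "clump_r2"))
  attr(out, "outcome_type") <- attr(sets[[1]], "outcome_type")
  attr(out, "outcome_trait") <- attr(sets[[1]], "outcome_trait")
  out
}

#' Serialise an instrument set
#'
#' Writes one TSV row per variant and, optionally, a sidecar plain-text
#' provenance log (one filter per line).
#'
#' @param inst an `instrument_set`.
#' @param path output TSV path.
#' @param provenance_path optional sidecar log path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(inst, path, provenance_path = NULL) {
  write_tsv_exact(as.data.frame(inst), path)
  if (!is.null(provenance_path)) {
    lines <- vapply(attr(inst, "provenance"), function(p)
      sprintf("%s\tremoved=%d\t%s", p$filter, length(p$removed),
              paste(p$removed, collapse = ",")), character(1))
    writeLines(lines, provenance_path)
  }
  invisible(path)
}
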