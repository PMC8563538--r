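#' Analysis configuration
#'
#' Collects the inputs and every threshold of the analysis. Inputs may be
#' given either as in-memory objects (`sumstats`, `ld_panel`, `region`
#' lists) or as file paths (tab-delimited summary statistics in the
#' [default_col_map()] dialect, an LD-panel manifest + matrix pair, and a
#' region TSV), which are read lazily by [run_analysis()].
#'
#' @param disease disease (exposure) `sumstats` or file path.
#' @param biomarker biomarker `sumstats` or file path.
#' @param outcomes named list of outcome `sumstats`, or named character
#'   vector of file paths (names `<trait>` or `<trait>:binary`).
#' @param panel `ld_panel`, or character vector `c(manifest, matrix)`.
#' @param regions list of [region()]s, or a region-TSV path.
#' @param pp_threshold colocalisation gate on PP4 (strict; default 0.8).
#' @param r2_mask conditional-coloc / pleiotropy LD mask (strict; default 0.2).
#' @param r2_clump clumping threshold (strict; default 0.1).
#' @param p_exposure,p_biomarker instrument p-value thresholds (strict;
#'   defaults `5e-6` and `0.05`).
#' @param palindrome_eaf_band palindromic-variant drop band (default 0.42).
#' @param priors a [coloc_priors()].
#' @param w_quantitative,w_binary prior effect variances by trait type.
#' @param pooled_requires_both require colocalisation at every region for
#'   the pooled cis analysis (default TRUE).
#' @param functional_variants optional character vector of variant ids for
#'   single-variant (Wald-ratio) sensitivity MR.
#' @param seed integer seed recorded in the report fingerprint.
#' @return an `analysis_config`.
#' @export
analysis_config <- function(disease, biomarker, outcomes, panel, regions,
                            pp_threshold = 0.8, r2_mask = 0.2,
                            r2_clump = 0.1, p_exposure = 5e-6,
                            p_biomarker = 0.05, palindrome_eaf_band = 0.42,
                            priors = coloc_priors(),
                            w_quantitative = 0.2^2, w_binary = 0.15^2,
                            pooled_requires_both = TRUE,
                            functional_variants = NULL, seed = 1L) {
  chk01 <- function(x, nm) if (!(x > 0 && x < 1)) abort("%s must lie in (0, 1)", nm)
  chk01(pp_threshold, "pp_threshold"); chk01(r2_mask, "r2_mask")
  chk01(r2_clump, "r2_clump"); chk01(p_biomarker, "p_biomarker")
  if (!(p_exposure > 0 && p_exposure < 1)) abort("p_exposure must lie in (0, 1)")
  stopifnot(inherits(priors, "coloc_priors"))
  structure(list(disease = disease, biomarker = biomarker,
                 outcomes = outcomes, panel = panel, regions = regions,
                 pp_threshold = pp_threshold, r2_mask = r2_mask,
                 r2_clump = r2_clump, p_exposure = p_exposure,
                 p_biomarker = p_biomarker,
                 palindrome_eaf_band = palindrome_eaf_band, priors = priors,
                 w_quantitative = w_quantitative, w_binary = w_binary,
                 pooled_requires_both = pooled_requires_both,
                 functional_variants = functional_variants,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# Materialise path-based config entries; in-memory objects pass through.
resolve_inputs <- function(config) {
  cfg <- config
  if (is.character(cfg$disease))
    cfg$disease <- read_sumstats(cfg$disease, "disease", "binary")
  if (is.character(cfg$biomarker))
    cfg$biomarker <- read_sumstats(cfg$biomarker, "biomarker", "quantitative")
  if (is.character(cfg$outcomes)) {
    paths <- cfg$outcomes
    cfg$outcomes <- lapply(names(paths), function(nm) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      read_sumstats(paths[[nm]], parts[1],
                    if (length(parts) > 1 && parts[2] == "binary") "binary"
                    else "quantitative")
    })
    names(cfg$outcomes) <- vapply(cfg$outcomes, `[[`, character(1), "trait")
  }
  if (is.character(cfg$panel))
    cfg$panel <- read_ld_panel(cfg$panel[1], cfg$panel[2])
  if (is.character(cfg$regions)) cfg$regions <- read_regions(cfg$regions)
  cfg
}

#' Fingerprint of an analysis configuration
#'
#' MD5 digest over every threshold, prior, scale parameter, the seed and
#' the input identities (paths when file-based; trait names and row counts
#' when in-memory), so the fingerprint changes whenever any of those change.
#'
#' @param config an [analysis_config()].
#' @return hex digest string.
#' @export
config_fingerprint <- function(config) {
  describe <- function(x) {
    if (is.character(x)) paste(x, collapse = "|")
    else if (inherits(x, "sumstats")) sprintf("mem:%s:%d", x$trait, nrow(x$data))
    else if (inherits(x, "ld_panel")) sprintf("mem:panel:%d", length(x$variant_ids))
    else if (is.list(x)) paste(vapply(x, describe, character(1)), collapse = "|")
    else paste(format(x, digits = 17), collapse = "|")
  }
  keys <- c("disease", "biomarker", "outcomes", "panel", "regions",
            "pp_threshold", "r2_mask", "r2_clump", "p_exposure",
            "p_biomarker", "palindrome_eaf_band", "w_quantitative",
            "w_binary", "pooled_requires_both", "seed")
  txt <- c(vapply(keys, function(k) sprintf("%s=%s", k, describe(config[[k]])),
                  character(1)),
           sprintf("priors=%.17g,%.17g,%.17g", config$priors$p1,
                   config$priors$p2, config$priors$p12),
           sprintf("functional=%s",
                   paste(config$functional_variants %||% "", collapse = ",")))
  f <- tempfile(); on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

mr_row <- function(outcome, source, exposure, est) {
  data.frame(outcome = outcome, source = source, exposure = exposure,
             k = est$n_instruments, beta = est$beta, se = est$se,
             ci_low = est$ci_low, ci_high = est$ci_high,
             pvalue = est$pvalue, Q = est$Q, scale = est$scale,
             outcome_scale = est$outcome_scale,
             or = if (is.null(est$or)) NA_real_ else est$or,
             or_low = if (is.null(est$or_ci)) NA_real_ else est$or_ci[1],
             or_high = if (is.null(est$or_ci)) NA_real_ else est$or_ci[2],
             stringsAsFactors = FALSE)
}

coloc_row <- function(outcome, reg_name, run, res) {
  data.frame(outcome = outcome, region = reg_name, run = run,
             PP0 = unname(res$pp[1]), PP1 = unname(res$pp[2]),
             PP2 = unname(res$pp[3]), PP3 = unname(res$pp[4]),
             PP4 = unname(res$pp[5]),
             top_variant_disease = res$top_variant1,
             top_variant_outcome = res$top_variant2,
             n_variants = res$n_variants, n_masked = length(res$masked),
             undeterminable = res$undeterminable, stringsAsFactors = FALSE)
}

#' Run the full colocalisation-gated MR analysis
#'
#' Executes, deterministically given the config and inputs: harmonisation;
#' per-region colocalisation of disease against every outcome (with the
#' conditional re-run whenever the initial posterior neither passes the gate
#' nor already favours a hypothesis other than distinct causal variants);
#' the colocalisation gate; cis instrument selection per region, with the
#' coloc-based pleiotropy filter, plus the genome-wide comparator set; IVW
#' per gated outcome and source; per-halving rescaling; the cis vs
#' genome-wide contrast; and the sensitivity modes (biomarker exposure,
#' optional single functional variants). Every gate decision is logged as
#' one plain-text line.
#'
#' @param config an [analysis_config()].
#' @return a `run_report`: list with data.frames `coloc`, `gate`, `mr`,
#'   `contrast`, `sensitivity`, the `cross_exposure_r` correlation, the
#'   decision `log`, and the config `fingerprint`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- resolve_inputs(config)
  log <- character()
  logf <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  wfor <- function(type) if (type == "binary") cfg$w_binary else cfg$w_quantitative
  w_dis <- wfor(cfg$disease$trait_type)

  coloc_rows <- list(); gate_rows <- list(); cond_runs <- list()
  decisions <- list()
  for (onm in names(cfg$outcomes)) {
    out <- cfg$outcomes[[onm]]
    pair_full <- suppressMessages(
      harmonise_pair(cfg$disease, out, cfg$palindrome_eaf_band))
    w_out <- wfor(out$trait_type)
    for (rnm in names(cfg$regions)) {
      reg <- cfg$regions[[rnm]]
      pair <- extract_region(pair_full, reg)
      if (nrow(pair) == 0) {
        logf("coloc %s @ %s: no shared variants; gate closed", onm, rnm)
        decisions[[onm]][[rnm]] <- FALSE
        gate_rows[[length(gate_rows) + 1]] <- data.frame(
          outcome = onm, region = rnm, colocalises = FALSE,
          evidence_path = "none", PP4_initial = NA_real_,
          PP4_conditional = NA_real_)
        next
      }
      init <- coloc_posteriors(pair, cfg$priors, w_dis, w_out)
      coloc_rows[[length(coloc_rows) + 1]] <- coloc_row(onm, rnm, "initial", init)
      cond <- NULL
      if (!(unname(init$pp["PP4"]) > cfg$pp_threshold) &&
          identical(modal_hypothesis(init), "H3")) {
        cond <- conditional_coloc(pair, cfg$priors, w_dis, w_out,
                                  cfg$panel, cfg$r2_mask)
        coloc_rows[[length(coloc_rows) + 1]] <-
          coloc_row(onm, rnm, "conditional", cond)
        cond_runs[[onm]][[rnm]] <- cond
        logf("coloc %s @ %s: distinct-variant mode, conditional re-run masked %d variant(s) around %s",
             onm, rnm, length(cond$masked), cond$reference_variant)
      }
      dec <- coloc_decision(init, cond, cfg$pp_threshold)
      decisions[[onm]][[rnm]] <- dec$colocalises
      gate_rows[[length(gate_rows) + 1]] <- data.frame(
        outcome = onm, region = rnm, colocalises = dec$colocalises,
        evidence_path = dec$evidence_path,
        PP4_initial = unname(init$pp["PP4"]),
        PP4_conditional = if (is.null(cond)) NA_real_
                          else unname(cond$pp["PP4"]))
      logf("coloc %s @ %s: PP4=%.3f (%s) -> %s", onm, rnm,
           unname(init$pp["PP4"]), dec$evidence_path,
           if (dec$colocalises) "colocalises" else "no colocalisation")
    }
  }

  cis_sets <- lapply(names(cfg$regions), function(rnm)
    suppressMessages(select_cis(cfg$disease, cfg$biomarker, cfg$regions[[rnm]],
                                cfg$p_exposure, cfg$p_biomarker, cfg$panel,
                                cfg$r2_clump, cfg$palindrome_eaf_band)))
  names(cis_sets) <- names(cfg$regions)
  for (rnm in names(cis_sets))
    logf("instruments %s: %d cis variant(s) selected", rnm,
         nrow(cis_sets[[rnm]]))
  gw_set <- suppressMessages(
    select_genomewide(cfg$disease, cfg$biomarker, cfg$regions, cfg$p_exposure,
                      cfg$p_biomarker, cfg$panel, cfg$r2_clump,
                      cfg$palindrome_eaf_band))
  logf("instruments genome-wide comparator: %d variant(s) (cis regions excluded)",
       nrow(gw_set))

  mr_rows <- list(); contrast_rows <- list(); sens_rows <- list()
  xcor_main <- numeric(); xcor_sens <- numeric()
  for (onm in names(cfg$outcomes)) {
    out <- cfg$outcomes[[onm]]
    passed <- names(which(unlist(decisions[[onm]])))
    if (!length(passed)) {
      logf("gate %s: no colocalising region; not taken forward to MR", onm)
      next
    }
    pooled_ok <- if (cfg$pooled_requires_both)
      length(passed) == length(cfg$regions) else length(passed) >= 1
    logf("gate %s: colocalises at %s -> %s MR", onm,
         paste(passed, collapse = "+"),
         if (pooled_ok) "pooled and per-region" else "per-region")

    filtered <- lapply(passed, function(rnm) {
      f <- filter_pleiotropy(
        attach_outcome(cis_sets[[rnm]], cfg$disease, out,
                       cfg$palindrome_eaf_band),
        cond_runs[[onm]][[rnm]], cfg$panel, cfg$r2_mask)
      prov <- attr(f, "provenance")
      last <- prov[[length(prov)]]
      if (startsWith(last$filter, "pleiotropy") && length(last$removed))
        logf("pleiotropy filter %s @ %s: removed %s", onm, rnm,
             paste(last$removed, collapse = ","))
      f
    })
    names(filtered) <- passed

    add_estimates <- function(inst, source) {
      if (nrow(inst) == 0) {
        logf("mr %s [%s]: empty instrument set; skipped", onm, source)
        return(invisible(NULL))
      }
      est <- rescale_per_halving(ivw(inst))
      mr_rows[[length(mr_rows) + 1]] <<- mr_row(onm, source, "disease", est)
      sens <- ivw(inst, exposure = "biomarker")
      # orient per 1 SD *lower* biomarker so directions match per-halving
      sens_l <- new_mr_estimate(-sens$beta, sens$se, sens$pvalue,
                                sens$n_instruments, Q = sens$Q,
                                scale = "per_sd_biomarker_lower",
                                outcome_scale = sens$outcome_scale,
                                method = sens$method)
      sens_rows[[length(sens_rows) + 1]] <<- mr_row(onm, source, "biomarker",
                                                    sens_l)
      xcor_main <<- c(xcor_main, est$beta)
      xcor_sens <<- c(xcor_sens, sens_l$beta)
      invisible(est)
    }

    region_ests <- lapply(passed, function(rnm)
      add_estimates(filtered[[rnm]], rnm))
    names(region_ests) <- passed
    pooled_est <- NULL
    if (pooled_ok && length(passed) > 1)
      pooled_est <- add_estimates(do.call(pool_instruments, unname(filtered)),
                                  "pooled")
    nonnull <- Filter(Negate(is.null), region_ests)
    primary <- pooled_est %||% (if (length(nonnull)) nonnull[[1]] else NULL)

    gw_out <- attach_outcome(gw_set, cfg$disease, out, cfg$palindrome_eaf_band)
    if (nrow(gw_out) > 0 && !is.null(primary)) {
      gw_est <- rescale_per_halving(ivw(gw_out))
      mr_rows[[length(mr_rows) + 1]] <- mr_row(onm, "genomewide", "disease",
                                               gw_est)
      cmp <- compare_estimates(primary, gw_est)
      contrast_rows[[length(contrast_rows) + 1]] <- data.frame(
        outcome = onm, delta = cmp$delta, se_delta = cmp$se_delta,
        z = cmp$z, pvalue = cmp$pvalue, stringsAsFactors = FALSE)
      logf("contrast %s: cis %.4f vs genome-wide %.4f (p=%.3g)", onm,
           primary$beta, gw_est$beta, cmp$pvalue)
    }

    fvs <- cfg$functional_variants %||% character()
    fv_pair <- if (length(fvs)) suppressMessages(
      harmonise_pair(cfg$disease, out, cfg$palindrome_eaf_band)) else NULL
    for (fv in fvs) {
      row <- fv_pair[fv_pair$variant_id == fv, , drop = FALSE]
      if (nrow(row) != 1 || row$beta_a == 0) {
        logf("functional variant %s not available for outcome %s", fv, onm)
        next
      }
      west <- rescale_per_halving(
        wald_ratio(row$beta_a, row$se_a, row$beta_b, row$se_b,
                   outcome_scale = if (out$trait_type == "binary") "log_or"
                                   else "sd_units"))
      mr_rows[[length(mr_rows) + 1]] <- mr_row(onm, sprintf("functional:%s", fv),
                                               "disease", west)
    }
  }

  bindr <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  report <- list(
    coloc = bindr(coloc_rows, coloc_row("", "", "", new_coloc_result(
      stats::setNames(rep(NA_real_, 5), paste0("PP", 0:4)), numeric(),
      numeric(), NA, NA, character(), numeric()))[0, ]),
    gate = do.call(rbind, gate_rows),
    mr = bindr(mr_rows, mr_row("", "", "", new_mr_estimate(0, 1, 1, 0L))[0, ]),
    contrast = bindr(contrast_rows,
                     data.frame(outcome = character(), delta = numeric(),
                                se_delta = numeric(), z = numeric(),
                                pvalue = numeric())),
    sensitivity = bindr(sens_rows,
                        mr_row("", "", "", new_mr_estimate(0, 1, 1, 0L))[0, ]),
    cross_exposure_r = if (length(xcor_main) >= 3)
      cross_exposure_concordance(xcor_main, xcor_sens) else NA_real_,
    instruments = c(cis_sets, list(genomewide = gw_set)),
    log = log, fingerprint = config_fingerprint(config), config = config)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d coloc run(s), %d MR row(s), %d contrast(s); fingerprint %s\n",
              nrow(x$coloc), nrow(x$mr), nrow(x$contrast),
              substr(x$fingerprint, 1, 8)))
  invisible(x)
}

#' Tidy plotting table for a forest display
#'
#' One `estimate` row per MR result (odds-ratio scale for binary outcomes,
#' SD units for quantitative ones) plus one `reference` entry per outcome
#' carrying the genome-wide comparator estimate (the dotted
#' glycaemic-control-in-general line of a forest plot). An empty report
#' yields an empty table.
#'
#' @param report a `run_report`.
#' @return data.frame with columns `outcome`, `source`, `row_type`,
#'   `estimate`, `ci_low`, `ci_high`, `scale`.
#' @export
render_forest_data <- function(report) {
  mr <- report$mr[report$mr$exposure == "disease", , drop = FALSE]
  empty <- data.frame(outcome = character(), source = character(),
                      row_type = character(), estimate = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      scale = character(), stringsAsFactors = FALSE)
  if (nrow(mr) == 0) return(empty)
  binary <- mr$outcome_scale == "log_or" & !is.na(mr$or)
  est <- data.frame(outcome = mr$outcome, source = mr$source,
                    row_type = "estimate",
                    estimate = ifelse(binary, mr$or, mr$beta),
                    ci_low = ifelse(binary, mr$or_low, mr$ci_low),
                    ci_high = ifelse(binary, mr$or_high, mr$ci_high),
                    scale = ifelse(binary, "or", "sd_units"),
                    stringsAsFactors = FALSE)
  gw <- est[mr$source == "genomewide", , drop = FALSE]
  if (nrow(gw)) {
    gw$row_type <- "reference"
    gw$source <- "glycaemic_control_general"
    est <- rbind(est, gw)
  }
  rownames(est) <- NULL
  est
}

#' Write a run report to a directory
#'
#' Writes `coloc.tsv`, `gate.tsv`, `mr.tsv`, `contrast.tsv`,
#' `sensitivity.tsv`, `forest.tsv`, the instrument tables with provenance
#' sidecars, the plain-text decision `log.txt` and `fingerprint.txt`. All
#' numeric columns are written at full double precision so re-reading
#' reproduces the report exactly.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv_exact(report$coloc, p("coloc.tsv"))
  write_tsv_exact(report$gate, p("gate.tsv"))
  write_tsv_exact(report$mr, p("mr.tsv"))
  write_tsv_exact(report$contrast, p("contrast.tsv"))
  write_tsv_exact(report$sensitivity, p("sensitivity.tsv"))
  write_tsv_exact(render_forest_data(report), p("forest.tsv"))
  for (nm in names(report$instruments))
    write_instruments(report$instruments[[nm]],
                      p(sprintf("instruments_%s.tsv", nm)),
                      p(sprintf("instruments_%s_provenance.txt", nm)))
  writeLines(report$log, p("log.txt"))
  writeLines(report$fingerprint, p("fingerprint.txt"))
  invisible(dir)
}
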