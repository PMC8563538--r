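test_that("log ABF matches the closed form and the integration oracle", {
  # frozen values computed from the normal marginal-likelihood ratio
  expect_equal(log_abf(0, 0.1, 0.04), 0.5 * log(0.2))
  expect_equal(log_abf(0, 0.1, 0.04), -0.80472, tolerance = 1e-5)
  expect_equal(log_abf(0.5, 0.1, 0.04), 0.5 * (log(0.2) + 0.8 * 25))
  expect_equal(log_abf(0.5, 0.1, 0.04), 9.19528, tolerance = 1e-5)

  for (case in list(c(0, 0.1, 0.04), c(0.5, 0.1, 0.04), c(-0.2, 0.05, 0.0225),
                    c(0.03, 0.2, 0.04)))
    expect_equal(log_abf(case[1], case[2], case[3]),
                 integrate_log_abf(case[1], case[2], case[3]),
                 tolerance = 1e-8)

  # prior concentrated at the null: Bayes factor tends to 1
  expect_equal(log_abf(0.3, 0.1, 1e-12), 0, tolerance = 1e-5)
  expect_error(log_abf(Inf, 0.1, 0.04), "finite")
  expect_error(log_abf(0.1, 0, 0.04), "se > 0")
})

test_that("priors are validated", {
  expect_error(coloc_priors(p12 = 2e-4), "p12")
  expect_error(coloc_priors(0.5, 0.4, 0.2), "< 1")
  expect_s3_class(coloc_priors(), "coloc_priors")
})

test_that("posteriors match brute-force configuration enumeration exactly", {
  pr <- coloc_priors()
  for (s in 1:20) {
    set.seed(s)
    m <- sample(2:8, 1)
    pair <- make_pair(rnorm(m, 0, 0.3), rnorm(m, 0, 0.3),
                      se_a = runif(m, 0.02, 0.1), se_b = runif(m, 0.02, 0.1))
    res <- coloc_posteriors(pair, pr)
    oracle <- enum_coloc(unname(res$labf1), unname(res$labf2),
                         pr$p1, pr$p2, pr$p12)
    expect_lt(max(abs(unname(res$pp) - unname(oracle))), 1e-10)
    expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  }
})

test_that("no-signal regions give PP0 near 1 and posteriors always sum to 1", {
  pair <- make_pair(rep(0, 40), rep(0, 40), se_a = 0.02, se_b = 0.02)
  res <- coloc_posteriors(pair)
  expect_gt(res$pp["PP0"], 0.97)
  # extreme z-scores must not break the log-space accumulation (the fixture
  # clamps p at the double minimum, tripping the p/z consistency warning)
  pair2 <- suppressWarnings(make_pair(c(3, 0.01, -0.02), c(2.9, 0, 0.01),
                                      se_a = 0.05, se_b = 0.05))
  res2 <- coloc_posteriors(pair2)
  expect_equal(sum(res2$pp), 1, tolerance = 1e-9)
  expect_gt(res2$pp["PP4"], 0.9)
})

test_that("a single-variant region has PP3 exactly zero", {
  pair <- make_pair(0.4, 0.38, se_a = 0.05, se_b = 0.05)
  res <- coloc_posteriors(pair)
  expect_identical(unname(res$pp["PP3"]), 0)
  expect_gte(min(res$pp), 0)
})

test_that("PP4 is monotone in the shared-causal prior p12", {
  pair <- make_pair(c(0.3, 0.01, 0.02), c(0.28, 0.02, 0), se_a = 0.05,
                    se_b = 0.05)
  p12s <- c(1e-7, 1e-6, 1e-5, 5e-5, 1e-4)
  pp4 <- vapply(p12s, function(p12)
    unname(coloc_posteriors(pair, coloc_priors(1e-4, 1e-4, p12))$pp["PP4"]),
    numeric(1))
  expect_true(all(diff(pp4) >= 0))
})

test_that("ABFs are invariant to trait rescaling when w is rescaled with it", {
  pair <- make_pair(c(0.3, 0.05), c(0.2, 0.01), se_a = 0.05, se_b = 0.04)
  k <- 3.7
  pair_scaled <- make_pair(k * c(0.3, 0.05), c(0.2, 0.01),
                           se_a = k * 0.05, se_b = 0.04)
  r1 <- coloc_posteriors(pair, w1 = 0.04, w2 = 0.04)
  r2 <- coloc_posteriors(pair_scaled, w1 = k^2 * 0.04, w2 = 0.04)
  expect_equal(r2$labf1, r1$labf1)
  expect_equal(unname(r2$pp), unname(r1$pp))
  # without rescaling w the ABFs change (documented behaviour)
  r3 <- coloc_posteriors(pair_scaled, w1 = 0.04, w2 = 0.04)
  expect_false(isTRUE(all.equal(r3$labf1, r1$labf1)))
})

test_that("top variants use the largest-ABF / smallest-position tie rule", {
  pair <- make_pair(c(0.1, 0.4, 0.4), c(0.4, 0.1, 0.4), se_a = 0.1,
                    se_b = 0.1, pos = c(10, 20, 30))
  res <- coloc_posteriors(pair)
  expect_identical(res$top_variant1, "rs2")  # tie rs2/rs3 -> smaller position
  expect_identical(res$top_variant2, "rs1")
})

test_that("conditional masking follows the strict r2 > threshold rule", {
  # hand-built 3-variant panel: r(1,2)^2 = 0.21, r(1,3)^2 = 0.20
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- sqrt(0.21)
  R[1, 3] <- R[3, 1] <- sqrt(0.20)
  panel <- colocmr:::new_ld_panel(c("rs1", "rs2", "rs3"), "1",
                                  c(1000, 1100, 1200), rep("A", 3),
                                  rep("G", 3), rep(0.3, 3), R)
  # outcome signal strongest at rs1
  pair <- make_pair(c(0.05, 0.01, 0.02), c(0.5, 0.05, 0.06), se_a = 0.1,
                    se_b = 0.1, pos = c(1000, 1100, 1200))
  res <- conditional_coloc(pair, panel = panel, r2_mask = 0.2)
  expect_identical(res$reference_variant, "rs1")
  expect_identical(sort(res$masked), c("rs1", "rs2"))   # 0.21 > 0.2 strictly
  expect_identical(res$variant_ids, "rs3")              # 0.20 retained
  expect_true(res$conditional)
})

test_that("zero-LD panels mask only the lead variant; full masking is flagged", {
  panel <- make_ld_panel(4, decay = 0, seed = 1)
  pair <- make_pair(c(0.1, 0, 0, 0), c(0.6, 0.01, 0, 0), se_a = 0.1,
                    se_b = 0.1, pos = panel$positions)
  pair$variant_id <- panel$variant_ids
  res <- conditional_coloc(pair, panel = panel, r2_mask = 0.2)
  expect_identical(res$masked, panel$variant_ids[1])
  expect_equal(res$n_variants, 3)

  one <- make_pair(0.1, 0.5, se_a = 0.1, se_b = 0.1,
                   pos = panel$positions[1])
  one$variant_id <- panel$variant_ids[1]
  res1 <- conditional_coloc(one, panel = panel, r2_mask = 0.2)
  expect_true(res1$undeterminable)
  expect_true(anyNA(res1$pp))
})

test_that("the colocalisation decision applies the strict two-stage rule", {
  mk <- function(pp4, conditional = FALSE) {
    pp <- c(1 - pp4 - 0.05, 0.01, 0.01, 0.03, pp4)
    colocmr:::new_coloc_result(setNames(pp, paste0("PP", 0:4)),
                               numeric(), numeric(), "rs1", "rs1", "rs1", 1,
                               conditional = conditional)
  }
  expect_identical(coloc_decision(mk(0.95))$evidence_path, "initial")
  # boundary: PP4 exactly at the threshold does not pass
  d <- coloc_decision(mk(0.80), pp_threshold = 0.8)
  expect_false(d$colocalises)
  d2 <- coloc_decision(mk(0.10), mk(0.85, conditional = TRUE))
  expect_true(d2$colocalises)
  expect_identical(d2$evidence_path, "conditional")
  expect_identical(coloc_decision(mk(0.1), NULL)$evidence_path, "none")
})

test_that("simulated shared and distinct scenarios are classified correctly", {
  panel <- make_ld_panel(50, decay = 0.8, seed = 10)
  pair_h4 <- simulate_region_pair("H4", panel, 25, 25, 0.15, 0.15, seed = 1)
  expect_gt(coloc_posteriors(pair_h4)$pp["PP4"], 0.8)
  pair_h3 <- simulate_region_pair("H3", panel, 5, 45, 0.15, 0.15, seed = 2)
  expect_gt(coloc_posteriors(pair_h3)$pp["PP3"], 0.8)
})

test_that("conditional re-run raises PP4 when an outcome-only signal overlays a shared one", {
  panel <- make_ld_panel(50, decay = 0.9, seed = 12)
  improved <- with_seed_wrap(77, {
    vapply(seq_len(200), function(i) {
      d <- simulate_trait(panel, causal = 10, beta = 0.15, n = 5e4)
      o <- simulate_trait(panel, causal = c(10, 40), beta = c(0.15, 0.25),
                          n = 5e4)
      pair <- harmonise_pair(d, o)
      init <- coloc_posteriors(pair)
      cond <- conditional_coloc(pair, panel = panel, r2_mask = 0.2)
      !cond$undeterminable &&
        unname(cond$pp["PP4"]) > unname(init$pp["PP4"])
    }, logical(1))
  })
  expect_gte(mean(improved), 0.8)
})

test_that("coloc results serialise to TSV with optional per-variant ABFs", {
  pair <- make_pair(c(0.3, 0.01), c(0.29, 0.02), se_a = 0.05, se_b = 0.05)
  res <- coloc_posteriors(pair)
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".tsv")
  write_coloc_results(list(pairA = res), f, g)
  tab <- read.delim(f)
  expect_equal(tab$PP4, unname(res$pp["PP4"]))
  lab <- read.delim(g)
  expect_equal(nrow(lab), 2)
})
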