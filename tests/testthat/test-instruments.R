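# Deterministic two-trait fixture over a custom panel: disease (a) and
# biomarker (b) stats built directly from z-scores on the panel manifest.
panel_pair <- function(panel, z_a, z_b, se = 0.01) {
  mk <- function(z, trait) {
    p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
    sumstats(data.frame(variant_id = panel$variant_ids, chr = panel$chr,
                        pos = panel$positions, ea = panel$ea,
                        oa = panel$oa, eaf = panel$eaf, beta = z * se,
                        se = se, pvalue = p, n = 1e5), trait)
  }
  list(a = mk(z_a, "disease"), b = mk(z_b, "biomarker"))
}

ar1_panel <- function(n, decay, seed = 1) {
  # non-palindromic alleles so harmonisation never drops fixture variants
  p <- make_ld_panel(n, decay = decay, seed = seed)
  p$ea <- rep("A", n); p$oa <- rep("G", n)
  p
}

test_that("greedy clumping retains leads and discards linked followers", {
  panel <- ar1_panel(3, decay = 0)
  cand <- data.frame(variant_id = panel$variant_ids, pvalue = c(1e-8, 1e-6, 1e-4),
                     pos = panel$positions)
  expect_equal(clump(cand, panel)$variant_id, cand$variant_id)  # unlinked: all kept

  panel2 <- ar1_panel(2, decay = sqrt(0.5))
  cand2 <- data.frame(variant_id = panel2$variant_ids, pvalue = c(1e-6, 1e-8),
                      pos = panel2$positions)
  kept <- clump(cand2, panel2, r2_threshold = 0.1)
  expect_identical(kept$variant_id, panel2$variant_ids[2])      # smaller p wins

  expect_error(clump(data.frame(variant_id = "rsX", pvalue = 0.1, pos = 1),
                     panel), "rsX")
})

test_that("clumping follows the hand-traced greedy chain a-b-c", {
  # r2: a-b 0.3, b-c 0.3, a-c 0; p(a) < p(b) < p(c) -> {a, c}
  r <- sqrt(0.3)
  R <- diag(3); R[1, 2] <- R[2, 1] <- r; R[2, 3] <- R[3, 2] <- r
  panel <- colocmr:::new_ld_panel(c("a", "b", "c"), "1", c(1, 2, 3),
                                  rep("A", 3), rep("G", 3), rep(0.3, 3), R)
  cand <- data.frame(variant_id = c("a", "b", "c"),
                     pvalue = c(1e-9, 1e-7, 1e-5), pos = c(1, 2, 3))
  expect_identical(clump(cand, panel, 0.1)$variant_id, c("a", "c"))
})

test_that("no retained pair ever violates the clump threshold", {
  for (s in 1:10) {
    set.seed(s)
    panel <- make_ld_panel(30, decay = runif(1, 0.5, 0.95), seed = s)
    cand <- data.frame(variant_id = panel$variant_ids,
                       pvalue = runif(30), pos = panel$positions)
    kept <- clump(cand, panel, 0.1)
    if (nrow(kept) > 1) {
      sub <- subset_panel(panel, kept$variant_id)
      offdiag <- sub$R[upper.tri(sub$R)]^2
      expect_true(all(offdiag <= 0.1))
    }
  }
})

test_that("cis selection applies strict thresholds and the concordance rule", {
  panel <- ar1_panel(6, decay = 0)
  # z for p = 5e-6 exactly (boundary), clearly significant, and null
  z_bound <- qnorm(2.5e-6, lower.tail = FALSE)
  z_a <- c(6, 6, 6, z_bound, 1, 6)
  z_b <- c(3, 1, -3, 3, 3, 3)        # rs2 weak biomarker, rs3 discordant
  pp <- panel_pair(panel, z_a, z_b)
  pp$a$data$pvalue[4] <- 5e-6      # pin the boundary case exactly
  reg <- region("G", panel$chr[1], min(panel$positions), max(panel$positions))
  inst <- select_cis(pp$a, pp$b, reg, panel = panel)

  expect_setequal(inst$variant_id, panel$variant_ids[c(1, 6)])
  prov <- provenance(inst)
  nms <- vapply(prov, `[[`, character(1), "filter")
  expect_true(any(grepl("exposure_p", nms)))
  # p exactly 5e-6 fails the strict < rule
  expect_true(panel$variant_ids[4] %in%
                prov[[which(grepl("exposure_p", nms))]]$removed)
  # discordant direction removed by the concordance filter
  expect_true(panel$variant_ids[3] %in%
                prov[[which(grepl("concordance", nms))]]$removed)
  # weak biomarker association removed at p < 0.05
  expect_true(panel$variant_ids[2] %in%
                prov[[which(grepl("biomarker_p", nms))]]$removed)
  expect_identical(attr(inst, "exposure_scale"), "per_logodds_exposure")
})

test_that("provenance removal counts reconcile candidates with retained set", {
  panel <- ar1_panel(40, decay = 0.85, seed = 3)
  set.seed(42)
  pp <- panel_pair(panel, rnorm(40, 0, 4), rnorm(40, 2, 1))
  reg <- region("G", panel$chr[1], min(panel$positions), max(panel$positions))
  inst <- select_cis(pp$a, pp$b, reg, panel = panel)
  removed <- sum(vapply(provenance(inst), function(p) length(p$removed),
                        integer(1)))
  expect_equal(removed, 40 - nrow(inst))
})

test_that("p-threshold and concordance filters commute", {
  panel <- ar1_panel(20, decay = 0)
  set.seed(5)
  z_a <- rnorm(20, 0, 4); z_b <- rnorm(20, 0, 2)
  pp <- panel_pair(panel, z_a, z_b)
  h <- harmonise_pair(pp$a, pp$b)
  f_p <- function(d) d[d$pvalue_a < 5e-6 & d$pvalue_b < 0.05, ]
  f_c <- function(d) d[sign(d$beta_a) == sign(d$beta_b) & d$beta_a != 0 &
                         d$beta_b != 0, ]
  expect_identical(f_c(f_p(h))$variant_id, f_p(f_c(h))$variant_id)
})

test_that("genome-wide selection excludes regions with flank and labels loci", {
  gw <- simulate_genomewide(4, n_variants = 15, causal_fraction = 1,
                            disease_effect = 0.15, seed = 17)
  blocks <- gw$panel$block
  reg2 <- region("locus_002", gw$panel$chr[16], gw$panel$positions[16],
                 gw$panel$positions[30])
  inst <- suppressMessages(
    select_genomewide(gw$disease, gw$biomarker, exclude = list(reg2),
                      panel = gw$panel))
  expect_gt(nrow(inst), 0)
  expect_false("locus_002" %in% inst$region)
  expect_true(all(inst$region %in% setdiff(unique(blocks), "locus_002")))

  # a variant 1 bp outside an excluded region stays eligible
  pos16 <- gw$panel$positions[16]
  reg_near <- region("near", gw$panel$chr[16], pos16 + 1,
                     gw$panel$positions[30])
  inst2 <- suppressMessages(
    select_genomewide(gw$disease, gw$biomarker, exclude = list(reg_near),
                      panel = gw$panel))
  excl <- provenance(inst2)[[1]]$removed
  expect_false(gw$panel$variant_ids[16] %in% excl)
})

test_that("the pleiotropy filter reuses the conditional masking set", {
  panel <- ar1_panel(30, decay = 0.9, seed = 6)
  # shared causal at 5; outcome-only (pleiotropic) signal at 20
  d <- simulate_trait(panel, causal = c(5, 20), beta = c(0.1, 0.1), n = 9e5,
                      type = "binary", case_fraction = 0.1, seed = 31,
                      trait = "disease")
  b <- simulate_trait(panel, causal = c(5, 20), beta = c(0.05, 0.05), n = 3e5,
                      seed = 32, trait = "biomarker")
  o <- simulate_trait(panel, causal = c(5, 20), beta = c(0.025, 0.08), n = 3e5,
                      seed = 33, trait = "outcome")
  reg <- region("G", panel$chr[1], min(panel$positions), max(panel$positions))
  inst <- attach_outcome(select_cis(d, b, reg, panel = panel), d, o)
  expect_gt(nrow(inst), 1)

  pair <- harmonise_pair(d, o)
  cond <- conditional_coloc(pair, panel = panel, r2_mask = 0.2)
  filt <- filter_pleiotropy(inst, cond, panel, r2_mask = 0.2)
  r2_ref <- panel_r2(panel, cond$reference_variant, filt$variant_id)
  expect_true(all(r2_ref <= 0.2))
  last <- provenance(filt)[[length(provenance(filt))]]
  expect_match(last$filter, "pleiotropy")

  # no conditional run -> identity
  expect_identical(filter_pleiotropy(inst, NULL, panel, 0.2), inst)
})

test_that("masking the pleiotropic signal moves the IVW estimate toward truth", {
  panel <- ar1_panel(40, decay = 0.9, seed = 8)
  reg <- region("G", panel$chr[1], min(panel$positions), max(panel$positions))
  theta <- 0.25
  closer <- with_seed_wrap(91, {
    vapply(seq_len(200), function(i) {
      d <- simulate_trait(panel, causal = c(8, 30), beta = c(0.1, 0.1),
                          n = 9e5, type = "binary", case_fraction = 0.1,
                          trait = "disease")
      b <- simulate_trait(panel, causal = c(8, 30), beta = c(0.05, 0.05),
                          n = 3e5, trait = "biomarker")
      o <- simulate_trait(panel, causal = c(8, 30),
                          beta = c(theta * 0.1, theta * 0.1 + 0.06), n = 3e5,
                          trait = "outcome")
      inst <- attach_outcome(select_cis(d, b, reg, panel = panel), d, o)
      if (nrow(inst) < 2) return(NA)
      cond <- conditional_coloc(harmonise_pair(d, o), panel = panel,
                                r2_mask = 0.2)
      filt <- filter_pleiotropy(inst, cond, panel, r2_mask = 0.2)
      if (nrow(filt) == 0 || nrow(filt) == nrow(inst)) return(NA)
      abs(ivw(filt)$beta - theta) < abs(ivw(inst)$beta - theta)
    }, logical(1))
  })
  expect_gte(mean(closer, na.rm = TRUE), 0.7)
})

test_that("instrument sets serialise with a provenance sidecar", {
  panel <- ar1_panel(10, decay = 0)
  pp <- panel_pair(panel, c(rep(6, 3), rep(0, 7)), rep(3, 10))
  reg <- region("G", panel$chr[1], min(panel$positions), max(panel$positions))
  inst <- select_cis(pp$a, pp$b, reg, panel = panel)
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".txt")
  write_instruments(inst, f, g)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(inst))
  expect_true("f_stat" %in% names(tab))
  expect_true(any(grepl("ld_clump", readLines(g))))
})
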