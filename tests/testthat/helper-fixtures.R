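# Fixture builders and independent oracles used across the test files.

# Build a harmonised pair directly from effect/SE vectors on a shared
# manifest (non-palindromic alleles so nothing is dropped).
make_pair <- function(beta_a, beta_b, se_a = 0.1, se_b = 0.1,
                      pos = NULL, type_a = "quantitative",
                      type_b = "quantitative", n = 1e5) {
  m <- length(beta_a)
  stopifnot(length(beta_b) == m)
  se_a <- rep_len(se_a, m); se_b <- rep_len(se_b, m)
  pos <- pos %||% (1000 + 100 * seq_len(m))
  base <- data.frame(variant_id = sprintf("rs%d", seq_len(m)), chr = "1",
                     pos = pos, ea = "A", oa = "G", eaf = 0.3, n = n)
  mk <- function(beta, se, trait, type) {
    d <- base
    d$beta <- beta; d$se <- se
    d$pvalue <- 2 * pnorm(-abs(beta / se))
    d$pvalue <- pmax(d$pvalue, .Machine$double.xmin)
    sumstats(d, trait, type)
  }
  harmonise_pair(mk(beta_a, se_a, "traitA", type_a),
                 mk(beta_b, se_b, "traitB", type_b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seed + evaluate (tests may freely use the global RNG stream)
with_seed_wrap <- function(seed, code) { set.seed(seed); force(code) }

# Brute-force five-hypothesis posterior by explicit enumeration of every
# causal-configuration pair (c1, c2) on a small region: c = 0 means no
# causal variant, c = i means variant i causal. Plain (non-log) arithmetic,
# independent of the log-sum-exp implementation path.
enum_coloc <- function(labf1, labf2, p1, p2, p12) {
  m <- length(labf1)
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  h <- c(H0 = 0, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (c1 in 0:m) {
    for (c2 in 0:m) {
      if (c1 == 0 && c2 == 0) h["H0"] <- h["H0"] + 1
      else if (c2 == 0)       h["H1"] <- h["H1"] + p1 * bf1[c1]
      else if (c1 == 0)       h["H2"] <- h["H2"] + p2 * bf2[c2]
      else if (c1 != c2)      h["H3"] <- h["H3"] + p1 * p2 * bf1[c1] * bf2[c2]
      else                    h["H4"] <- h["H4"] + p12 * bf1[c1] * bf2[c1]
    }
  }
  h / sum(h)
}

# Numerical-integration oracle for the single-variant Bayes factor:
# marginal likelihood of beta-hat under b ~ N(0, w) divided by the null
# likelihood, integrated with stats::integrate.
integrate_log_abf <- function(beta, se, w) {
  num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, sqrt(w)),
                   -Inf, Inf, rel.tol = 1e-12)$value
  log(num) - dnorm(beta, 0, se, log = TRUE)
}

# Random instrument sets (with outcome columns) for IVW property tests.
random_instruments <- function(k, seed) {
  set.seed(seed)
  data.frame(
    beta_exposure = runif(k, 0.02, 0.3) * sample(c(-1, 1), k, TRUE),
    se_exposure = runif(k, 0.005, 0.05),
    beta_outcome = rnorm(k, 0, 0.1),
    se_outcome = runif(k, 0.005, 0.08))
}

# Weighted-least-squares-through-origin oracle for IVW (lm route).
wls_ivw <- function(inst) {
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
            weights = 1 / inst$se_outcome^2)
  s <- summary(fit)
  k <- nrow(inst)
  se_fixed <- s$coefficients[1, 2] / s$sigma
  list(beta = unname(coef(fit)[1]), se_fixed = se_fixed,
       Q = s$sigma^2 * (k - 1),
       se_mre = se_fixed * sqrt(max(1, s$sigma^2)))
}

# Single region pair simulated under a named coloc scenario; returns the
# harmonised pair and the panel.
simulate_region_pair <- function(hyp, panel, causal1, causal2, beta1, beta2,
                                 n = 50000, seed = NULL) {
  scen <- scenario(hyp, causal1 = causal1, causal2 = causal2,
                   beta1 = beta1, beta2 = beta2, n1 = n, n2 = n, seed = seed)
  ss <- simulate_sumstats(panel, scen)
  harmonise_pair(ss$trait1, ss$trait2)
}
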