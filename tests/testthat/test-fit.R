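test_that("saturated Gaussian log-likelihood at the sample moments has the closed form", {
  d <- simulate_trios(trio_config(n_trios = 60, seed = 11))
  stats <- triopgs:::.trio_suffstats(d)
  ll <- triopgs:::.mvn_loglik_suff(stats, stats$mean, stats$cov)
  p <- stats$dim
  ld <- as.numeric(determinant(stats$cov, logarithm = TRUE)$modulus)
  expect_equal(ll, -0.5 * stats$n * (p * log(2 * pi) + ld + p),
               tolerance = 1e-10)
})

test_that("single-factor parameter recovery at large n", {
  n <- 20000
  cfg <- tiny_config(n = n, seed = 12)
  d <- simulate_trios(cfg)
  pat <- matrix(1L, 6, 1, dimnames = list(paste0("trait", 1:6), "G"))
  fit <- fit_trio_ml(d, trio_model_spec(pat), n_starts = 2)
  expect_true(fit$converged)
  est <- fit$estimates
  se <- fit$std_errors
  lam_idx <- grep("^lambda", names(est))
  expect_true(all(abs(est[lam_idx] - 0.6) < pmax(3 * se[lam_idx], 0.01)))
  expect_lt(abs(est["psi[G]"] - 1), max(3 * se["psi[G]"], 0.02))
  res_idx <- grep("^resid", names(est))
  expect_true(all(abs(est[res_idx] - 0.64) < pmax(3 * se[res_idx], 0.02)))
  # BIC invariant
  expect_equal(fit$bic, fit$n_params * log(fit$n_trios) - 2 * fit$loglik)
})

test_that("tidy/glance expose bracketing intervals and fit diagnostics", {
  d <- simulate_trios(tiny_config(n = 1500, seed = 13))
  pat <- matrix(1L, 6, 1, dimnames = list(paste0("trait", 1:6), "G"))
  fit <- fit_trio_ml(d, trio_model_spec(pat), n_starts = 1)
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_setequal(names(td),
                  c("term", "estimate", "std.error", "conf.low", "conf.high"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$BIC, fit$bic)
  expect_lt(gl$gradient_norm, 1)
})

test_that("fits are deterministic given the RNG state and invariant to family relabeling", {
  d <- simulate_trios(tiny_config(n = 1200, seed = 14))
  pat <- matrix(1L, 6, 1, dimnames = list(paste0("trait", 1:6), "G"))
  spec <- trio_model_spec(pat)
  set.seed(1); f1 <- fit_trio_ml(d, spec, n_starts = 3, se = FALSE)
  set.seed(1); f2 <- fit_trio_ml(d, spec, n_starts = 3, se = FALSE)
  expect_identical(f1$theta, f2$theta)

  d3 <- d
  d3$family_id <- sprintf("z%06d", as.integer(factor(d3$family_id,
    levels = rev(sort(unique(d3$family_id))))))
  f3 <- fit_trio_ml(d3, spec, n_starts = 1, se = FALSE)
  f1b <- fit_trio_ml(d, spec, n_starts = 1, se = FALSE)
  expect_equal(f3$loglik, f1b$loglik, tolerance = 1e-8)
  expect_equal(f3$theta, f1b$theta, tolerance = 1e-5)
})

test_that("a single-indicator specific factor is rejected as unidentified", {
  pat <- pgs_simple_structure()
  pat <- cbind(pat, EXTRA = 0L)
  pat["MDD", "EXTRA"] <- 1L
  d <- simulate_trios(trio_config(n_trios = 200, seed = 15))
  expect_error(fit_trio_ml(d, trio_model_spec(pat), n_starts = 1),
               "not locally identified")
  pat0 <- cbind(pgs_simple_structure(), EMPTY = 0L)
  expect_error(trio_model_spec(pat0), "without any free loading")
})

test_that("within-family structure is untouched by switching assortment and selection on", {
  n <- 25000
  base <- trio_config(n_trios = n, seed = 16)
  biased <- trio_config(partner_cross_cov = c(0, 0, 0.081, 0.257),
                        selection_means_mother = c(0, 0.035, 0.037, 0),
                        selection_means_father = c(0, 0, 0, 0.183),
                        n_trios = n, seed = 16)
  w_of <- function(cfg) {
    d <- simulate_trios(cfg)
    triopgs:::.role_matrix(d, "child") -
      0.5 * (triopgs:::.role_matrix(d, "mother") +
               triopgs:::.role_matrix(d, "father"))
  }
  W0 <- w_of(base); W1 <- w_of(biased)
  # independent replicates: elementwise difference within 3 sqrt(2) MC SE
  tol <- 3 * sqrt(2) * sqrt(2 / n)
  expect_lt(max(abs(cov(W0) - cov(W1))), tol)
  expect_lt(max(abs(colMeans(W1))), 3 * sqrt(2 * 0.5 / n) * sqrt(2))
})
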