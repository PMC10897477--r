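test_that("identity covariance: perfect fit with diagonal implied covariance", {
  f <- extract_efa(diag(11), k = 2, n_obs = 1000)
  Sigma <- tcrossprod(f$loadings) + diag(f$uniquenesses)
  expect_lt(max(abs(Sigma - diag(11))), 1e-4)
  expect_lt(f$criterion, 1e-8)
})

test_that("exact calibrated structure is recovered to high precision", {
  L <- pgs_loadings("full")
  S <- tcrossprod(L) + diag(pgs_unique_variances("full"))
  f <- extract_efa(S, 5, 25293)
  expect_lt(max(abs(tcrossprod(f$loadings) - tcrossprod(L))), 1e-6)
  expect_lt(max(abs(f$uniquenesses - pgs_unique_variances("full"))), 1e-6)
})

test_that("extraction agrees with factanal on sampled data", {
  set.seed(51)
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- 0.7; L[5:8, 2] <- 0.6
  X <- matrix(rnorm(2000 * 2), 2000, 2) %*% t(L) +
    matrix(rnorm(2000 * 8), 2000, 8) %*% diag(sqrt(1 - rowSums(L^2)))
  R <- cor(X)
  ours <- extract_efa(R, 2, 2000)
  fa <- stats::factanal(covmat = R, factors = 2, n.obs = 2000,
                        rotation = "none")
  expect_lt(max(abs(tcrossprod(ours$loadings) -
                      tcrossprod(matrix(fa$loadings, 8, 2)))), 2e-3)
  expect_lt(max(abs(ours$uniquenesses - fa$uniquenesses)), 2e-3)
})

test_that("log-likelihood is monotone in the number of factors", {
  d <- simulate_trios(trio_config(n_trios = 3000, seed = 52))
  S <- cov(triopgs:::.role_matrix(d, "child"))
  lls <- vapply(0:5, function(k) extract_efa(S, k, 3000)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("sequential search recovers a single equal-structure factor", {
  L1 <- pgs_loadings("bold")[, 1, drop = FALSE]
  hits <- 0L
  for (s in 1:5) {
    cfg <- trio_config(loadings = L1, unique_var = 1 - rowSums(L1^2),
                       n_trios = 4000, seed = 520 + s)
    led <- sequential_efa_search(simulate_trios(cfg), max_k = 3)
    best <- attr(led, "best_model")
    if (led$k_between[best] == 1 && led$k_within[best] == 1 &&
        led$equal_structure[best]) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("pure-noise panels favour the zero-factor baseline", {
  L0 <- matrix(0, 11, 1, dimnames = list(pgs_traits(), "G"))
  cfg <- trio_config(loadings = L0, unique_var = rep(1, 11),
                     n_trios = 3000, seed = 53)
  led <- sequential_efa_search(simulate_trios(cfg), max_k = 2)
  best <- attr(led, "best_model")
  expect_equal(led$k_between[best], 0L)
  expect_equal(led$k_within[best], 0L)
})

test_that("ledger BIC is recomputable and the flagged model attains the minimum", {
  d <- simulate_trios(trio_config(n_trios = 2000, seed = 54))
  led <- sequential_efa_search(d, max_k = 3)
  n_tot <- 2 * attr(led, "n_trios")
  expect_equal(led$bic, led$n_params * log(n_tot) - 2 * led$loglik)
  best <- attr(led, "best_model")
  expect_equal(led$bic[best], min(led$bic[led$converged]))
})

test_that("BIC selection frequency of the generative dimensionality increases with n", {
  pick_k <- function(n, seed) {
    cfg <- trio_config(loadings = pgs_loadings("full"),
                       unique_var = pgs_unique_variances("full"),
                       n_trios = n, seed = seed)
    led <- sequential_efa_search(simulate_trios(cfg), max_k = 6)
    b <- attr(led, "best_model")
    led$k_between[b] == 5 && led$k_within[b] == 5 && led$equal_structure[b]
  }
  freq <- vapply(c(2000, 10000, 25293), function(n) {
    mean(vapply(1:3, function(s) pick_k(n, 900 + s), logical(1)))
  }, numeric(1))
  expect_true(all(diff(freq) >= 0))
  expect_equal(freq[3], 1)
})
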