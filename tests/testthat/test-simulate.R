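test_that("couple sampler: independence, assortment recovery, reproducibility", {
  n <- 200000
  cfg0 <- trio_config(n_trios = n, seed = 101)
  cpl0 <- simulate_couples(cfg0)
  cors <- diag(cor(cpl0$mother, cpl0$father))
  expect_lt(max(abs(cors)), 0.01)

  cfg1 <- trio_config(partner_cross_cov = c(0, 0, 0, 0.257),
                      n_trios = n, seed = 102)
  cpl1 <- simulate_couples(cfg1)
  r <- cor(cpl1$mother[, 4], cpl1$father[, 4])
  expect_lt(abs(r - 0.257), 3 * (1 - 0.257^2) / sqrt(n))
  # other factors stay independent
  expect_lt(max(abs(diag(cor(cpl1$mother, cpl1$father))[1:3])), 0.01)

  cpl1b <- simulate_couples(cfg1)
  expect_identical(cpl1, cpl1b)
  cfg2 <- trio_config(partner_cross_cov = c(0, 0, 0, 0.257),
                      n_trios = n, seed = 103)
  expect_false(isTRUE(all.equal(simulate_couples(cfg2), cpl1)))
})

test_that("couple sampler validates the joint couple covariance", {
  expect_error(trio_config(partner_cross_cov = diag(1.5, 4), n_trios = 10),
               "partner_cross_cov")
  expect_error(trio_config(factor_cov = matrix(c(1, 0.5, 0, 1), 2, 2),
                           loadings = matrix(0.5, 11, 2), n_trios = 10),
               "symmetric")
  expect_error(trio_config(unique_var = c(rep(0.5, 10), -0.1), n_trios = 10),
               "non-negative")
})

test_that("transmission: variance bookkeeping, within-family covariance, no-segregation limit", {
  n <- 200000
  cfg <- trio_config(n_trios = n, seed = 201)
  d <- simulate_trios(cfg)
  truth <- attr(d, "latent_truth")
  child_f <- as.matrix(dplyr::filter(truth, role == "child")[, -(1:2)])
  # 0.25 + 0.25 + 0.5 variance bookkeeping forced by the fixed 0.5 paths
  expect_lt(max(abs(apply(child_f, 2, var) - 1)), 3 * sqrt(2 / n))

  # child minus midparent has covariance 0.5 * population covariance
  traits <- pgs_traits()
  D <- triopgs:::.role_matrix(d, "child") -
    0.5 * (triopgs:::.role_matrix(d, "mother") +
             triopgs:::.role_matrix(d, "father"))
  expect_lt(max(abs(cov(D) - 0.5 * pop_cov(cfg))), 0.012)

  # degenerate no-segregation override: child is exactly the midparent
  cpl <- simulate_couples(cfg, use_seed = TRUE)
  um <- matrix(0, n, 11); uf <- matrix(0, n, 11)
  ch <- transmit(cpl$mother, cpl$father, um, uf, cfg,
                 segregation_var_scale = 0)
  expect_equal(ch$factors, 0.5 * cpl$mother + 0.5 * cpl$father)

  expect_error(transmit(cpl$mother[, 1:2], cpl$father, um, uf, cfg),
               "columns")
})

test_that("selection shifts parental observed means by lambda alpha, within-family mean stays 0", {
  n <- 100000
  a_m <- c(0, 0.3, 0, 0)
  cfg <- trio_config(selection_means_mother = a_m, n_trios = n, seed = 301)
  d <- simulate_trios(cfg)
  mu_m <- colMeans(triopgs:::.role_matrix(d, "mother"))
  mu_f <- colMeans(triopgs:::.role_matrix(d, "father"))
  expect_lt(max(abs(mu_m - drop(cfg$loadings %*% a_m))), 0.015)
  expect_lt(max(abs(mu_f)), 0.015)
  W <- triopgs:::.role_matrix(d, "child") -
    0.5 * (triopgs:::.role_matrix(d, "mother") +
             triopgs:::.role_matrix(d, "father"))
  expect_lt(max(abs(colMeans(W))), 0.012)
})

test_that("emit_pgs maps latents through the measurement layer", {
  n <- 50
  k <- 4; p <- 11
  cfg <- trio_config(n_trios = n, seed = 7)
  mk <- function() list(factors = matrix(rnorm(n * k), n, k),
                        uniques = matrix(rnorm(n * p), n, p))
  lat <- list(mother = mk(), father = mk(), child = mk())

  # zero loadings: observed scores equal the unique components exactly
  cfg0 <- trio_config(loadings = matrix(0, p, k,
                                        dimnames = list(pgs_traits(), NULL)),
                      unique_var = rep(1, p), n_trios = n)
  d0 <- emit_pgs(lat, cfg0)
  expect_equal(unname(triopgs:::.role_matrix(d0, "mother")),
               lat$mother$uniques)

  # single factor, unit loading on one trait, zero uniqueness: identity map
  L1 <- matrix(0, 1, 1, dimnames = list("MDD", "G")); L1[1, 1] <- 1
  cfg1 <- trio_config(loadings = L1, unique_var = 0, n_trios = n)
  lat1 <- list(mother = list(factors = matrix(rnorm(n), n, 1),
                             uniques = matrix(0, n, 1)),
               father = list(factors = matrix(rnorm(n), n, 1),
                             uniques = matrix(0, n, 1)),
               child = list(factors = matrix(rnorm(n), n, 1),
                            uniques = matrix(0, n, 1)))
  d1 <- emit_pgs(lat1, cfg1)
  expect_equal(unname(triopgs:::.role_matrix(d1, "father")[, 1]),
               drop(lat1$father$factors))

  # full calibrated structure: empirical covariance matches the moment oracle
  n2 <- 200000
  cfg2 <- trio_config(loadings = pgs_loadings("full"),
                      unique_var = pgs_unique_variances("full"),
                      n_trios = n2, seed = 8)
  d2 <- simulate_trios(cfg2)
  S <- cov(triopgs:::.role_matrix(d2, "mother"))
  expect_lt(max(abs(S - pop_cov(cfg2))), 0.015)
})

test_that("threshold-participation mode shifts retained parental factor means", {
  n <- 20000
  cfg <- trio_config(n_trios = n, seed = 11,
                     participation_weights_father = c(0, 0, 0, 1),
                     participation_rate = 0.5)
  cpl <- simulate_couples(cfg)
  expect_equal(nrow(cpl$father), n)
  expect_gt(mean(cpl$father[, 4]), 0.2)       # truncation raises the mean
  expect_lt(max(abs(colMeans(cpl$mother))), 0.05)
})

test_that("different seeds give statistically indistinguishable score distributions", {
  d1 <- simulate_trios(trio_config(n_trios = 4000, seed = 31))
  d2 <- simulate_trios(trio_config(n_trios = 4000, seed = 32))
  ks <- suppressWarnings(stats::ks.test(d1$MDD[d1$role == "child"],
                                        d2$MDD[d2$role == "child"]))
  expect_gt(ks$p.value, 1e-4)
})
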