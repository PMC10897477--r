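# A minimal spec whose implied moments are the identity: zero loading
# (single free loading held at 0), unit residual variances, independent
# child residuals.
.identity_spec_theta <- function() {
  pat <- matrix(0L, 11, 1, dimnames = list(pgs_traits(), "G"))
  pat[1, 1] <- 1L
  spec <- trio_model_spec(pat, psi_within = 0.5, transmit_uniques = FALSE)
  theta <- triopgs:::.theta_init(spec)
  theta[] <- 0                     # lambda 0, log psi 0, log resid 0
  list(spec = spec, theta = theta)
}

test_that("single standard-normal trio has the closed-form log-density", {
  st <- .identity_spec_theta()
  mom <- implied_moments(st$spec, st$theta)
  expect_equal(unname(mom$cov), diag(33))
  d <- panel_from_matrices(
    matrix(0, 1, 11, dimnames = list(NULL, pgs_traits())),
    matrix(0, 1, 11, dimnames = list(NULL, pgs_traits())),
    matrix(0, 1, 11, dimnames = list(NULL, pgs_traits())))
  expect_equal(trio_loglik(st$spec, st$theta, d), -0.5 * 33 * log(2 * pi))
})

test_that("log-likelihood matches the dense explicit-inverse oracle", {
  spec <- trio_model_spec(pgs_simple_structure(), psi_within = 1,
                          estimate_partner_cov = TRUE)
  set.seed(5)
  theta <- triopgs:::.theta_init(spec) + 0.1 * rnorm(spec$n_par)
  d <- simulate_trios(trio_config(n_trios = 5, seed = 6))
  mom <- implied_moments(spec, theta)
  X <- triopgs:::.trio_matrix(d)
  expect_equal(trio_loglik(spec, theta, d),
               dense_mvn_loglik(X, mom$mean, mom$cov), tolerance = 1e-8)
})

test_that("log-likelihood is additive over trios and invariant to row order", {
  st <- .identity_spec_theta()
  d <- simulate_trios(trio_config(n_trios = 7, seed = 8))
  ll <- trio_loglik(st$spec, st$theta, d)
  d2 <- d
  d2$family_id <- paste0("copy_", d2$family_id)
  ll2 <- trio_loglik(st$spec, st$theta, dplyr::bind_rows(d, d2))
  expect_equal(ll2, 2 * ll, tolerance = 1e-10)

  shuf <- d[sample(nrow(d)), ]
  expect_equal(trio_loglik(st$spec, st$theta, shuf), ll)
})

test_that("singular implied covariance yields a finite penalty, not NaN", {
  pat <- matrix(1L, 2, 1, dimnames = list(c("a", "b"), "G"))
  spec <- trio_model_spec(pat, psi_within = 0, transmit_uniques = FALSE)
  theta <- c(1, 1, 40, -60, -60)  # huge psi, vanishing residuals
  d <- panel_from_matrices(matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("a", "b"))),
                           matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("a", "b"))),
                           matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("a", "b"))))
  ll <- suppressWarnings(trio_loglik(spec, theta, d))
  expect_true(is.finite(ll))
  expect_warning(trio_loglik(spec, theta, d), "singular")
})

test_that("analytic likelihood gradient matches central differences", {
  for (means in c(FALSE, TRUE)) {
    spec <- trio_model_spec(pgs_simple_structure(),
                            psi_within = if (means) 0.5 else 1,
                            estimate_partner_cov =
                              if (means) c(TRUE, FALSE, TRUE, FALSE) else TRUE,
                            estimate_latent_means = means)
    d <- simulate_trios(trio_config(partner_cross_cov = c(0, 0, 0.1, 0.2),
                                    n_trios = 400, seed = 9 + means))
    stats <- triopgs:::.trio_suffstats(d)
    set.seed(10)
    th <- triopgs:::.theta_init(spec) + 0.1 * rnorm(spec$n_par)
    ga <- triopgs:::.loglik_grad(spec, th, stats)
    f <- function(t_) {
      mom <- triopgs:::.implied_core(spec, t_)
      triopgs:::.mvn_loglik_suff(stats, mom$mean, mom$cov)
    }
    gn <- triopgs:::.num_jacobian(f, th)[1, ]
    expect_lt(max(abs(ga - gn) / (abs(gn) + 1)), 1e-6)
  }
})
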