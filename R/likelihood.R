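# Sufficient statistics of a trio panel for the Gaussian likelihood:
# sample mean and (MLE, 1/n) covariance of the stacked 3p-vector.
.trio_suffstats <- function(data, traits = NULL) {
  X <- .trio_matrix(data, traits)
  n <- nrow(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  S <- crossprod(Xc) / n
  list(n = n, mean = xbar, cov = S, dim = ncol(X))
}

# Gaussian log-likelihood from sufficient statistics; Cholesky-based, no
# explicit inverse. Returns `penalty` for a non-PD implied covariance so
# the optimiser can back off without crashing.
.mvn_loglik_suff <- function(stats, mu, Sigma, penalty = -1e10) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(penalty)
  p <- stats$dim
  logdet <- 2 * sum(log(diag(ch)))
  d <- stats$mean - mu
  # tr(Sigma^-1 S) + d' Sigma^-1 d via triangular solves
  B <- backsolve(ch, t(backsolve(ch, stats$cov, transpose = TRUE)),
                 transpose = TRUE)
  quad <- sum(backsolve(ch, d, transpose = TRUE)^2)
  -0.5 * stats$n * (p * log(2 * pi) + logdet + sum(diag(B)) + quad)
}

#' Trio model log-likelihood
#'
#' Sum over complete trios of the 3p-dimensional Gaussian log-density of the
#' stacked mother/father/child score vector at the model-implied moments.
#' Evaluated from the sufficient statistics (sample mean and covariance), so
#' the cost is independent of the number of trios once they are computed.
#'
#' @inheritParams implied_moments
#' @param data long-format trio tibble (traits must match the spec's).
#' @return Scalar log-likelihood. A numerically singular implied covariance
#'   yields a large negative value (with a warning), never `NaN`.
#' @export
trio_loglik <- function(spec, theta, data) {
  stopifnot(inherits(spec, "trio_model_spec"))
  stats <- .trio_suffstats(data, spec$traits)
  mom <- implied_moments(spec, theta)
  ll <- .mvn_loglik_suff(stats, mom$mean, mom$cov)
  if (ll <= -1e10) {
    warning("Implied covariance is singular at this parameter point; ",
            "returning penalty value.", call. = FALSE)
  }
  ll
}

# Analytic gradient of the trio log-likelihood w.r.t. the unconstrained
# parameter vector. Uses the compact form Sigma = Lt Omega Lt' + U (x) Theta
# with Lt = I_3 (x) Lambda, Omega the 3k x 3k latent covariance implied by
# the fixed 0.5 transmission paths, and U the unique-transmission pattern;
# then d ll / d Sigma = -(n/2) (W - W A W), W = Sigma^-1, A = S + d d'.
.loglik_grad <- function(spec, theta, stats) {
  pr <- .theta_to_params(spec, theta)
  k <- spec$k; p <- spec$p
  lam <- pr$lambda
  Psi <- diag(pr$psi_between, k)
  Psi_w <- diag(spec$psi_within, k)
  Gam <- if (is.null(pr$gamma)) matrix(0, k, k) else diag(pr$gamma, k)
  tu <- if (spec$transmit_uniques) 0.5 else 0
  mom <- .trio_moments_core(lam, Psi, Psi_w, Gam, pr$alpha_m, pr$alpha_f,
                            pr$resid_var, spec$transmit_uniques)
  ch <- tryCatch(chol(mom$cov), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, spec$n_par))
  W <- chol2inv(ch)
  n <- stats$n
  d <- stats$mean - mom$mean
  A <- stats$cov + d %o% d
  G <- -(n / 2) * (W - W %*% A %*% W)
  gmu <- n * drop(W %*% d)

  # latent covariance Omega (3k x 3k) and the stacked loading map
  Om <- rbind(
    cbind(Psi, Gam, 0.5 * Psi + 0.5 * Gam),
    cbind(t(Gam), Psi, 0.5 * Psi + 0.5 * t(Gam)),
    cbind(0.5 * Psi + 0.5 * t(Gam), 0.5 * Psi + 0.5 * Gam,
          0.5 * Psi + 0.25 * (Gam + t(Gam)) + Psi_w))
  Lt <- matrix(0, 3 * p, 3 * k)
  for (r in 0:2) Lt[r * p + seq_len(p), r * k + seq_len(k)] <- lam

  a <- c(pr$alpha_m, pr$alpha_f, 0.5 * (pr$alpha_m + pr$alpha_f))
  dLt <- 2 * G %*% Lt %*% Om + gmu %o% a
  dlam <- matrix(0, p, k)
  for (r in 0:2) dlam <- dlam + dLt[r * p + seq_len(p), r * k + seq_len(k)]

  K <- crossprod(Lt, G %*% Lt)            # d ll / d Omega
  bi <- function(r, s) K[(r - 1) * k + seq_len(k), (s - 1) * k + seq_len(k), drop = FALSE]
  K11 <- bi(1, 1); K22 <- bi(2, 2); K33 <- bi(3, 3)
  K12 <- bi(1, 2); K21 <- bi(2, 1)
  K13 <- bi(1, 3); K31 <- bi(3, 1)
  K23 <- bi(2, 3); K32 <- bi(3, 2)
  dpsi <- diag(K11) + diag(K22) + 0.5 * (diag(K13) + diag(K31)) +
    0.5 * (diag(K23) + diag(K32)) + 0.5 * diag(K33)
  dgam <- diag(K12) + diag(K21) + 0.5 * (diag(K13) + diag(K31)) +
    0.5 * (diag(K23) + diag(K32)) + 0.5 * diag(K33)

  gb <- function(r, s) G[(r - 1) * p + seq_len(p), (s - 1) * p + seq_len(p), drop = FALSE]
  deps <- diag(gb(1, 1)) + diag(gb(2, 2)) + diag(gb(3, 3)) +
    tu * (diag(gb(1, 3)) + diag(gb(3, 1)) + diag(gb(2, 3)) + diag(gb(3, 2)))

  La <- crossprod(Lt, gmu)                # d ll / d a
  dalpha_m <- La[seq_len(k)] + 0.5 * La[2 * k + seq_len(k)]
  dalpha_f <- La[k + seq_len(k)] + 0.5 * La[2 * k + seq_len(k)]

  out <- c(dlam[spec$free_load],
           dpsi * pr$psi_between,          # chain rule for log psi
           if (spec$estimate_partner_cov) dgam[spec$gamma_free],
           if (spec$estimate_latent_means) c(dalpha_m, dalpha_f),
           deps * pr$resid_var)            # chain rule for log epsilon
  out
}

# Numeric central-difference Jacobian of f : R^m -> R^q.
.num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Generic local identification check: the Jacobian of the implied moments
# (mean + lower-triangle covariance) w.r.t. theta must have full column
# rank. Evaluated at a deterministic perturbation of the starting point:
# special parameter points (e.g. zero partner covariance with the
# within-family variance exactly half the between variance) can sit on
# measure-zero rank-deficient sets even though the model is identified
# almost everywhere.
.check_identified <- function(spec, theta) {
  f <- function(th) {
    m <- implied_moments(spec, th)
    c(m$mean, m$cov[lower.tri(m$cov, diag = TRUE)])
  }
  probe <- theta + 0.1 * sin(1.7 * seq_along(theta))
  J <- .num_jacobian(f, probe)
  r <- qr(J)$rank
  if (r < spec$n_par) {
    stop("Model is not locally identified: implied-moment Jacobian has rank ",
         r, " for ", spec$n_par, " free parameters.", call. = FALSE)
  }
  invisible(TRUE)
}
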