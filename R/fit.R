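#' Fit a trio factor model by maximum likelihood
#'
#' Maximises the multivariate-Gaussian trio likelihood over the free
#' parameters of a [trio_model_spec()] with L-BFGS-B on an unconstrained
#' scale (variances as logs, so Heywood crashes cannot occur), using
#' multiple jittered starts and keeping the best solution. Standard errors
#' come from the observed information (numerical Hessian at the optimum);
#' confidence intervals are Wald, `estimate +/- 1.96 * SE`, delta-method
#' transformed for variance parameters.
#'
#' @param data long-format trio tibble of standardized scores.
#' @param spec a [trio_model_spec()].
#' @param init optional starting vector (unconstrained scale); defaults to a
#'   deterministic pattern-based start.
#' @param n_starts number of optimisation starts (first is `init`, the rest
#'   jittered; default 10 — the likelihood can have local optima).
#' @param se compute standard errors (numerical Hessian)? Disable for large
#'   replicate studies where only point estimates are needed.
#' @param control passed to [stats::optim()]; defaults
#'   `list(maxit = 2000, factr = 1e7)`.
#' @param jitter_sd standard deviation of the start jitter.
#' @return An object of class `trio_fit`: estimates (raw scale), the
#'   unconstrained solution and its covariance, log-likelihood, BIC
#'   (`n_par * log(n_trios) - 2 * loglik`), convergence diagnostics.
#' @export
#' @examples
#' cfg <- trio_config(n_trios = 800, seed = 3)
#' pat <- pgs_simple_structure()
#' fit <- fit_trio_ml(simulate_trios(cfg), trio_model_spec(pat),
#'                    n_starts = 1, se = FALSE)
#' glance(fit)
fit_trio_ml <- function(data, spec, init = NULL, n_starts = 10,
                        se = TRUE, control = list(), jitter_sd = 0.15) {
  stopifnot(inherits(spec, "trio_model_spec"))
  stats <- .trio_suffstats(data, spec$traits)
  init <- init %||% .theta_init(spec)
  if (length(init) != spec$n_par) {
    stop("`init` must have length ", spec$n_par, ".", call. = FALSE)
  }
  .check_identified(spec, init)
  control <- utils::modifyList(list(maxit = 2000, factr = 1e7), control)

  negll <- function(th) {
    mom <- .implied_core(spec, th)
    -.mvn_loglik_suff(stats, mom$mean, mom$cov)
  }
  negll_gr <- function(th) -.loglik_grad(spec, th, stats)

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1L) init else init + rnorm(spec$n_par, sd = jitter_sd)
    res <- tryCatch(
      optim(th0, negll, negll_gr, method = "L-BFGS-B", control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("All optimisation starts failed.", call. = FALSE)
  }
  theta <- setNames(best$par, .theta_names(spec))
  loglik <- -best$value
  converged <- best$convergence == 0 && loglik > -1e9

  gradient_norm <- sqrt(sum(negll_gr(theta)^2))

  vcov_theta <- NULL
  se_theta <- rep(NA_real_, spec$n_par)
  cond <- NA_real_
  if (se && converged) {
    H <- tryCatch(optimHess(theta, negll, negll_gr), error = function(e) NULL)
    if (!is.null(H)) {
      eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
      cond <- max(eh$values) / min(eh$values)
      tol <- max(eh$values) * 1e-10
      if (min(eh$values) > tol) {
        vcov_theta <- eh$vectors %*% (t(eh$vectors) / eh$values)
      } else {
        # near-singular observed information (e.g. a flat loading-ratio
        # direction of a two-indicator factor at a boundary truth):
        # pseudo-inverse; SEs along collapsed directions are unreliable
        keep <- eh$values > tol
        vcov_theta <- eh$vectors[, keep, drop = FALSE] %*%
          (t(eh$vectors[, keep, drop = FALSE]) / eh$values[keep])
      }
      dimnames(vcov_theta) <- list(names(theta), names(theta))
      se_theta <- sqrt(pmax(diag(vcov_theta), 0))
    }
  }

  params <- .theta_to_params(spec, theta)
  estimates <- .raw_estimates(spec, theta)
  se_raw <- .raw_se(spec, theta, se_theta)

  structure(
    list(spec = spec, theta = theta, vcov_theta = vcov_theta,
         estimates = estimates, std_errors = se_raw, params = params,
         loglik = loglik, n_params = spec$n_par, n_trios = stats$n,
         bic = spec$n_par * log(stats$n) - 2 * loglik,
         converged = converged, n_starts = n_starts,
         n_starts_converged = n_conv,
         gradient_norm = gradient_norm, hessian_condition = cond),
    class = "trio_fit")
}

# Raw-scale estimates: exponentiate the log-variance coordinates.
.raw_estimates <- function(spec, theta) {
  out <- theta
  idx <- .variance_idx(spec)
  out[idx] <- exp(theta[idx])
  out
}

.raw_se <- function(spec, theta, se_theta) {
  out <- se_theta
  idx <- .variance_idx(spec)
  out[idx] <- exp(theta[idx]) * se_theta[idx]  # delta method for exp()
  setNames(out, names(theta))
}

.variance_idx <- function(spec) {
  nm <- .theta_names(spec)
  grep("^(psi|resid)\\[", nm)
}

#' @export
print.trio_fit <- function(x, ...) {
  cat("<trio_fit> ", x$spec$p, " traits, ", x$spec$k, " factors, ",
      x$n_params, " free parameters\n", sep = "")
  cat("  n_trios: ", x$n_trios, "   logLik: ", format(x$loglik),
      "   BIC: ", format(x$bic), "\n", sep = "")
  cat("  converged: ", x$converged, " (", x$n_starts_converged, "/",
      x$n_starts, " starts)   |grad|: ",
      format(x$gradient_norm, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted trio model
#'
#' @param x a `trio_fit`.
#' @param conf_level Wald confidence level.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` on the raw parameter scale.
#' @export
tidy.trio_fit <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$estimates
  se <- x$std_errors
  idx <- .variance_idx(x$spec)
  lo <- est - z * se
  hi <- est + z * se
  # variance parameters: transform the Wald interval from the log scale
  lo[idx] <- est[idx] * exp(-z * se[idx] / est[idx])
  hi[idx] <- est[idx] * exp(z * se[idx] / est[idx])
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se),
                 conf.low = unname(lo), conf.high = unname(hi))
}

#' Model-level summary of a fitted trio model
#'
#' @param x a `trio_fit`.
#' @param ... unused.
#' @export
glance.trio_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, BIC = x$bic, n_params = x$n_params,
                 n_trios = x$n_trios, converged = x$converged,
                 gradient_norm = x$gradient_norm)
}

# Delta-method CI for a scalar function of theta (unconstrained scale).
.derived_quantity <- function(fit, f, conf_level = 0.95) {
  est <- f(fit$theta)
  se <- NA_real_
  if (!is.null(fit$vcov_theta)) {
    g <- .num_jacobian(function(th) f(th), fit$theta)[1, ]
    se <- sqrt(drop(t(g) %*% fit$vcov_theta %*% g))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(estimate = est, std.error = se,
    conf.low = est - z * se, conf.high = est + z * se)
}

#' Export a fitted trio model as JSON
#'
#' Writes the tidy parameter table, the model-level summary and the free
#' parameter specification to JSON (full numeric precision).
#'
#' @param fit a `trio_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "trio_fit"))
  jsonlite::write_json(
    list(parameters = tidy(fit), summary = glance(fit),
         psi_within = fit$spec$psi_within,
         pattern = apply(fit$spec$pattern, 1, identity, simplify = FALSE)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
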