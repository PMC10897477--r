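#' Specify a confirmatory trio factor model
#'
#' Defines the free/fixed parameter pattern of the trio structural model.
#' The transmission paths from each parental factor to the child factor are
#' always fixed at 0.5 (meiosis) and the within-family latent mean is always
#' fixed at 0; the within-family factor variance `psi_within` is fixed at a
#' chosen constant, which sets the latent metric (0.5 in the baseline
#' population metric, 1 in the assortment-CFA convention). Mother and
#' father measurement parameters (loadings, residual variances) are tied
#' equal, intercepts are fixed at 0 and scalings at 1 (pre-standardized
#' scores). Between-family factors are orthogonal with free variances.
#'
#' Free parameters, in packing order: loadings flagged by `pattern`
#' (nonzero entries; the sign is only an initialisation hint), log
#' between-family factor variances, per-factor mother-father latent
#' covariances (if `estimate_partner_cov`), mother then father latent means
#' (if `estimate_latent_means`), and log residual variances.
#'
#' @param pattern `p x k` matrix with entries `1` (free, init positive),
#'   `-1` (free, init negative) and `0` (fixed at zero). Row/column names
#'   name the traits and factors.
#' @param psi_within fixed within-family factor variance, scalar or
#'   length-k.
#' @param estimate_partner_cov free mother-father latent covariance
#'   (assortment model)? A scalar applies to all factors; a length-k
#'   logical vector frees the covariance factor-by-factor.
#' @param estimate_latent_means free mother/father latent factor means
#'   (selection model)?
#' @param transmit_uniques residual variances transmitted with the 0.5 rule
#'   (adds `0.5 * epsilon` to parent-child cross-blocks); default `TRUE`,
#'   matching the generator's default.
#' @return An object of class `trio_model_spec`.
#' @export
#' @examples
#' spec <- trio_model_spec(pgs_simple_structure(), psi_within = 1,
#'                         estimate_partner_cov = TRUE)
#' spec$n_par
trio_model_spec <- function(pattern,
                            psi_within = 0.5,
                            estimate_partner_cov = FALSE,
                            estimate_latent_means = FALSE,
                            transmit_uniques = TRUE) {
  pattern <- as.matrix(pattern)
  p <- nrow(pattern); k <- ncol(pattern)
  if (is.null(rownames(pattern))) rownames(pattern) <- paste0("trait", seq_len(p))
  if (is.null(colnames(pattern))) colnames(pattern) <- paste0("F", seq_len(k))
  if (any(colSums(pattern != 0) == 0)) {
    bad <- colnames(pattern)[colSums(pattern != 0) == 0]
    stop("Factor(s) without any free loading: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  psi_within <- .as_len_k(psi_within, k, "psi_within")
  gamma_free <- rep(isTRUE(estimate_partner_cov) ||
                      identical(estimate_partner_cov, TRUE), k)
  if (length(estimate_partner_cov) == k) {
    gamma_free <- as.logical(estimate_partner_cov)
  }
  free_load <- which(pattern != 0)
  n_par <- length(free_load) + k + sum(gamma_free) +
    (if (estimate_latent_means) 2L * k else 0L) + p
  structure(
    list(pattern = pattern, p = p, k = k,
         traits = rownames(pattern), factors = colnames(pattern),
         psi_within = psi_within,
         estimate_partner_cov = any(gamma_free),
         gamma_free = gamma_free,
         estimate_latent_means = isTRUE(estimate_latent_means),
         transmit_uniques = isTRUE(transmit_uniques),
         free_load = free_load, n_par = n_par),
    class = "trio_model_spec")
}

#' @export
print.trio_model_spec <- function(x, ...) {
  cat("<trio_model_spec> ", x$p, " traits, ", x$k, " factors, ",
      x$n_par, " free parameters\n", sep = "")
  cat("  psi_within fixed at:", x$psi_within, "\n")
  cat("  partner covariance:",
      if (x$estimate_partner_cov) "free (per factor)" else "fixed 0", "\n")
  cat("  latent means:",
      if (x$estimate_latent_means) "free (mother, father)" else "fixed 0", "\n")
  invisible(x)
}

# Names of the free parameters, matching the packing order.
.theta_names <- function(spec) {
  ij <- arrayInd(spec$free_load, dim(spec$pattern))
  nm <- paste0("lambda[", spec$traits[ij[, 1]], ",", spec$factors[ij[, 2]], "]")
  nm <- c(nm, paste0("psi[", spec$factors, "]"))
  if (spec$estimate_partner_cov)
    nm <- c(nm, paste0("gamma[", spec$factors[spec$gamma_free], "]"))
  if (spec$estimate_latent_means)
    nm <- c(nm, paste0("alpha_m[", spec$factors, "]"),
            paste0("alpha_f[", spec$factors, "]"))
  c(nm, paste0("resid[", spec$traits, "]"))
}

# Default starting point on the unconstrained scale.
.theta_init <- function(spec) {
  th <- c(0.3 * sign(spec$pattern[spec$free_load]),
          rep(0, spec$k),
          rep(0, sum(spec$gamma_free)),
          if (spec$estimate_latent_means) rep(0, 2 * spec$k),
          rep(log(0.5), spec$p))
  setNames(th, .theta_names(spec))
}

# Unpack the unconstrained parameter vector into raw-scale matrices.
# Variances are optimised on the log scale.
.theta_to_params <- function(spec, theta) {
  stopifnot(length(theta) == spec$n_par)
  k <- spec$k; p <- spec$p
  i <- 0L
  lam <- matrix(0, p, k, dimnames = dimnames(spec$pattern))
  nl <- length(spec$free_load)
  lam[spec$free_load] <- theta[i + seq_len(nl)]; i <- i + nl
  psi <- exp(theta[i + seq_len(k)]); i <- i + k
  gam <- NULL
  if (spec$estimate_partner_cov) {
    gam <- rep(0, k)
    ng <- sum(spec$gamma_free)
    gam[spec$gamma_free] <- theta[i + seq_len(ng)]
    i <- i + ng
  }
  am <- af <- rep(0, k)
  if (spec$estimate_latent_means) {
    am <- theta[i + seq_len(k)]; i <- i + k
    af <- theta[i + seq_len(k)]; i <- i + k
  }
  resid <- exp(theta[i + seq_len(p)])
  list(lambda = lam, psi_between = psi, gamma = gam,
       alpha_m = am, alpha_f = af, resid_var = resid)
}

# Fast implied-moments path for the optimiser: no names, no validation.
.implied_core <- function(spec, theta) {
  pr <- .theta_to_params(spec, theta)
  k <- spec$k
  Gam <- if (is.null(pr$gamma)) matrix(0, k, k) else diag(pr$gamma, k)
  .trio_moments_core(pr$lambda, diag(pr$psi_between, k),
                     diag(spec$psi_within, k), Gam,
                     pr$alpha_m, pr$alpha_f, pr$resid_var,
                     spec$transmit_uniques)
}

#' Implied moment structure at a parameter point
#'
#' Evaluates the model-implied 3p-dimensional mean and covariance of a
#' [trio_model_spec()] at a free-parameter vector (unconstrained scale, as
#' used by the optimiser: variances enter as logs).
#'
#' @param spec a [trio_model_spec()].
#' @param theta numeric vector of length `spec$n_par`.
#' @return See [trio_moments()].
#' @export
implied_moments <- function(spec, theta) {
  stopifnot(inherits(spec, "trio_model_spec"))
  pr <- .theta_to_params(spec, theta)
  trio_moments(lambda = pr$lambda,
               psi_between = pr$psi_between,
               psi_within = spec$psi_within,
               gamma = pr$gamma,
               alpha_m = pr$alpha_m, alpha_f = pr$alpha_f,
               resid_var = pr$resid_var,
               transmit_uniques = spec$transmit_uniques)
}
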