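#' Model-implied trio moments
#'
#' Computes the mean vector and covariance matrix of the stacked
#' mother/father/child observed-score vector implied by the trio model with
#' meiosis-fixed transmission: the child latent factor vector is
#' `0.5 * F_mother + 0.5 * F_father + S` with segregation covariance
#' `psi_within` fixed by design (0.5 times the population variance under
#' random mating). Measurement parameters (loadings, intercepts, scalings,
#' residual variances) are shared across the three roles.
#'
#' Block layout: coordinates `1..p` mother, `p+1..2p` father, `2p+1..3p`
#' child, traits in loading-matrix row order throughout.
#'
#' @param lambda `p x k` loading matrix.
#' @param psi_between between-family (population) factor covariance; vector
#'   = diagonal.
#' @param psi_within within-family (segregation) factor covariance, fixed by
#'   the identification convention (e.g. `0.5` in the baseline metric, `1`
#'   in the assortment CFA metric); vector = diagonal.
#' @param gamma mother-father latent cross-covariance (vector = diagonal);
#'   `NULL` means no assortment.
#' @param alpha_m,alpha_f length-k parental latent factor means.
#' @param resid_var length-p residual variances (epsilon).
#' @param nu length-p observed-variable intercepts (default 0).
#' @param delta length-p observed-variable scaling constants (default 1,
#'   pre-standardized data).
#' @param transmit_uniques logical; if `TRUE` residual genetic components are
#'   transmitted with the same 0.5 rule, adding `0.5 * resid_var` to the
#'   parent-child cross-blocks.
#' @return List with `mean` (length `3p`), `cov` (`3p x 3p`, exactly
#'   symmetric), and `block_index`, a tibble mapping role/trait to
#'   coordinate.
#' @seealso [implied_moments()] for the version driven by a
#'   [trio_model_spec()] parameter vector.
#' @export
#' @examples
#' m <- trio_moments(lambda = matrix(1, 2, 1), psi_between = 1,
#'                   psi_within = 0.5, resid_var = c(0, 0))
#' m$cov
trio_moments <- function(lambda, psi_between, psi_within,
                         gamma = NULL,
                         alpha_m = NULL, alpha_f = NULL,
                         resid_var,
                         nu = NULL, delta = NULL,
                         transmit_uniques = TRUE) {
  lambda <- as.matrix(lambda)
  p <- nrow(lambda); k <- ncol(lambda)
  Psi <- .as_square_matrix(psi_between, k, "psi_between")
  Psi_w <- .as_square_matrix(psi_within, k, "psi_within")
  Gam <- if (is.null(gamma)) matrix(0, k, k) else
    .as_square_matrix(gamma, k, "gamma")
  alpha_m <- .as_len_k(alpha_m %||% rep(0, k), k, "alpha_m")
  alpha_f <- .as_len_k(alpha_f %||% rep(0, k), k, "alpha_f")
  resid_var <- .as_len_k(resid_var, p, "resid_var")
  nu <- .as_len_k(nu %||% rep(0, p), p, "nu")
  delta <- .as_len_k(delta %||% rep(1, p), p, "delta")

  core <- .trio_moments_core(lambda, Psi, Psi_w, Gam, alpha_m, alpha_f,
                             resid_var, transmit_uniques)
  S <- core$cov
  mu <- core$mean
  D <- rep(delta, 3)
  S <- S * (D %o% D)
  mu <- rep(nu, 3) + D * mu
  S <- (S + t(S)) / 2

  traits <- rownames(lambda) %||% paste0("trait", seq_len(p))
  roles <- c("mother", "father", "child")
  idx <- tibble::tibble(role = rep(roles, each = p),
                        trait = rep(traits, 3),
                        coordinate = seq_len(3 * p))
  nm <- paste0(rep(traits, 3), c("_m", "_f", "_c")[rep(1:3, each = p)])
  dimnames(S) <- list(nm, nm); names(mu) <- nm
  list(mean = mu, cov = S, block_index = idx)
}

# Bare moment algebra without names/validation: the likelihood hot path.
.trio_moments_core <- function(lambda, Psi, Psi_w, Gam, alpha_m, alpha_f,
                               resid_var, transmit_uniques) {
  p <- nrow(lambda)
  tl <- t(lambda)
  LP <- lambda %*% Psi
  LG <- lambda %*% Gam
  Smm <- LP %*% tl
  diag(Smm) <- diag(Smm) + resid_var
  Smf <- LG %*% tl
  Smc <- 0.5 * (LP + LG) %*% tl
  Sfc <- 0.5 * LP %*% tl + 0.5 * t(LG %*% tl)
  if (transmit_uniques) {
    diag(Smc) <- diag(Smc) + 0.5 * resid_var
    diag(Sfc) <- diag(Sfc) + 0.5 * resid_var
  }
  Gs <- (Gam + t(Gam)) / 2
  Scc <- lambda %*% (0.5 * Psi + 0.5 * Gs + Psi_w) %*% tl
  diag(Scc) <- diag(Scc) + resid_var
  S <- rbind(cbind(Smm, Smf, Smc),
             cbind(t(Smf), Smm, Sfc),
             cbind(t(Smc), t(Sfc), Scc))
  mu <- c(lambda %*% alpha_m, lambda %*% alpha_f,
          0.5 * lambda %*% (alpha_m + alpha_f))
  list(mean = mu, cov = S)
}
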