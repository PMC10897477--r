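#' Maximum-likelihood exploratory factor extraction
#'
#' ML factor extraction by profile likelihood over the uniquenesses
#' (optimised with an analytic gradient on the canonical eigenvalue form),
#' returning the unrotated canonical solution. The fit is computed on the
#' correlation matrix and reported back on the scale of the input
#' covariance, so `loadings %*% t(loadings) + diag(uniquenesses)`
#' approximates `cov_matrix` itself. `k = 0` fits the independence
#' (diagonal) model.
#'
#' @param cov_matrix symmetric positive semi-definite covariance (or
#'   correlation) matrix.
#' @param k number of common factors, `0 <= k < p`.
#' @param n_obs number of observations behind `cov_matrix`, used for the
#'   log-likelihood and BIC.
#' @param lower lower bound on uniquenesses; a solution pinned at the bound
#'   is a Heywood case and is flagged with a warning.
#' @return Object of class `efa_fit`: `loadings` (`p x k`),
#'   `uniquenesses`, `loglik`, `n_params`
#'   (`p(k+1) - k(k-1)/2`), `bic`, `criterion` (ML discrepancy),
#'   `converged`, `heywood`.
#' @export
#' @examples
#' L <- pgs_loadings("bold")
#' R <- tcrossprod(L) + diag(pgs_unique_variances("bold"))
#' f <- extract_efa(R, k = 4, n_obs = 1000)
#' max(abs(tcrossprod(f$loadings) - tcrossprod(L)))
extract_efa <- function(cov_matrix, k, n_obs, lower = 1e-4) {
  S <- as.matrix(cov_matrix)
  p <- nrow(S)
  stopifnot(k >= 0, k < p, n_obs > 1)
  if (max(abs(S - t(S))) > 1e-8) stop("`cov_matrix` must be symmetric.",
                                      call. = FALSE)
  R <- stats::cov2cor(S)
  traits <- rownames(S) %||% paste0("trait", seq_len(p))

  if (k == 0) {
    lam <- matrix(0, p, 0, dimnames = list(traits, NULL))
    ll <- .cov_loglik(S, diag(diag(S), p), n_obs)
    q <- p
    return(structure(list(loadings = lam,
                          uniquenesses = setNames(diag(S), traits),
                          loglik = ll, n_params = q,
                          bic = q * log(n_obs) - 2 * ll,
                          criterion = .ml_discrepancy(R, diag(p)),
                          converged = TRUE, heywood = FALSE, k = 0L,
                          n_obs = n_obs),
                     class = "efa_fit"))
  }

  obj <- function(psi) {
    e <- eigen(R / sqrt(psi %o% psi), symmetric = TRUE, only.values = TRUE)$values
    ee <- e[(k + 1):p]
    sum(ee - log(ee) - 1)
  }
  grad <- function(psi) {
    E <- eigen(R / sqrt(psi %o% psi), symmetric = TRUE)
    lam <- E$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(E$values[seq_len(k)] - 1, 0)), k)
    lam <- lam * sqrt(psi)
    g <- lam %*% t(lam) + diag(psi) - R
    diag(g) / psi^2
  }
  start <- pmin(pmax((1 - 0.5 * k / p) / diag(solve(R)), lower), 1)
  opt <- optim(start, obj, grad, method = "L-BFGS-B",
               lower = lower, upper = 1,
               control = list(factr = 0.01, pgtol = 1e-14, maxit = 5000))
  # restart once from the solution: resets the L-BFGS Hessian approximation
  # and polishes convergence when the start sat near the bounds
  opt <- optim(opt$par, obj, grad, method = "L-BFGS-B",
               lower = lower, upper = 1,
               control = list(factr = 0.01, pgtol = 1e-14, maxit = 5000))
  psi <- opt$par
  E <- eigen(R / sqrt(psi %o% psi), symmetric = TRUE)
  lam <- E$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(E$values[seq_len(k)] - 1, 0)), k)
  lam <- lam * sqrt(psi)
  heywood <- any(psi <= lower * 1.01)
  if (heywood) {
    warning("Heywood case: uniqueness bounded at ", lower, ".", call. = FALSE)
  }
  # back to the input covariance scale
  sdv <- sqrt(diag(S))
  lam <- lam * sdv
  psi <- psi * diag(S)
  dimnames(lam) <- list(traits, paste0("F", seq_len(k)))
  Sigma <- lam %*% t(lam) + diag(psi)
  ll <- .cov_loglik(S, Sigma, n_obs)
  q <- p * (k + 1) - k * (k - 1) / 2
  structure(list(loadings = lam, uniquenesses = setNames(psi, traits),
                 loglik = ll, n_params = q, bic = q * log(n_obs) - 2 * ll,
                 criterion = opt$value,
                 converged = opt$convergence %in% c(0L, 52L) ||
                   opt$value < 1e-8,
                 heywood = heywood, k = as.integer(k), n_obs = n_obs),
            class = "efa_fit")
}

#' @export
print.efa_fit <- function(x, ...) {
  cat("<efa_fit> k = ", x$k, ", logLik = ", format(x$loglik),
      ", BIC = ", format(x$bic), "\n", sep = "")
  invisible(x)
}

# Gaussian log-likelihood of n_obs draws with sample covariance S under a
# model covariance Sigma (means saturated/centered out).
.cov_loglik <- function(S, Sigma, n_obs) {
  p <- nrow(S)
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  B <- backsolve(ch, t(backsolve(ch, S, transpose = TRUE)), transpose = TRUE)
  -0.5 * n_obs * (p * log(2 * pi) + logdet + sum(diag(B)))
}

.ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  ch <- chol(Sigma)
  B <- backsolve(ch, t(backsolve(ch, S, transpose = TRUE)), transpose = TRUE)
  2 * sum(log(diag(ch))) - determinant(S)$modulus[1] + sum(diag(B)) - p
}

# Joint ML fit of one factor structure to two covariance matrices
# (between-family and within-family layers) with the loading matrix
# constrained equal across layers; uniquenesses stay layer-specific.
# Lambda is left rotation-unconstrained (the likelihood is rotation
# invariant); the parameter count removes the k(k-1)/2 indeterminacy.
.efa_two_group_equal <- function(S_b, n_b, S_w, n_w, k, lower = 1e-4) {
  p <- nrow(S_b)
  pooled <- (n_b * S_b + n_w * S_w) / (n_b + n_w)
  init_fit <- extract_efa(pooled, k, n_b + n_w, lower = lower)
  par0 <- c(init_fit$loadings,
            log(pmax(init_fit$uniquenesses, lower)),
            log(pmax(init_fit$uniquenesses, lower)))
  negll <- function(par) {
    lam <- matrix(par[seq_len(p * k)], p, k)
    psi_b <- exp(par[p * k + seq_len(p)])
    psi_w <- exp(par[p * k + p + seq_len(p)])
    C <- lam %*% t(lam)
    ll <- tryCatch(.cov_loglik(S_b, C + diag(psi_b, p), n_b) +
                     .cov_loglik(S_w, C + diag(psi_w, p), n_w),
                   error = function(e) -1e10)
    -ll
  }
  opt <- optim(par0, negll, method = "L-BFGS-B",
               control = list(maxit = 3000, factr = 1e4))
  opt <- optim(opt$par, negll, method = "L-BFGS-B",
               control = list(maxit = 3000, factr = 1e4))
  lam <- matrix(opt$par[seq_len(p * k)], p, k,
                dimnames = list(rownames(S_b), paste0("F", seq_len(k))))
  q <- p * k - k * (k - 1) / 2 + 2 * p
  list(loadings = lam,
       uniquenesses_between = exp(opt$par[p * k + seq_len(p)]),
       uniquenesses_within = exp(opt$par[p * k + p + seq_len(p)]),
       loglik = -opt$value,
       n_params = q, converged = opt$convergence == 0)
}

#' Sequential between/within exploratory factor search
#'
#' Implements the stepwise dimensionality-and-equality search over the
#' between-family layer (the child score covariance) and the within-family
#' layer (covariance of the child-minus-midparent deviations, rescaled by
#' the fixed factor 2 to the population metric). At each dimensionality the
#' sequence adds one factor between families, then one within families,
#' then constrains the two new factors to a common structure; every step is
#' scored by BIC (`n_params * log(n) - 2 * loglik`, lower is better) and the
#' best-scoring converged model is flagged.
#'
#' @param data long-format trio tibble of standardized scores.
#' @param max_k largest number of factors to consider (bounded by the ML
#'   degrees-of-freedom limit `(p - k)^2 >= p + k`).
#' @return An object of class `efa_ledger`: a tibble with one row per
#'   fitted model (`model`, `k_between`, `k_within`, `equal_structure`,
#'   `loglik`, `n_params`, `bic`, `converged`) with attributes `best_model`
#'   (row index) and `best_fit` (the equal-structure fit of the winning
#'   dimensionality, when the winner is an equal model).
#' @export
sequential_efa_search <- function(data, max_k = 6) {
  traits <- .check_trios(data)
  p <- length(traits)
  kmax_df <- max(which(vapply(seq_len(p - 1),
                              function(k) (p - k)^2 >= p + k, TRUE)))
  max_k <- min(max_k, kmax_df)
  C <- .role_matrix(data, "child", traits)
  M <- .role_matrix(data, "mother", traits)
  F_ <- .role_matrix(data, "father", traits)
  n <- nrow(C)
  S_b <- cov(C) * (n - 1) / n
  D <- C - 0.5 * (M + F_)
  S_w <- 2 * cov(D) * (n - 1) / n
  n_tot <- 2L * n

  rows <- list()
  fits <- list()
  n_heywood <- 0L
  # overfitted search steps routinely pin a uniqueness at its bound; record
  # the fact in the ledger rather than emitting one warning per step
  quietly <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("Heywood", conditionMessage(w))) {
        n_heywood <<- n_heywood + 1L
        invokeRestart("muffleWarning")
      }
    })
  }
  add <- function(desc, kb, kw, equal, ll, q, conv) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      model = desc, k_between = kb, k_within = kw, equal_structure = equal,
      loglik = ll, n_params = q, bic = q * log(n_tot) - 2 * ll,
      converged = conv)
  }
  unequal <- function(kb, kw) {
    fb <- quietly(extract_efa(S_b, kb, n))
    fw <- quietly(extract_efa(S_w, kw, n))
    list(ll = fb$loglik + fw$loglik, q = fb$n_params + fw$n_params,
         conv = fb$converged && fw$converged)
  }

  base <- unequal(0, 0)
  add("0 factors (independence)", 0L, 0L, FALSE, base$ll, base$q, base$conv)
  for (k in seq_len(max_k)) {
    st1 <- unequal(k, k - 1L)
    add(sprintf("%d between / %d within", k, k - 1L), k, k - 1L, FALSE,
        st1$ll, st1$q, st1$conv)
    st2 <- unequal(k, k)
    add(sprintf("%d between / %d within", k, k), k, k, FALSE,
        st2$ll, st2$q, st2$conv)
    st3 <- quietly(.efa_two_group_equal(S_b, n, S_w, n, k))
    add(sprintf("%d factors, equal structure", k), k, k, TRUE,
        st3$loglik, st3$n_params, st3$converged)
    fits[[paste0("equal", k)]] <- st3
  }
  ledger <- dplyr::bind_rows(rows)
  ok <- which(ledger$converged)
  if (!length(ok)) {
    warning("No model converged; best_model undefined.", call. = FALSE)
    best <- NA_integer_
  } else {
    best <- ok[which.min(ledger$bic[ok])]
  }
  attr(ledger, "best_model") <- best
  if (!is.na(best) && ledger$equal_structure[best]) {
    attr(ledger, "best_fit") <- fits[[paste0("equal", ledger$k_between[best])]]
  }
  attr(ledger, "between_cov") <- S_b
  attr(ledger, "within_cov") <- S_w
  attr(ledger, "n_trios") <- n
  attr(ledger, "n_heywood_bounded") <- n_heywood
  class(ledger) <- c("efa_ledger", class(ledger))
  ledger
}

#' @export
print.efa_ledger <- function(x, ...) {
  best <- attr(x, "best_model")
  cat("<efa_ledger> sequential between/within factor search\n")
  NextMethod()
  if (!is.null(best) && !is.na(best) && best <= nrow(x)) {
    cat("best model (min BIC): row ", best, " -- ", x$model[best], "\n",
        sep = "")
  }
  invisible(x)
}
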