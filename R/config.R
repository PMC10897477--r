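#' Generative configuration for synthetic trio panels
#'
#' Bundles the full generating truth for a synthetic mother-father-child
#' polygenic-score panel: a bifactor measurement structure, the population
#' factor covariance, cross-partner latent covariance (assortative mating),
#' sex-specific latent mean shifts (participation selection), residual
#' genetic variances, and the sample size and seed.
#'
#' Latent genetic factors are sampled jointly for the two partners; child
#' latent values follow Mendelian transmission (midparent average plus a
#' segregation deviation carrying half the population variance). Observed
#' scores are `loadings %*% factors + unique`, so with the default calibrated
#' loadings and unit factor variances each score has population variance 1.
#'
#' @param loadings numeric n_traits x k loading matrix; column 1 is the
#'   general factor by convention. Defaults to [pgs_loadings()].
#' @param factor_cov k x k population factor covariance (default identity:
#'   orthogonal bifactor). A vector is taken as a diagonal.
#' @param partner_cross_cov k x k mother-father latent cross-covariance
#'   (default zero). A vector is taken as a diagonal; diagonal entries are
#'   the per-factor assortment parameters.
#' @param selection_means_mother,selection_means_father length-k latent mean
#'   shifts of the participating mothers/fathers, in standardized factor
#'   units (default zero: no participation selection).
#' @param unique_var length-n_traits residual genetic variances. Defaults to
#'   [pgs_unique_variances()] when `loadings` is left at its default,
#'   otherwise `1 - rowSums(loadings^2)` floored at zero.
#' @param n_trios number of complete trios to generate.
#' @param seed integer RNG seed; every draw from this configuration is
#'   reproducible given the seed.
#' @param trait_labels character vector of trait names; defaults to the row
#'   names of `loadings`.
#' @param transmit_uniques logical; if `TRUE` (default) the trait-specific
#'   residual genetic component is itself transmitted with the same
#'   0.5/0.5 + segregation rule as the factors, keeping
#'   `Var(child) == Var(parent)`. If `FALSE` children receive an independent
#'   residual draw.
#' @param participation_weights_mother,participation_weights_father optional
#'   length-k weights switching on the threshold-participation robustness
#'   mode: instead of shifting latent means, candidate couples are retained
#'   when a liability `w_m'F_m + w_f'F_f + e`, with standard normal `e`,
#'   exceeds the `1 - participation_rate` population quantile.
#' @param participation_rate retention rate for the threshold mode.
#' @return An object of class `trio_config`.
#' @seealso [simulate_trios()], [simulate_couples()]
#' @export
#' @examples
#' cfg <- trio_config(n_trios = 500, seed = 1)
#' cfg
trio_config <- function(loadings = pgs_loadings(),
                        factor_cov = NULL,
                        partner_cross_cov = NULL,
                        selection_means_mother = NULL,
                        selection_means_father = NULL,
                        unique_var = NULL,
                        n_trios = 1000L,
                        seed = NULL,
                        trait_labels = NULL,
                        transmit_uniques = TRUE,
                        participation_weights_mother = NULL,
                        participation_weights_father = NULL,
                        participation_rate = 0.5) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  p <- nrow(loadings)
  if (is.null(trait_labels)) {
    trait_labels <- rownames(loadings)
    if (is.null(trait_labels)) trait_labels <- paste0("trait", seq_len(p))
  }
  if (length(trait_labels) != p) {
    stop("`loadings` must have one row per entry of `trait_labels` (",
         p, " rows vs ", length(trait_labels), " labels).", call. = FALSE)
  }
  rownames(loadings) <- trait_labels
  if (is.null(colnames(loadings))) colnames(loadings) <- paste0("F", seq_len(k))

  factor_cov <- .as_cov_matrix(factor_cov %||% diag(k), k, "factor_cov")
  partner_cross_cov <- .as_square_matrix(partner_cross_cov %||% matrix(0, k, k),
                                         k, "partner_cross_cov")
  .check_psd(factor_cov, "factor_cov")
  joint <- rbind(cbind(factor_cov, partner_cross_cov),
                 cbind(t(partner_cross_cov), factor_cov))
  .check_psd(joint, "partner_cross_cov (joint couple covariance)")

  alpha_m <- .as_len_k(selection_means_mother %||% rep(0, k), k,
                       "selection_means_mother")
  alpha_f <- .as_len_k(selection_means_father %||% rep(0, k), k,
                       "selection_means_father")

  if (is.null(unique_var)) {
    unique_var <- if (identical(unname(loadings), unname(pgs_loadings()))) {
      pgs_unique_variances()
    } else {
      pmax(1 - rowSums(loadings^2), 0)
    }
  }
  unique_var <- .as_len_k(unique_var, p, "unique_var")
  if (any(unique_var < 0)) {
    stop("`unique_var` entries must be non-negative.", call. = FALSE)
  }
  names(unique_var) <- trait_labels

  stopifnot(is.numeric(n_trios), length(n_trios) == 1, n_trios >= 1)

  structure(
    list(
      trait_labels = trait_labels,
      loadings = loadings,
      factor_cov = factor_cov,
      partner_cross_cov = partner_cross_cov,
      selection_means_mother = alpha_m,
      selection_means_father = alpha_f,
      unique_var = unique_var,
      n_trios = as.integer(n_trios),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      transmit_uniques = isTRUE(transmit_uniques),
      participation_weights_mother = participation_weights_mother,
      participation_weights_father = participation_weights_father,
      participation_rate = participation_rate
    ),
    class = "trio_config"
  )
}

#' @export
print.trio_config <- function(x, ...) {
  cat("<trio_config>\n")
  cat("  traits:  ", length(x$trait_labels), " (",
      paste(head(x$trait_labels, 4), collapse = ", "),
      if (length(x$trait_labels) > 4) ", ..." else "", ")\n", sep = "")
  cat("  factors: ", ncol(x$loadings), " (",
      paste(colnames(x$loadings), collapse = ", "), ")\n", sep = "")
  cat("  n_trios: ", x$n_trios, "   seed: ",
      if (is.null(x$seed)) "none" else x$seed, "\n", sep = "")
  gam <- diag(x$partner_cross_cov)
  if (any(gam != 0)) cat("  assortment (diag):", signif(gam, 3), "\n")
  if (any(x$selection_means_mother != 0) || any(x$selection_means_father != 0)) {
    cat("  selection means  mother:", signif(x$selection_means_mother, 3),
        " father:", signif(x$selection_means_father, 3), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_cov_matrix <- function(x, k, name) {
  m <- .as_square_matrix(x, k, name)
  if (max(abs(m - t(m))) > 1e-10) {
    stop("`", name, "` must be symmetric.", call. = FALSE)
  }
  (m + t(m)) / 2
}

.as_square_matrix <- function(x, k, name) {
  if (is.vector(x) && length(x) %in% c(1L, k)) x <- diag(rep(x, length.out = k), k)
  x <- as.matrix(x)
  if (!all(dim(x) == c(k, k))) {
    stop("`", name, "` must be a ", k, " x ", k, " matrix.", call. = FALSE)
  }
  unname(x)
}

.as_len_k <- function(x, k, name) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, k)
  if (length(x) != k) {
    stop("`", name, "` must have length ", k, ".", call. = FALSE)
  }
  x
}

.check_psd <- function(m, name, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop("`", name, "` is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ").", call. = FALSE)
  }
  invisible(TRUE)
}

# Sample n draws from N(mean, cov) allowing singular (PSD) covariance.
.rmvnorm <- function(n, mean, cov) {
  k <- length(mean)
  e <- eigen(cov, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  A <- e$vectors %*% (t(e$vectors) * sqrt(vals))
  z <- matrix(rnorm(n * k), n, k)
  sweep(z %*% t(A), 2, mean, `+`)
}
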