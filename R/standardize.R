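#' Residualize and standardize a trio polygenic-score panel
#'
#' Mirrors the usual post-processing of polygenic scores before factor
#' analysis: each trait column is (optionally) residualized on covariates
#' such as genetic principal components and genotyping batch by ordinary
#' least squares, then scaled to mean 0 and standard deviation 1. With no
#' covariates this is pure z-scoring.
#'
#' The scaling constants are computed on a reference group (default: the
#' parent generation pooled across sexes) and applied to everyone, so that
#' parent/child and mother/father mean differences are preserved on a common
#' scale. Per-sex centering is deliberately not offered: it would erase
#' exactly the parental mean signal that the selection-means model estimates.
#'
#' @param data long-format trio tibble (may carry extra covariate columns).
#' @param covariates character vector of covariate column names in `data` to
#'   residualize on, or `NULL`.
#' @param reference reference group for the scaling constants: `"parents"`
#'   (default), `"all"`, or `"children"`.
#' @return The panel with trait columns residualized/standardized;
#'   attributes are preserved.
#' @export
#' @examples
#' cfg <- trio_config(n_trios = 200, seed = 1)
#' std <- standardize_panel(simulate_trios(cfg))
#' round(mean(std$MDD[std$role != "child"]), 10)
standardize_panel <- function(data, covariates = NULL,
                              reference = c("parents", "all", "children")) {
  reference <- match.arg(reference)
  traits <- .check_trios(data, .panel_traits(data, covariates))
  ref_rows <- switch(reference,
                     parents = data$role %in% c("mother", "father"),
                     children = data$role == "child",
                     all = rep(TRUE, nrow(data)))
  out <- data
  for (tr in traits) {
    y <- data[[tr]]
    if (!is.null(covariates)) {
      X <- as.matrix(data[covariates])
      fit <- stats::lm.fit(cbind(1, X), y)
      y <- fit$residuals
    }
    s <- sd(y[ref_rows])
    if (!is.finite(s) || s < 1e-12) {
      stop("Trait `", tr, "` has zero variance after residualization.",
           call. = FALSE)
    }
    out[[tr]] <- (y - mean(y[ref_rows])) / s
  }
  attributes(out)[c("latent_truth", "trio_config")] <-
    attributes(data)[c("latent_truth", "trio_config")]
  out
}

#' Within-family scores: child deviation from the midparent expectation
#'
#' Per trait, ordinary least squares of the child score on the mother and
#' father scores (with intercept). The residuals are the within-family
#' scores randomized by meiosis; under random mating the regression
#' coefficients converge to (0.5, 0.5) and the residual covariance to half
#' the population covariance.
#'
#' @param data long-format trio tibble.
#' @return Tibble of per-family residuals (one column per trait) with a
#'   `coefficients` attribute: a tibble of `(trait, intercept, b_mother,
#'   b_father)`.
#' @export
residualize_child_on_parents <- function(data) {
  traits <- .check_trios(data)
  M <- .role_matrix(data, "mother", traits)
  F_ <- .role_matrix(data, "father", traits)
  C <- .role_matrix(data, "child", traits)
  ids <- sort(unique(data$family_id))
  res <- matrix(NA_real_, nrow(M), length(traits),
                dimnames = list(NULL, traits))
  coefs <- vector("list", length(traits))
  for (j in seq_along(traits)) {
    X <- cbind(1, M[, j], F_[, j])
    q <- qr(X)
    if (q$rank < 3L) {
      stop("Parental scores for trait `", traits[j],
           "` are collinear; within-family regression is not identified.",
           call. = FALSE)
    }
    fit <- qr.coef(q, C[, j])
    res[, j] <- C[, j] - drop(X %*% fit)
    coefs[[j]] <- tibble::tibble(trait = traits[j], intercept = fit[1],
                                 b_mother = fit[2], b_father = fit[3])
  }
  out <- dplyr::bind_cols(tibble::tibble(family_id = ids),
                          tibble::as_tibble(res))
  attr(out, "coefficients") <- dplyr::bind_rows(coefs)
  out
}
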