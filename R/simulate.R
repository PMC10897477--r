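#' Draw couple latent factors under assortment and selection
#'
#' Samples mother and father latent genetic factors jointly from a
#' 2k-dimensional Gaussian whose marginal covariances are the population
#' factor covariance, whose cross-partner covariance encodes assortative
#' mating, and whose means carry the sex-specific participation-selection
#' shifts.
#'
#' @param config a [trio_config()].
#' @param use_seed set the RNG seed from `config$seed` before drawing
#'   (default `TRUE`; internal callers that manage the seed themselves pass
#'   `FALSE`).
#' @return List with `mother` and `father`, each an `n_trios x k` matrix of
#'   latent factor draws.
#' @export
#' @examples
#' cfg <- trio_config(n_trios = 100, seed = 7)
#' cpl <- simulate_couples(cfg)
#' dim(cpl$mother)
simulate_couples <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "trio_config"))
  if (use_seed && !is.null(config$seed)) set.seed(config$seed)
  k <- ncol(config$loadings)
  Psi <- config$factor_cov
  Gam <- config$partner_cross_cov
  joint <- rbind(cbind(Psi, Gam), cbind(t(Gam), Psi))
  .check_psd(joint, "partner_cross_cov (joint couple covariance)")

  wm <- config$participation_weights_mother
  wf <- config$participation_weights_father
  if (!is.null(wm) || !is.null(wf)) {
    return(.simulate_couples_threshold(config, joint, wm %||% rep(0, k),
                                       wf %||% rep(0, k)))
  }
  mu <- c(config$selection_means_mother, config$selection_means_father)
  draws <- .rmvnorm(config$n_trios, mu, joint)
  list(mother = draws[, seq_len(k), drop = FALSE],
       father = draws[, k + seq_len(k), drop = FALSE])
}

# Threshold-participation robustness mode: couples are drawn from the
# unshifted population and retained when a liability index on the parental
# factors exceeds the (1 - rate) population quantile. Latent means of the
# retained sample then emerge from truncation rather than being imposed.
.simulate_couples_threshold <- function(config, joint, wm, wf) {
  k <- ncol(config$loadings)
  n <- config$n_trios
  rate <- config$participation_rate
  w <- c(wm, wf)
  cut <- qnorm(1 - rate, sd = sqrt(sum((joint %*% w) * w) + 1))
  got <- 0L
  out <- matrix(NA_real_, n, 2 * k)
  while (got < n) {
    m <- ceiling((n - got) / rate * 1.2) + 50L
    cand <- .rmvnorm(m, rep(0, 2 * k), joint)
    keep <- which(drop(cand %*% w) + rnorm(m) > cut)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n - got))]
      out[got + seq_along(take), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  list(mother = out[, seq_len(k), drop = FALSE],
       father = out[, k + seq_len(k), drop = FALSE])
}

#' Mendelian transmission of latent factors and unique components
#'
#' Builds the child generation from parental draws: each child latent factor
#' is the midparent average plus an independent segregation deviation with
#' half the population factor variance, `0.5 * mother + 0.5 * father + s`,
#' `s ~ N(0, 0.5 * factor_cov)`. When `config$transmit_uniques` is `TRUE`
#' the trait-specific residual genetic components follow the same rule with
#' segregation variance `0.5 * unique_var`; otherwise children get an
#' independent residual draw.
#'
#' @param mother_factors,father_factors `n x k` parental factor matrices.
#' @param mother_uniques,father_uniques `n x p` parental unique-component
#'   matrices.
#' @inheritParams simulate_couples
#' @param segregation_var_scale multiplier on the segregation variances;
#'   `0` gives the degenerate no-segregation limit in which the child equals
#'   the midparent exactly.
#' @return List with `factors` (`n x k`) and `uniques` (`n x p`) for the
#'   children.
#' @export
transmit <- function(mother_factors, father_factors,
                     mother_uniques, father_uniques,
                     config, segregation_var_scale = 1) {
  stopifnot(inherits(config, "trio_config"))
  k <- ncol(config$loadings)
  p <- nrow(config$loadings)
  dims <- vapply(list(mother_factors, father_factors), ncol, 1L)
  if (any(dims != k)) {
    stop("Parental factor blocks must have ", k, " columns.", call. = FALSE)
  }
  if (ncol(mother_uniques) != p || ncol(father_uniques) != p ||
      nrow(mother_factors) != nrow(father_factors) ||
      nrow(mother_uniques) != nrow(mother_factors)) {
    stop("Dimension mismatch between parental blocks.", call. = FALSE)
  }
  n <- nrow(mother_factors)
  s <- .rmvnorm(n, rep(0, k), 0.5 * segregation_var_scale * config$factor_cov)
  factors <- 0.5 * mother_factors + 0.5 * father_factors + s
  if (config$transmit_uniques) {
    u <- matrix(rnorm(n * p), n, p) *
      rep(sqrt(0.5 * segregation_var_scale * config$unique_var), each = n)
    uniques <- 0.5 * mother_uniques + 0.5 * father_uniques + u
  } else {
    uniques <- matrix(rnorm(n * p), n, p) *
      rep(sqrt(config$unique_var), each = n)
  }
  list(factors = factors, uniques = uniques)
}

#' Map latent draws to an observed polygenic-score panel
#'
#' Applies the measurement layer: each person's observed score vector is
#' `loadings %*% factors + unique`. The generating latent values are kept in
#' a `latent_truth` attribute (synthetic data only; real panels have no such
#' block).
#'
#' @param latents list with elements `mother`, `father`, `child`, each a list
#'   holding `factors` (`n x k`) and `uniques` (`n x p`).
#' @inheritParams simulate_couples
#' @return A tibble in long trio format: `family_id`, `role`
#'   (`mother`/`father`/`child`) and one column per trait, with attributes
#'   `trio_config` and `latent_truth`.
#' @export
emit_pgs <- function(latents, config) {
  stopifnot(inherits(config, "trio_config"))
  L <- config$loadings
  n <- nrow(latents$mother$factors)
  ids <- sprintf("fam%06d", seq_len(n))
  roles <- c("mother", "father", "child")
  obs <- purrr::map(roles, function(r) {
    y <- latents[[r]]$factors %*% t(L) + latents[[r]]$uniques
    colnames(y) <- config$trait_labels
    dplyr::bind_cols(tibble::tibble(family_id = ids, role = r),
                     tibble::as_tibble(y))
  })
  out <- dplyr::arrange(dplyr::bind_rows(obs), .data$family_id,
                        factor(.data$role, levels = roles))
  truth <- purrr::map(roles, function(r) {
    f <- latents[[r]]$factors
    colnames(f) <- colnames(L)
    dplyr::bind_cols(tibble::tibble(family_id = ids, role = r),
                     tibble::as_tibble(f))
  })
  attr(out, "latent_truth") <- dplyr::bind_rows(truth)
  attr(out, "trio_config") <- config
  out
}

#' Simulate a complete synthetic trio polygenic-score panel
#'
#' End-to-end generator: couple latent draws (assortment + selection),
#' Mendelian transmission to the child, and the measurement layer. This is
#' the reference data source for every downstream stage; its defaults encode
#' the calibrated bifactor structure of the 11-trait psychiatric panel.
#'
#' @inheritParams simulate_couples
#' @return A long-format tibble of trios; see [emit_pgs()].
#' @export
#' @examples
#' cfg <- trio_config(n_trios = 200, seed = 42)
#' trios <- simulate_trios(cfg)
#' dplyr::count(trios, role)
simulate_trios <- function(config) {
  stopifnot(inherits(config, "trio_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- ncol(config$loadings)
  p <- nrow(config$loadings)
  n <- config$n_trios
  couples <- simulate_couples(config, use_seed = FALSE)
  um <- matrix(rnorm(n * p), n, p) * rep(sqrt(config$unique_var), each = n)
  uf <- matrix(rnorm(n * p), n, p) * rep(sqrt(config$unique_var), each = n)
  child <- transmit(couples$mother, couples$father, um, uf, config)
  emit_pgs(list(mother = list(factors = couples$mother, uniques = um),
                father = list(factors = couples$father, uniques = uf),
                child = child),
           config)
}
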