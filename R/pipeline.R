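#' Mother-father polygenic score correlations
#'
#' Pearson correlation between mother and father scores per trait, with
#' Fisher-z 95% confidence intervals — the descriptive check for assortative
#' mating on the observed-score scale.
#'
#' @param data long-format trio tibble.
#' @param conf_level confidence level.
#' @return Tibble with `trait`, `r`, `conf.low`, `conf.high`, `n`.
#' @export
#' @examples
#' cfg <- trio_config(n_trios = 500, seed = 9)
#' partner_pgs_correlations(simulate_trios(cfg))
partner_pgs_correlations <- function(data, conf_level = 0.95) {
  traits <- .check_trios(data)
  M <- .role_matrix(data, "mother", traits)
  F_ <- .role_matrix(data, "father", traits)
  n <- nrow(M)
  if (n < 4) stop("Need at least 4 trios for a confidence interval.",
                  call. = FALSE)
  purrr::map_dfr(seq_along(traits), function(j) {
    ct <- cor.test(M[, j], F_[, j], conf.level = conf_level)
    tibble::tibble(trait = traits[j], r = unname(ct$estimate),
                   conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
                   n = n)
  })
}

#' Confirmatory assortment model: partner latent correlations
#'
#' Fits the trio model with the rotated simple structure, fixing the
#' within-family latent variance to 1 and freeing the mother-father latent
#' covariance of every factor. With the within-family variance as the
#' anchor, the standardized partner covariance (the estimated covariance
#' divided by the between-family factor variance) is the partner
#' correlation for that factor.
#'
#' @param data long-format trio tibble of standardized scores.
#' @param pattern sign-pattern matrix for the confirmatory loadings
#'   (default [pgs_simple_structure()]).
#' @param factors which factors get a free partner covariance: `"joint"`
#'   (default, all factors simultaneously) or a character vector of factor
#'   names for a factor-by-factor analysis.
#' @param ... passed to [fit_trio_ml()] (`n_starts`, `se`, ...).
#' @return A `trio_fit` with additional class `cfa_assortment`; use
#'   [partner_latent_correlations()] to extract the per-factor correlations
#'   with delta-method confidence intervals.
#' @export
fit_cfa_assortment <- function(data, pattern = pgs_simple_structure(),
                               factors = "joint", ...) {
  free <- if (identical(factors, "joint")) TRUE else {
    fn <- colnames(pattern) %||% paste0("F", seq_len(ncol(pattern)))
    if (!all(factors %in% fn)) {
      stop("Unknown factor name(s): ",
           paste(setdiff(factors, fn), collapse = ", "), call. = FALSE)
    }
    fn %in% factors
  }
  spec <- trio_model_spec(pattern, psi_within = 1,
                          estimate_partner_cov = free,
                          estimate_latent_means = FALSE)
  fit <- fit_trio_ml(data, spec, ...)
  class(fit) <- c("cfa_assortment", class(fit))
  fit
}

#' @rdname fit_cfa_assortment
#' @param fit a fit from `fit_cfa_assortment()`.
#' @param conf_level confidence level for the Wald intervals.
#' @export
partner_latent_correlations <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "cfa_assortment"))
  spec <- fit$spec
  nm <- .theta_names(spec)
  purrr::map_dfr(which(spec$gamma_free), function(j) {
    f <- function(th) {
      th <- setNames(th, nm)
      unname(th[paste0("gamma[", spec$factors[j], "]")] /
               exp(th[paste0("psi[", spec$factors[j], "]")]))
    }
    q <- .derived_quantity(fit, f, conf_level)
    tibble::tibble(factor = spec$factors[j], estimate = q[["estimate"]],
                   std.error = q[["std.error"]], conf.low = q[["conf.low"]],
                   conf.high = q[["conf.high"]])
  })
}

#' Confirmatory selection model: sex-specific latent factor means
#'
#' Fits the trio model with free mother and father latent factor means,
#' identified by fixing the within-family latent mean to zero and the
#' within-family variance to 0.5 (the baseline population metric). A
#' participating parent population whose latent mean deviates from 0 — the
#' population mean implied by the within-family anchor — indicates
#' selective participation. Estimates are reported in latent
#' standard-deviation units (divided by the square root of the estimated
#' between-family factor variance).
#'
#' The input scores must not be re-centered per sex (and should be
#' standardized against a pooled or population reference): per-sex centering
#' removes exactly the parental mean signal this model estimates. The
#' function stops if every trait mean is exactly zero within both parent
#' blocks separately, the footprint of per-sex centering.
#'
#' @inheritParams fit_cfa_assortment
#' @param estimate_partner_cov also free the partner latent covariances
#'   (default `TRUE`).
#' @return A `trio_fit` with additional class `cfa_selection`; use
#'   [latent_selection_means()] for the per-factor, per-parent means.
#' @export
fit_cfa_selection_means <- function(data, pattern = pgs_simple_structure(),
                                    estimate_partner_cov = TRUE, ...) {
  traits <- .check_trios(data)
  pm <- colMeans(.role_matrix(data, "mother", traits))
  pf <- colMeans(.role_matrix(data, "father", traits))
  if (max(abs(pm)) < 1e-12 && max(abs(pf)) < 1e-12) {
    stop("Mother and father blocks are each exactly mean-centered; ",
         "per-sex centering destroys the selection-mean signal. ",
         "Standardize against a pooled reference instead.", call. = FALSE)
  }
  spec <- trio_model_spec(pattern, psi_within = 0.5,
                          estimate_partner_cov = estimate_partner_cov,
                          estimate_latent_means = TRUE)
  fit <- fit_trio_ml(data, spec, ...)
  class(fit) <- c("cfa_selection", class(fit))
  fit
}

#' @rdname fit_cfa_selection_means
#' @param fit a fit from `fit_cfa_selection_means()`.
#' @param conf_level confidence level.
#' @export
latent_selection_means <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "cfa_selection"))
  spec <- fit$spec
  nm <- .theta_names(spec)
  grid <- tidyr::expand_grid(parent = c("mother", "father"),
                             factor = spec$factors)
  purrr::pmap_dfr(grid, function(parent, factor) {
    a_nm <- paste0("alpha_", substr(parent, 1, 1), "[", factor, "]")
    f <- function(th) {
      th <- setNames(th, nm)
      unname(th[a_nm] / sqrt(exp(th[paste0("psi[", factor, "]")])))
    }
    q <- .derived_quantity(fit, f, conf_level)
    tibble::tibble(parent = parent, factor = factor,
                   estimate = q[["estimate"]], std.error = q[["std.error"]],
                   conf.low = q[["conf.low"]], conf.high = q[["conf.high"]])
  })
}

#' Assemble an analysis report
#'
#' Collects the outputs of the pipeline stages — descriptive partner score
#' correlations, the sequential factor-search ledger, the rotated loading
#' matrix, the confirmatory partner latent correlations and the
#' sex-specific latent means — into one serialisable object with
#' provenance (configuration hash, seed, package version). Missing stages
#' are allowed and recorded as gaps.
#'
#' @param partner_correlations tibble from [partner_pgs_correlations()].
#' @param ledger an `efa_ledger` from [sequential_efa_search()].
#' @param rotation a `rotation_solution`.
#' @param assortment a `cfa_assortment` fit or the tibble from
#'   [partner_latent_correlations()].
#' @param selection a `cfa_selection` fit or the tibble from
#'   [latent_selection_means()].
#' @param config the generating [trio_config()] (synthetic runs) or `NULL`.
#' @return An object of class `analysis_report`.
#' @export
build_report <- function(partner_correlations = NULL, ledger = NULL,
                         rotation = NULL, assortment = NULL,
                         selection = NULL, config = NULL) {
  if (inherits(assortment, "cfa_assortment")) {
    assortment <- partner_latent_correlations(assortment)
  }
  if (inherits(selection, "cfa_selection")) {
    selection <- latent_selection_means(selection)
  }
  loadings <- if (!is.null(rotation)) {
    L <- rotation$rotated_loadings
    dplyr::bind_cols(tibble::tibble(trait = rownames(L)),
                     tibble::as_tibble(L))
  }
  ledger_tbl <- if (!is.null(ledger)) {
    tibble::as_tibble(ledger)
  }
  gaps <- c("partner_correlations", "ledger", "rotated_loadings",
            "partner_latent_correlations", "latent_selection_means")[
    vapply(list(partner_correlations, ledger_tbl, loadings,
                assortment, selection), is.null, TRUE)]
  structure(
    list(partner_correlations = partner_correlations,
         ledger = ledger_tbl,
         best_model = if (!is.null(ledger)) attr(ledger, "best_model"),
         rotated_loadings = loadings,
         partner_latent_correlations = assortment,
         latent_selection_means = selection,
         gaps = gaps,
         provenance = list(
           config_hash = if (!is.null(config)) rlang::hash(.config_to_list(config)),
           seed = if (!is.null(config)) config$seed,
           package_version = as.character(packageVersion("triopgs")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (nm in c("partner_correlations", "ledger", "rotated_loadings",
               "partner_latent_correlations", "latent_selection_means")) {
    v <- x[[nm]]
    cat("  ", nm, ": ", if (is.null(v)) "missing" else
      paste0(nrow(v), " rows"), "\n", sep = "")
  }
  cat("  provenance: hash ",
      x$provenance$config_hash %||% "none", ", seed ",
      x$provenance$seed %||% "none", "\n", sep = "")
  invisible(x)
}

#' Serialise / restore an analysis report
#'
#' `write_report()` writes the report as JSON (full numeric precision) and,
#' optionally, a human-readable markdown summary next to it.
#' `read_report()` restores the report from the JSON; the round trip is the
#' identity up to floating-point representation.
#'
#' @param report an `analysis_report`.
#' @param path output JSON path.
#' @param markdown also write `<path>.md`.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   restored `analysis_report`.
#' @export
write_report <- function(report, path, markdown = FALSE) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  if (markdown) {
    md <- c("# Trio PGS comorbidity analysis report", "",
            paste0("Package version: ", report$provenance$package_version))
    for (nm in c("partner_correlations", "ledger", "rotated_loadings",
                 "partner_latent_correlations", "latent_selection_means")) {
      v <- report[[nm]]
      if (is.null(v)) next
      md <- c(md, "", paste0("## ", gsub("_", " ", nm)), "",
              knit_simple_table(v))
    }
    writeLines(md, paste0(path, ".md"))
  }
  invisible(path)
}

# Minimal pipe-table renderer (no table package dependency).
knit_simple_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  body <- apply(as.data.frame(lapply(df, fmt)), 1, paste, collapse = " | ")
  c(paste(names(df), collapse = " | "),
    paste(rep("---", ncol(df)), collapse = " | "),
    body)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("partner_correlations", "ledger", "rotated_loadings",
               "partner_latent_correlations", "latent_selection_means")) {
    if (!is.null(x[[nm]])) x[[nm]] <- tibble::as_tibble(x[[nm]])
  }
  x$gaps <- as.character(x$gaps %||% character())
  structure(x, class = "analysis_report")
}
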