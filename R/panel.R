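#' Trait columns of a trio panel
#'
#' @param data long-format trio tibble.
#' @return Character vector of trait column names (everything except
#'   `family_id`, `role` and any declared covariate columns).
#' @keywords internal
.panel_traits <- function(data, covariates = NULL) {
  cfg <- attr(data, "trio_config")
  if (!is.null(cfg)) return(intersect(cfg$trait_labels, names(data)))
  setdiff(names(data), c("family_id", "role", covariates))
}

.check_trios <- function(data, traits = NULL) {
  if (!all(c("family_id", "role") %in% names(data))) {
    stop("Trio data needs `family_id` and `role` columns.", call. = FALSE)
  }
  traits <- traits %||% .panel_traits(data)
  roles <- c("mother", "father", "child")
  tab <- table(data$family_id, factor(data$role, levels = roles))
  if (!all(tab == 1L)) {
    stop("Every family must have exactly one mother, father and child record.",
         call. = FALSE)
  }
  if (anyNA(data[traits])) {
    stop("Complete-trio analysis: trait columns must have no missing values.",
         call. = FALSE)
  }
  invisible(traits)
}

#' Reshape a trio panel to wide format
#'
#' One row per family with `_m`, `_f`, `_c` suffixed trait columns
#' (mother, father, child).
#'
#' @param data long-format trio tibble.
#' @return A tibble with `family_id` plus `3 * n_traits` columns.
#' @export
trios_wide <- function(data) {
  traits <- .check_trios(data)
  d <- dplyr::select(data, "family_id", "role", dplyr::all_of(traits))
  d$role <- c(mother = "m", father = "f", child = "c")[d$role]
  wide <- tidyr::pivot_wider(d, names_from = "role",
                             values_from = dplyr::all_of(traits),
                             names_glue = "{.value}_{role}")
  ord <- c("family_id",
           paste0(rep(traits, times = 3),
                  rep(c("_m", "_f", "_c"), each = length(traits))))
  dplyr::select(wide, dplyr::all_of(ord))
}

# n x 3p numeric matrix in block order mother(1..p), father, child --
# the coordinate layout of the implied trio moments.
.trio_matrix <- function(data, traits = NULL) {
  traits <- .check_trios(data, traits)
  wide <- trios_wide(data[c("family_id", "role", traits)])
  as.matrix(wide[, -1, drop = FALSE])
}

# Extract the n x p block for one role, rows aligned across roles.
.role_matrix <- function(data, role, traits = NULL) {
  traits <- traits %||% .panel_traits(data)
  d <- dplyr::arrange(dplyr::filter(data, .data$role == !!role), .data$family_id)
  as.matrix(d[, traits, drop = FALSE])
}
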