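#' Write / read trio panels as tab-separated text
#'
#' `write_trios()` writes the long format (`family_id`, `role`, one column
#' per trait) or the wide `_m/_f/_c` format, plus an optional YAML sidecar
#' carrying the full generative configuration (including the seed) when the
#' panel was simulated. `read_trios()` reads either layout back, restoring
#' the configuration from the sidecar when present.
#'
#' @param data long-format trio tibble.
#' @param path output TSV path.
#' @param format `"long"` (default) or `"wide"`.
#' @param sidecar write `<path>.yaml` with the generating config when the
#'   panel carries one (default `TRUE`).
#' @return `write_trios()` returns `path` invisibly; `read_trios()` returns
#'   a long-format trio tibble.
#' @export
write_trios <- function(data, path, format = c("long", "wide"),
                        sidecar = TRUE) {
  format <- match.arg(format)
  .check_trios(data)
  out <- if (format == "wide") trios_wide(data) else
    data[c("family_id", "role", .panel_traits(data))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(data, "trio_config")
  if (sidecar && !is.null(cfg)) {
    yaml::write_yaml(.config_to_list(cfg), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_trios
#' @export
read_trios <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  df <- tibble::as_tibble(df)
  if (!"role" %in% names(df)) {
    traits <- unique(sub("_[mfc]$", "", setdiff(names(df), "family_id")))
    long <- tidyr::pivot_longer(df, -"family_id",
                                names_to = c(".value", "role"),
                                names_pattern = "(.*)_([mfc])$")
    long$role <- c(m = "mother", f = "father", c = "child")[long$role]
    df <- dplyr::arrange(long, .data$family_id,
                         factor(.data$role,
                                levels = c("mother", "father", "child")))
    df <- df[c("family_id", "role", traits)]
  }
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    attr(df, "trio_config") <- .config_from_list(yaml::read_yaml(side))
  }
  df
}

.config_to_list <- function(cfg) {
  list(
    trait_labels = cfg$trait_labels,
    factor_names = colnames(cfg$loadings),
    loadings = apply(cfg$loadings, 1, identity, simplify = FALSE),
    factor_cov = apply(cfg$factor_cov, 1, identity, simplify = FALSE),
    partner_cross_cov = apply(cfg$partner_cross_cov, 1, identity,
                              simplify = FALSE),
    selection_means_mother = cfg$selection_means_mother,
    selection_means_father = cfg$selection_means_father,
    unique_var = unname(cfg$unique_var),
    n_trios = cfg$n_trios,
    seed = cfg$seed,
    transmit_uniques = cfg$transmit_uniques,
    participation_weights_mother = cfg$participation_weights_mother,
    participation_weights_father = cfg$participation_weights_father,
    participation_rate = cfg$participation_rate
  )
}

.config_from_list <- function(x) {
  L <- do.call(rbind, lapply(x$loadings, unlist))
  dimnames(L) <- list(x$trait_labels, x$factor_names)
  trio_config(
    loadings = L,
    factor_cov = do.call(rbind, lapply(x$factor_cov, unlist)),
    partner_cross_cov = do.call(rbind, lapply(x$partner_cross_cov, unlist)),
    selection_means_mother = x$selection_means_mother,
    selection_means_father = x$selection_means_father,
    unique_var = x$unique_var,
    n_trios = x$n_trios,
    seed = x$seed,
    trait_labels = x$trait_labels,
    transmit_uniques = x$transmit_uniques,
    participation_weights_mother = x$participation_weights_mother,
    participation_weights_father = x$participation_weights_father,
    participation_rate = x$participation_rate
  )
}

#' Read / write loading matrices as TSV
#'
#' Loading matrices travel as tab-separated text with trait-label row names
#' and factor-label headers.
#'
#' @param loadings numeric matrix with row and column names.
#' @param path TSV path.
#' @return `write_loadings()` returns `path` invisibly; `read_loadings()`
#'   the matrix.
#' @export
write_loadings <- function(loadings, path) {
  df <- data.frame(trait = rownames(loadings), loadings,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loadings
#' @export
read_loadings <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
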