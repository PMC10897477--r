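#' Plot the BIC path of a sequential factor search
#'
#' @param object an `efa_ledger`.
#' @param ... unused.
#' @return A ggplot: BIC per fitted model, best model highlighted.
#' @export
autoplot.efa_ledger <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$step <- seq_len(nrow(d))
  d$best <- d$step == (attr(object, "best_model") %||% 0L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$bic)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best,
                                     shape = .data$equal_structure),
                        size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "model in search order", y = "BIC",
                  shape = "equal structure",
                  title = "Sequential between/within factor search") +
    ggplot2::theme_minimal()
}

#' Heatmap of a rotated loading matrix
#'
#' @param object a `rotation_solution`.
#' @param ... unused.
#' @return A ggplot tile map of loadings, traits by factors.
#' @export
autoplot.rotation_solution <- function(object, ...) {
  L <- object$rotated_loadings
  d <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(trait = rownames(L)),
                     tibble::as_tibble(L)),
    -"trait", names_to = "factor", values_to = "loading")
  d$trait <- factor(d$trait, levels = rev(rownames(L)))
  d$factor <- factor(d$factor, levels = colnames(L))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor, y = .data$trait,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = object$kind) +
    ggplot2::theme_minimal()
}

#' Bar chart of sex-specific latent selection means
#'
#' Mirrors the usual presentation of participation bias: one bar per factor
#' and parent, with Wald intervals, against the population reference of 0.
#'
#' @param means tibble from [latent_selection_means()] (or a `cfa_selection`
#'   fit).
#' @return A ggplot.
#' @export
plot_selection_means <- function(means) {
  if (inherits(means, "cfa_selection")) means <- latent_selection_means(means)
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$factor, y = .data$estimate,
                               fill = .data$parent)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           position = ggplot2::position_dodge(0.8),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "purple") +
    ggplot2::labs(x = NULL, y = "latent mean (SD units)",
                  title = "Sex-specific latent selection means") +
    ggplot2::theme_minimal()
}

#' Point-range plot of partner latent correlations
#'
#' @param cors tibble from [partner_latent_correlations()] (or a
#'   `cfa_assortment` fit).
#' @return A ggplot.
#' @export
plot_partner_correlations <- function(cors) {
  if (inherits(cors, "cfa_assortment")) cors <- partner_latent_correlations(cors)
  ggplot2::ggplot(cors, ggplot2::aes(x = .data$factor, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "partner latent correlation",
                  title = "Assortative mating on latent factors") +
    ggplot2::theme_minimal()
}
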