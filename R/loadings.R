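#' Psychiatric polygenic score panel
#'
#' The eleven psychiatric traits whose polygenic scores make up the default
#' analysis panel: attention deficit hyperactivity disorder, anorexia, autism
#' spectrum disorder, bipolar disorder, major depressive disorder,
#' neuroticism, obsessive-compulsive disorder, post-traumatic stress
#' disorder, schizophrenia, anxiety, and alcohol use disorders.
#'
#' @return Character vector of 11 trait labels, in panel order.
#' @export
#' @examples
#' pgs_traits()
pgs_traits <- function() {
  c("ADHD", "ANOR", "ASD", "BIPO", "MDD", "NEUR",
    "OCD", "PTSD", "SCHZ", "ANXI", "AUD")
}

# Published bifactor loading matrix for the 11-trait PGS panel, used as the
# calibrated generating truth of the synthetic-trio module. The "full"
# structure carries all five rotated factors (general p-factor,
# neurodevelopmental, psychotic, constraint, and a residual factor that is
# almost entirely MDD measurement error) together with the residual
# variances. The "bold" structure is the simple structure retained for
# confirmatory modelling: the general factor on all traits, NDV on
# ADHD/ASD, PSYCH on BIPO/SCHZ, CONS on ANOR/OCD/AUD(-), residual factor
# dropped and small cross-loadings zeroed.
.pgs_loadings_full <- function() {
  m <- matrix(c(
    0.211,  0.425,  0.014, -0.051, -0.022,
    0.173,  0.094,  0.073,  0.127, -0.056,
    0.166,  0.625,  0.003,  0.026,  0.012,
    0.111,  0.019,  0.436, -0.003,  0.030,
    0.747, -0.003, -0.004, -0.007,  0.636,
    0.504, -0.070, -0.057,  0.057,  0.047,
    0.062, -0.014,  0.073,  0.217, -0.026,
    0.277, -0.009,  0.022, -0.035, -0.107,
    0.166,  0.002,  0.374,  0.028, -0.055,
    0.496,  0.022, -0.031, -0.027,  0.002,
    0.150, -0.036,  0.015, -0.108, -0.067),
    nrow = 11, ncol = 5, byrow = TRUE,
    dimnames = list(pgs_traits(), c("P", "NDV", "PSYCH", "CONS", "RES")))
  m
}

.pgs_unique_full <- function() {
  setNames(c(0.772, 0.937, 0.581, 0.796, 0.037, 0.732,
             0.943, 0.910, 0.829, 0.752, 0.960), pgs_traits())
}

.pgs_loadings_bold <- function() {
  L <- .pgs_loadings_full()[, 1:4]
  keep <- .pgs_simple_pattern() != 0
  L[!keep] <- 0
  L
}

.pgs_simple_pattern <- function() {
  p <- matrix(0L, 11, 4,
              dimnames = list(pgs_traits(), c("P", "NDV", "PSYCH", "CONS")))
  p[, "P"] <- 1L
  p[c("ADHD", "ASD"), "NDV"] <- 1L
  p[c("BIPO", "SCHZ"), "PSYCH"] <- 1L
  p[c("ANOR", "OCD"), "CONS"] <- 1L
  p["AUD", "CONS"] <- -1L
  p
}

#' Calibrated generating loadings for the PGS panel
#'
#' Returns the bifactor loading matrix used as default generating truth for
#' [trio_config()]. `"full"` is the complete five-factor rotated solution
#' (general factor, neurodevelopmental, psychotic, constraint, and a residual
#' factor dominated by MDD measurement error); `"bold"` is the retained
#' confirmatory simple structure (four factors, small cross-loadings set to
#' zero, residual factor dropped).
#'
#' @param structure `"bold"` (default) or `"full"`.
#' @return An 11 x k numeric matrix with trait row names and factor column
#'   names.
#' @seealso [pgs_unique_variances()], [pgs_simple_structure()]
#' @export
#' @examples
#' pgs_loadings("bold")[1:3, ]
pgs_loadings <- function(structure = c("bold", "full")) {
  structure <- match.arg(structure)
  if (structure == "full") .pgs_loadings_full() else .pgs_loadings_bold()
}

#' Residual (unique) genetic variances matching [pgs_loadings()]
#'
#' For the `"full"` structure these are the published residual variances; for
#' the `"bold"` structure they are recomputed as `1 - rowSums(loadings^2)` so
#' that every generated score keeps unit population variance after the small
#' cross-loadings and the residual factor are dropped.
#'
#' @inheritParams pgs_loadings
#' @return Named numeric vector of length 11.
#' @export
pgs_unique_variances <- function(structure = c("bold", "full")) {
  structure <- match.arg(structure)
  if (structure == "full") return(.pgs_unique_full())
  L <- .pgs_loadings_bold()
  setNames(1 - rowSums(L^2), rownames(L))
}

#' Confirmatory simple-structure pattern for the PGS panel
#'
#' The free/fixed loading pattern used in the confirmatory trio models: the
#' general factor loads on all 11 scores, the neurodevelopmental factor on
#' ADHD and ASD, the psychotic factor on BIPO and SCHZ, and the constraint
#' factor on ANOR and OCD with a negative loading on AUD. Entries are `1`
#' (free, expected positive), `-1` (free, expected negative; the sign is only
#' used to initialise the optimiser) and `0` (fixed at zero).
#'
#' @return An 11 x 4 integer matrix.
#' @export
#' @examples
#' pgs_simple_structure()
pgs_simple_structure <- function() {
  .pgs_simple_pattern()
}
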