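# Shared fixture builders: every fixture is generated in code.

# A small single-factor panel spec/config for fast fits.
tiny_loadings <- function(p = 6, value = 0.6) {
  matrix(value, p, 1, dimnames = list(paste0("trait", seq_len(p)), "G"))
}

tiny_config <- function(n = 2000, seed = 1, value = 0.6, p = 6, ...) {
  L <- tiny_loadings(p, value)
  trio_config(loadings = L, unique_var = 1 - value^2, n_trios = n,
              seed = seed, ...)
}

# Build a long trio tibble directly from role matrices (column names = traits).
panel_from_matrices <- function(mother, father, child) {
  traits <- colnames(mother)
  n <- nrow(mother)
  ids <- sprintf("fam%06d", seq_len(n))
  one <- function(m, role) {
    dplyr::bind_cols(tibble::tibble(family_id = ids, role = role),
                     tibble::as_tibble(m))
  }
  dplyr::bind_rows(one(mother, "mother"), one(father, "father"),
                   one(child, "child"))
}

# Population covariance implied by a generating config (per person).
pop_cov <- function(cfg) {
  cfg$loadings %*% cfg$factor_cov %*% t(cfg$loadings) + diag(cfg$unique_var)
}

# Dense Gaussian log-density oracle with explicit inverse and determinant.
dense_mvn_loglik <- function(X, mu, Sigma) {
  Sinv <- solve(Sigma)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  s <- 0
  for (i in seq_len(nrow(X))) {
    d <- X[i, ] - mu
    s <- s - 0.5 * (ncol(X) * log(2 * pi) + ld + drop(t(d) %*% Sinv %*% d))
  }
  s
}
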