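# Geomin complexity criterion and its gradient. For an p x k loading
# matrix, f(L) = sum_i (prod_j (l_ij^2 + eps))^(1/k): small when every row
# has (near-)zeros in most columns, i.e. simple structure. eps smooths the
# criterion; 0.01 is the usual convention for panels of this size.
.geomin_crit <- function(L, eps) {
  k <- ncol(L)
  if (k == 0L) return(list(f = 0, G = L))
  L2 <- L^2 + eps
  pr <- exp(rowMeans(log(L2)))
  G <- (2 / k) * pr * L / L2
  list(f = sum(pr), G = G)
}

# Gradient-projection rotation (Bernaards & Jennrich). A is the unrotated
# loading matrix. Oblique: L = A t(solve(T)), T with unit-length columns,
# factor correlations Phi = t(T) T. Orthogonal: L = A T, T orthonormal.
# `cols` restricts the criterion to a subset of columns (bifactor family:
# the general column is exempt). Returns the solution and the criterion
# trace (monotone non-increasing by step halving).
.gpa_rotate <- function(A, T0, eps, orthogonal, cols = NULL,
                        maxit = 1000, tol = 1e-9) {
  k <- ncol(A)
  cols <- cols %||% seq_len(k)
  crit <- function(L) {
    out <- .geomin_crit(L[, cols, drop = FALSE], eps)
    G <- matrix(0, nrow(L), k)
    G[, cols] <- out$G
    list(f = out$f, G = G)
  }
  Tm <- T0
  if (orthogonal) {
    L <- A %*% Tm
    cf <- crit(L)
    G <- crossprod(A, cf$G)
  } else {
    Ti <- solve(Tm)
    L <- A %*% t(Ti)
    cf <- crit(L)
    G <- -t(t(L) %*% cf$G %*% Ti)
  }
  f <- cf$f
  trace <- f
  al <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    if (orthogonal) {
      M <- crossprod(Tm, G)
      Gp <- G - Tm %*% (M + t(M)) / 2
    } else {
      Gp <- G - Tm %*% diag(diag(crossprod(Tm, G)), k)
    }
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    improved <- FALSE
    for (half in 1:20) {
      X <- Tm - al * Gp
      if (orthogonal) {
        sv <- svd(X)
        Tt <- sv$u %*% t(sv$v)
      } else {
        Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      }
      if (orthogonal) {
        Lt <- A %*% Tt
      } else {
        Tti <- solve(Tt)
        Lt <- A %*% t(Tti)
      }
      cft <- crit(Lt)
      if (cft$f < f - 0.5 * s^2 * al * 1e-4) { improved <- TRUE; break }
      al <- al / 2
    }
    if (!improved) { converged <- s < 1e-5; break }
    Tm <- Tt; L <- Lt; f <- cft$f
    trace <- c(trace, f)
    if (orthogonal) {
      G <- crossprod(A, cft$G)
    } else {
      G <- -t(t(L) %*% cft$G %*% Tti)
    }
  }
  Phi <- if (orthogonal) diag(k) else crossprod(Tm)
  list(loadings = L, Phi = Phi, Tmat = Tm, f = f, converged = converged,
       trace = trace)
}

.random_T <- function(k, orthogonal) {
  X <- matrix(rnorm(k * k), k, k)
  if (orthogonal) qr.Q(qr(X)) else X %*% diag(1 / sqrt(colSums(X^2)), k)
}

# Flip column signs so each factor's largest-|loading| entry is positive;
# for oblique solutions the factor correlations are flipped to match.
.sign_convention <- function(L, Phi) {
  flip <- vapply(seq_len(ncol(L)), function(j) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) -1 else 1
  }, numeric(1))
  L <- sweep(L, 2, flip, `*`)
  Phi <- diag(flip, ncol(L)) %*% Phi %*% diag(flip, ncol(L))
  list(L = L, Phi = Phi, flip = flip)
}

.finish_rotation <- function(A, best, n_starts, eps, kind) {
  sc <- .sign_convention(best$loadings, best$Phi)
  dimnames(sc$L) <- dimnames(A)
  structure(
    list(rotated_loadings = sc$L,
         factor_correlations = sc$Phi,
         criterion_value = best$f,
         rotation_matrix = best$Tmat,
         converged = best$converged,
         n_random_starts = n_starts,
         epsilon = eps,
         kind = kind,
         trace = best$trace,
         unrotated = A),
    class = "rotation_solution")
}

#' Oblique geomin rotation
#'
#' Minimises the geomin complexity criterion over oblique rotations of an
#' unrotated loading matrix by gradient projection, taking the best of
#' several random starts (the criterion is known to have local minima).
#'
#' @param loadings unrotated `p x k` loading matrix, `k >= 2`.
#' @param epsilon geomin smoothing constant (default 0.01).
#' @param n_starts number of rotation starts; the first is the identity,
#'   the rest random.
#' @param seed optional seed for the random starts.
#' @return An object of class `rotation_solution`: `rotated_loadings`,
#'   `factor_correlations`, `criterion_value` (minimum across starts),
#'   `rotation_matrix`, `converged`, `n_random_starts`, and the per-iteration
#'   criterion `trace` of the winning start. The rotated solution reproduces
#'   the unrotated common variance: `L Phi L' = A A'`.
#' @export
geomin_rotate <- function(loadings, epsilon = 0.01, n_starts = 30,
                          seed = NULL) {
  A <- as.matrix(loadings)
  stopifnot(ncol(A) >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(A)
  best <- NULL
  for (s in seq_len(n_starts)) {
    T0 <- if (s == 1L) diag(k) else .random_T(k, orthogonal = FALSE)
    res <- .gpa_rotate(A, T0, epsilon, orthogonal = FALSE)
    if (is.null(best) || res$f < best$f) best <- res
  }
  .finish_rotation(A, best, n_starts, epsilon, "geomin (oblique)")
}

#' Bi-factor geomin rotation
#'
#' Orthogonal rotation in the bi-factor family: the first column is treated
#' as the general factor and the geomin criterion is applied to the
#' remaining `k - 1` columns only, so specific factors are driven toward
#' simple structure while the general factor absorbs the shared variance.
#' Factors are mutually orthogonal, matching a bifactor model with a single
#' general factor and uncorrelated subfactors.
#'
#' @inheritParams geomin_rotate
#' @return An object of class `rotation_solution`; see [geomin_rotate()].
#'   `rotated_loadings` column 1 is the general factor.
#' @export
bifactor_geomin_rotate <- function(loadings, epsilon = 0.01, n_starts = 30,
                                   seed = NULL) {
  A <- as.matrix(loadings)
  stopifnot(ncol(A) >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(A)
  best <- NULL
  for (s in seq_len(n_starts)) {
    T0 <- if (s == 1L) diag(k) else .random_T(k, orthogonal = TRUE)
    res <- .gpa_rotate(A, T0, epsilon, orthogonal = TRUE, cols = 2:k)
    if (is.null(best) || res$f < best$f) best <- res
  }
  sol <- .finish_rotation(A, best, n_starts, epsilon, "bifactor geomin (orthogonal)")
  # make column 1 the general factor: it is the column with the largest
  # total squared loading once the criterion has emptied the others
  ss <- colSums(sol$rotated_loadings^2)
  g <- which.max(ss)
  if (g != 1L) {
    ord <- c(g, setdiff(seq_len(k), g))
    sol$rotated_loadings <- sol$rotated_loadings[, ord, drop = FALSE]
    sol$rotation_matrix <- sol$rotation_matrix[, ord, drop = FALSE]
  }
  sol
}

#' @export
print.rotation_solution <- function(x, ...) {
  cat("<rotation_solution> ", x$kind, ", criterion = ",
      format(x$criterion_value, digits = 6),
      ", converged = ", x$converged, "\n", sep = "")
  print(round(x$rotated_loadings, 3))
  invisible(x)
}

#' Align a loading matrix to a reference by column permutation and sign
#'
#' Recovery comparisons of rotated solutions are only defined up to column
#' permutation and sign. This matches columns to a reference matrix by
#' maximising total absolute Tucker congruence over permutations (exhaustive
#' for `k <= 6`), then flips signs to agree with the reference.
#'
#' @param L loading matrix to align.
#' @param reference reference loading matrix, same dimension.
#' @param fix_first keep column 1 in place (bifactor convention: the
#'   general factor is not permuted among the specifics).
#' @return `L` with columns permuted/sign-flipped; the permutation and signs
#'   are attached as attributes `perm` and `signs`.
#' @export
align_loadings <- function(L, reference, fix_first = FALSE) {
  L <- as.matrix(L); R <- as.matrix(reference)
  stopifnot(all(dim(L) == dim(R)))
  k <- ncol(L)
  cong <- abs(crossprod(L, R)) /
    (sqrt(colSums(L^2)) %o% sqrt(colSums(R^2)) + 1e-12)
  idx <- if (fix_first) 2:k else seq_len(k)
  perms <- .permutations(length(idx))
  bestp <- NULL; bestv <- -Inf
  for (r in seq_len(nrow(perms))) {
    pp <- seq_len(k)
    pp[idx] <- idx[perms[r, ]]
    v <- sum(cong[cbind(pp, seq_len(k))])
    if (v > bestv) { bestv <- v; bestp <- pp }
  }
  out <- L[, bestp, drop = FALSE]
  signs <- vapply(seq_len(k), function(j) {
    s <- sum(out[, j] * R[, j])
    if (s < 0) -1 else 1
  }, numeric(1))
  out <- sweep(out, 2, signs, `*`)
  dimnames(out) <- dimnames(R)
  attr(out, "perm") <- bestp
  attr(out, "signs") <- signs
  out
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Derive a confirmatory simple-structure pattern from a rotated solution
#'
#' Converts a rotated loading matrix into the free/fixed sign pattern used
#' by the confirmatory trio models. The default rule returns the packaged
#' calibrated pattern for the 11-trait panel ([pgs_simple_structure()]);
#' the `"threshold"` rule retains every loading with `|lambda| >= threshold`
#' with its sign.
#'
#' @param solution a `rotation_solution`.
#' @param rule `"packaged"` (default) or `"threshold"`.
#' @param threshold absolute-loading cutoff for the threshold rule.
#' @param drop_factors columns to drop from the pattern (e.g. a residual
#'   factor interpreted as measurement error), by index or name.
#' @return Integer sign-pattern matrix suitable for [trio_model_spec()].
#' @export
simple_structure_from_rotation <- function(solution,
                                           rule = c("packaged", "threshold"),
                                           threshold = 0.1,
                                           drop_factors = NULL) {
  rule <- match.arg(rule)
  if (!solution$converged) {
    warning("Rotation did not converge; pattern may be unstable.",
            call. = FALSE)
  }
  if (rule == "packaged") {
    pat <- pgs_simple_structure()
    L <- solution$rotated_loadings
    if (nrow(L) != nrow(pat)) {
      stop("Packaged pattern is for the 11-trait panel; use rule = \"threshold\".",
           call. = FALSE)
    }
    return(pat)
  }
  L <- solution$rotated_loadings
  if (!is.null(drop_factors)) L <- L[, setdiff(seq_len(ncol(L)),
                                               .col_idx(L, drop_factors)),
                                     drop = FALSE]
  pat <- matrix(0L, nrow(L), ncol(L), dimnames = dimnames(L))
  pat[abs(L) >= threshold] <- ifelse(L[abs(L) >= threshold] > 0, 1L, -1L)
  empty <- colSums(pat != 0) == 0
  if (any(empty)) {
    stop("Factor(s) with no indicator above threshold: ",
         paste(colnames(pat)[empty], collapse = ", "),
         "; the confirmatory factor would be unidentified.", call. = FALSE)
  }
  pat
}

.col_idx <- function(M, sel) {
  if (is.character(sel)) match(sel, colnames(M)) else as.integer(sel)
}
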