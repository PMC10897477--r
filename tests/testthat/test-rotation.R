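test_that("rotation preserves the common-variance matrix and descends monotonically", {
  set.seed(31)
  for (i in 1:5) {
    A <- matrix(rnorm(33), 11, 3)
    sol <- geomin_rotate(A, n_starts = 5, seed = i)
    L <- sol$rotated_loadings
    Phi <- sol$factor_correlations
    expect_lt(max(abs(L %*% Phi %*% t(L) - tcrossprod(A))), 1e-8)
    expect_true(all(diff(sol$trace) <= 1e-12))
  }
  # orthogonal bifactor case preserves fit too
  A <- matrix(rnorm(44), 11, 4)
  sol <- bifactor_geomin_rotate(A, n_starts = 5, seed = 1)
  expect_lt(max(abs(tcrossprod(sol$rotated_loadings) - tcrossprod(A))), 1e-8)
})

test_that("perfect simple structure is a fixed point up to permutation and sign", {
  A <- matrix(0, 9, 3)
  A[1:3, 1] <- c(0.7, 0.6, 0.5)
  A[4:6, 2] <- c(0.8, 0.6, 0.4)
  A[7:9, 3] <- c(0.7, 0.5, 0.6)
  sol <- geomin_rotate(A, n_starts = 10, seed = 2)
  al <- align_loadings(sol$rotated_loadings, A)
  expect_lt(max(abs(al - A)), 0.02)
  expect_lte(sol$criterion_value, triopgs:::.geomin_crit(A, 0.01)$f + 1e-10)
})

test_that("criterion matches a heavy random-restart oracle", {
  set.seed(33)
  A <- matrix(rnorm(33), 11, 3)
  sol <- geomin_rotate(A, n_starts = 30, seed = 3)
  oracle <- geomin_rotate(A, n_starts = 200, seed = 4)
  expect_lt(abs(sol$criterion_value - oracle$criterion_value), 1e-5)
})

test_that("large epsilon flattens the criterion across rotations", {
  set.seed(34)
  A <- matrix(rnorm(33), 11, 3)
  eps <- 1000
  f0 <- triopgs:::.geomin_crit(A, eps)$f
  vals <- replicate(5, {
    Tm <- triopgs:::.random_T(3, orthogonal = TRUE)
    triopgs:::.geomin_crit(A %*% Tm, eps)$f
  })
  expect_lt(max(abs(vals - f0)) / f0, 1e-2)
})

test_that("bifactor rotation keeps an already-bifactor input and obeys the sign convention", {
  A <- pgs_loadings("bold")
  sol <- bifactor_geomin_rotate(A, n_starts = 20, seed = 5)
  al <- align_loadings(sol$rotated_loadings, A, fix_first = TRUE)
  # general column essentially reproduced
  cong <- sum(al[, 1] * A[, 1]) / sqrt(sum(al[, 1]^2) * sum(A[, 1]^2))
  expect_gt(cong, 0.99)
  # sign convention: dominant loading of every factor is positive
  expect_true(all(apply(sol$rotated_loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
})

test_that("bifactor geomin recovers the calibrated generating structure from its exact covariance", {
  L <- pgs_loadings("full")
  S <- tcrossprod(L) + diag(pgs_unique_variances("full"))
  ef <- extract_efa(S, 5, 25293)
  expect_lt(max(abs(tcrossprod(ef$loadings) - tcrossprod(L))), 1e-6)
  sol <- bifactor_geomin_rotate(ef$loadings, n_starts = 30, seed = 6)
  al <- align_loadings(sol$rotated_loadings, L, fix_first = TRUE)
  cong <- sum(al[, 1] * L[, 1]) / sqrt(sum(al[, 1]^2) * sum(L[, 1]^2))
  expect_gt(cong, 0.99)
  expect_equal(al["MDD", 1], 0.747, tolerance = 0.01)
  expect_lt(max(abs(al - L)), 0.05)
})

test_that("simple-structure extraction: packaged pattern, threshold rule, and failure modes", {
  L <- pgs_loadings("full")
  S <- tcrossprod(L) + diag(pgs_unique_variances("full"))
  sol <- bifactor_geomin_rotate(extract_efa(S, 5, 25293)$loadings,
                                n_starts = 10, seed = 7)
  pat <- simple_structure_from_rotation(sol)
  expect_equal(unname(pat[, "P"]), rep(1L, 11))
  expect_equal(rownames(pat)[pat[, "NDV"] != 0], c("ADHD", "ASD"))
  expect_equal(rownames(pat)[pat[, "PSYCH"] != 0], c("BIPO", "SCHZ"))
  expect_equal(rownames(pat)[pat[, "CONS"] != 0], c("ANOR", "OCD", "AUD"))
  expect_equal(pat["AUD", "CONS"], -1L)
  expect_equal(ncol(pat), 4L)   # residual factor dropped

  fake <- structure(list(rotated_loadings = matrix(c(0.5, 0.05, 0.05, 0.5),
                                                   2, 2), converged = TRUE),
                    class = "rotation_solution")
  thr <- simple_structure_from_rotation(fake, rule = "threshold",
                                        threshold = 0.1)
  expect_equal(unname(thr), matrix(c(1L, 0L, 0L, 1L), 2, 2))

  fake0 <- structure(list(rotated_loadings = matrix(c(0.5, 0.4, 0.01, 0.02),
                                                    2, 2), converged = TRUE),
                     class = "rotation_solution")
  expect_error(simple_structure_from_rotation(fake0, rule = "threshold",
                                              threshold = 0.1),
               "unidentified")
})
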