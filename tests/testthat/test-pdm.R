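test_that("Procrustes alignment undoes rigid and similarity motion", {
  set.seed(41)
  base <- matrix(rnorm(73 * 3, sd = 25), 73, 3)
  # identical shapes stay put (up to centering)
  ga0 <- procrustes_align(list(base, base))
  expect_lt(sqrt(mean((ga0$aligned[[1]] - ga0$aligned[[2]])^2)), 1e-10)
  # a rigidly moved copy aligns back
  R <- random_rotation()
  moved <- sweep(base %*% R, 2, c(12, -3, 40), `+`)
  ga <- procrustes_align(list(base, moved))
  expect_lt(sqrt(mean((ga$aligned[[1]] - ga$aligned[[2]])^2)), 1e-8)
  # several random similarity copies of one shape coincide after alignment
  copies <- lapply(1:6, function(i)
    sweep(runif(1, 0.5, 2) * base %*% random_rotation(), 2,
          rnorm(3, sd = 50), `+`))
  ga2 <- procrustes_align(copies)
  for (i in 2:6)
    expect_lt(sqrt(mean((ga2$aligned[[1]] - ga2$aligned[[i]])^2)), 1e-6)
  expect_error(procrustes_align(list(matrix(1, 5, 3), matrix(1, 5, 3))),
               "degenerate")
})

test_that("the pairwise similarity fit agrees with an independent oracle", {
  skip_if_not_installed("vegan")
  set.seed(48)
  X <- matrix(rnorm(60, sd = 15), 20, 3)
  Y <- sweep(1.4 * X %*% random_rotation(), 2, c(5, -2, 9), `+`) +
    matrix(rnorm(60, sd = 0.5), 20, 3)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sim <- landcorr:::.procrustes_fit(Yc, Xc)
  ours <- sim$beta * Yc %*% sim$R
  vg <- vegan::procrustes(Xc, Yc)     # rotates and scales Y onto X
  expect_lt(max(abs(ours - vg$Yrot)), 1e-8)
})

test_that("PCA modes are orthonormal, ordered and recover a planted field", {
  set.seed(42)
  base <- matrix(rnorm(73 * 3, sd = 25), 73, 3)
  field <- matrix(rnorm(73 * 3), 73, 3)
  field <- field / sqrt(sum(field^2))
  shapes <- lapply(seq(-2, 2, length.out = 9), function(b) base + 2 * b * field)
  pdm <- fit_pdm(shapes)          # already in a common frame
  expect_gt(abs(sum(pdm$modes[, 1] * as.vector(field))), 0.999)
  g <- crossprod(pdm$modes)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  expect_true(all(diff(pdm$mode_variances) <= 1e-12))
  # identical shapes give a modeless model
  pdm0 <- fit_pdm(list(base, base, base))
  expect_equal(length(pdm0$mode_variances), 0)
  expect_equal(compactness(pdm0, 1), 1)
  # total mode variance equals the total per-point variance
  X <- t(vapply(shapes, as.vector, numeric(73 * 3)))
  expect_equal(pdm$total_variance, sum(apply(X, 2, var)), tolerance = 1e-8)
  expect_equal(sum(pdm$mode_variances), pdm$total_variance, tolerance = 1e-8)
})

test_that("reconstruction is exact on training members and nested in modes", {
  set.seed(43)
  base <- matrix(rnorm(50 * 3, sd = 25), 50, 3)
  shapes <- lapply(1:8, function(i) base + matrix(rnorm(150, sd = 2), 50, 3))
  ga <- procrustes_align(shapes)
  pdm <- fit_pdm(ga)
  errs <- vapply(shapes, function(s)
    reconstruct(pdm, s, n_modes = ncol(pdm$modes))$error, numeric(1))
  expect_lt(max(errs), 1e-8)
  # zero modes reproduce the mean shape
  r0 <- reconstruct(pdm, shapes[[1]], n_modes = 0)
  expect_equal(r0$n_modes, 0)
  # the RMS error is non-increasing in the number of modes (nested
  # projections); the mean-distance error tracks it closely
  test_shape <- base + matrix(rnorm(150, sd = 2), 50, 3)
  e <- vapply(0:ncol(pdm$modes), function(k)
    reconstruct(pdm, test_shape, n_modes = k)$error_rms, numeric(1))
  expect_true(all(diff(e) <= 1e-10))
  expect_warning(reconstruct(pdm, test_shape, n_modes = 99), "clamped")
})

test_that("compactness is the explained-variance ratio", {
  set.seed(44)
  base <- matrix(rnorm(40 * 3, sd = 20), 40, 3)
  f1 <- matrix(rnorm(120), 40, 3); f1 <- f1 / sqrt(sum(f1^2))
  f2raw <- matrix(rnorm(120), 40, 3)
  f2 <- f2raw - sum(f2raw * f1) * f1
  f2 <- f2 / sqrt(sum(f2^2))
  # coefficients with sample variances exactly 4 and 1
  b1 <- c(-2, 2, -2, 2, 0, 0) * sqrt(4 / var(c(-2, 2, -2, 2, 0, 0)))
  b2 <- c(1, 1, -1, -1, 1, -1) * sqrt(1 / var(c(1, 1, -1, -1, 1, -1)))
  expect_equal(sum(b1 * b2), 0)     # uncorrelated coefficients by design
  shapes <- lapply(1:6, function(i) base + b1[i] * f1 + b2[i] * f2)
  pdm <- fit_pdm(shapes)
  expect_equal(compactness(pdm, 1), 0.8, tolerance = 1e-8)
  expect_equal(compactness(pdm, length(pdm$mode_variances)), 1)
})

test_that("coupled LOO prefers random-operator models under operator bias", {
  noise <- annotation_noise_model(1, 0.1, 0.3, n_operators = 4,
                                  n_sessions = 2)
  sim <- simulate_study(10, noise, sigma_portrait = 2, seed = 45)
  loo <- coupled_loo_cv(sim$annotations, seed = 45)
  expect_equal(dim(loo$table), c(4, 3))
  expect_lt(loo$mean_random, loo$mean_single)
  # deterministic repeat
  loo2 <- coupled_loo_cv(sim$annotations, seed = 45)
  expect_identical(loo$table, loo2$table)
  # identical operators without noise: both schemes coincide
  z <- annotation_noise_model(0, 0, 0, n_operators = 3, n_sessions = 2)
  simz <- simulate_study(5, z, sigma_portrait = 2, seed = 46)
  looz <- coupled_loo_cv(simz$annotations, seed = 46)
  expect_lt(max(abs(looz$table$single_error - looz$table$random_error)), 1e-8)
  expect_error(coupled_loo_cv(annotation_set(
    simz$annotations$coords[1:2, , , , , drop = FALSE])), ">= 3 portraits")
})

test_that("models round-trip through the text container", {
  set.seed(47)
  shapes <- lapply(1:5, function(i) matrix(rnorm(60, sd = 10), 20, 3))
  pdm <- fit_pdm(procrustes_align(shapes))
  d <- withr::local_tempdir()
  write_pdm(pdm, file.path(d, "model"))
  back <- read_pdm(file.path(d, "model"))
  expect_equal(back$mean_shape, pdm$mean_shape, tolerance = 1e-12)
  expect_equal(back$modes, pdm$modes, tolerance = 1e-12)
  expect_equal(back$mode_variances, pdm$mode_variances, tolerance = 1e-12)
})
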