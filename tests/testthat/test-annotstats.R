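test_that("consensus positions average the replicates", {
  sim <- small_study(seed = 3)
  ann <- sim$annotations
  cons <- consensus_positions(ann)
  expect_equal(dim(cons), c(4, 73, 3))
  expect_equal(cons[2, 5, ], colMeans(rbind(
    ann$coords[2, 1, 1, 5, ], ann$coords[2, 1, 2, 5, ],
    ann$coords[2, 2, 1, 5, ], ann$coords[2, 2, 2, 5, ],
    ann$coords[2, 3, 1, 5, ], ann$coords[2, 3, 2, 5, ])))
  # zero-noise simulation: consensus equals the true landmarks exactly
  z <- small_study(sigma = c(0, 0, 0), seed = 4)
  expect_equal(consensus_positions(z$annotations), z$true_landmarks)
})

test_that("error summary is zero without noise and scales with the data", {
  z <- small_study(sigma = c(0, 0, 0), seed = 5)
  es0 <- error_summary(z$annotations)
  expect_equal(max(es0$mean_error), 0)
  expect_equal(max(es0$sd_error), 0)
  sim <- small_study(seed = 6)
  es <- error_summary(sim$annotations)
  doubled <- annotation_set(2 * sim$annotations$coords)
  es2 <- error_summary(doubled)
  expect_equal(es2$mean_error, 2 * es$mean_error, tolerance = 1e-12)
  expect_true(all(es$mean_error >= 0) && all(es$sd_error >= 0))
})

test_that("mean error matches the Monte-Carlo oracle under isotropic noise", {
  # residual-only noise, sigma 1 mm, large design; the distance to the
  # replicate mean is chi-distributed and shrunk by the centering factor
  noise <- annotation_noise_model(0, 0, 1, n_operators = 4, n_sessions = 3)
  sim <- simulate_study(60, noise, sigma_portrait = 0, seed = 7)
  es <- error_summary(sim$annotations)
  oracle <- mc_mean_error(r = 12, sigma = 1)
  expect_equal(mean(es$mean_error), oracle, tolerance = 0.01)
})

test_that("variance components are exact on zero noise and match the oracle", {
  z <- small_study(sigma = c(0, 0, 0), sigma_portrait = 0, seed = 8)
  vc0 <- fit_variance_components(z$annotations)
  expect_lt(max(abs(as.matrix(vc0[, 2:5]))), 1e-12)
  # EMS estimator equals the quadratic-form (MIVQUE0) oracle on a tiny
  # 3-operator x 2-session x 2-portrait design
  noise <- annotation_noise_model(1, 0.5, 0.7, n_operators = 3, n_sessions = 2)
  sim <- simulate_study(2, noise, sigma_portrait = 1.5, seed = 9)
  vc <- fit_variance_components(sim$annotations)
  for (l in c(1, 20, 73)) {
    oracle <- c(0, 0, 0, 0)
    for (c3 in 1:3) {
      y <- aperm(sim$annotations$coords[, , , l, c3], c(1, 2, 3))
      oracle <- oracle + vc_oracle(y)
    }
    est_raw <- c(vc$var_operator[l], vc$var_day[l], vc$var_portrait[l],
                 vc$var_residual[l])
    # compare before truncation: clip the oracle the same way
    expect_equal(est_raw, pmax(oracle, 0), tolerance = 1e-8)
  }
})

test_that("variance components are equivariant under rigid motion", {
  sim <- small_study(seed = 10)
  vc <- fit_variance_components(sim$annotations)
  set.seed(99)
  R <- random_rotation()
  tr <- c(10, -40, 25)
  moved <- sim$annotations$coords
  dm <- dim(moved)
  flat <- matrix(moved, ncol = 3)
  flat <- flat %*% R + matrix(tr, nrow(flat), 3, byrow = TRUE)
  vc2 <- fit_variance_components(annotation_set(array(flat, dm)))
  expect_equal(as.matrix(vc2[, 2:5]), as.matrix(vc[, 2:5]), tolerance = 1e-8)
})

test_that("negative component estimates are truncated and flagged", {
  # tiny design with pure residual noise often drives operator/day
  # components negative before truncation
  noise <- annotation_noise_model(0, 0, 1, n_operators = 2, n_sessions = 2)
  sim <- simulate_study(3, noise, sigma_portrait = 0, seed = 11)
  vc <- fit_variance_components(sim$annotations)
  expect_true(all(as.matrix(vc[, 2:5]) >= 0))
  expect_true(any(vc$truncated))
})

test_that("interaction check flags additive data negligible, planted not", {
  # full study design so every interaction has enough degrees of freedom
  hits <- 0
  n_seeds <- 50
  noise <- annotation_noise_model(1, 0.3, 0.5, n_operators = 6,
                                  n_sessions = 2)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_study(36, noise, sigma_portrait = 2, seed = 100 + s)
    if (interaction_check(sim$annotations, 1)$negligible) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_seeds)
  # plant an operator x portrait interaction of SD 2 mm at landmark 1
  sim <- small_study(n_portraits = 6, seed = 55)
  coords <- sim$annotations$coords
  set.seed(56)
  inter <- array(rnorm(6 * 3 * 3, sd = 2), c(6, 3, 3))   # (portrait, op, axis)
  for (j in seq_len(dim(coords)[3]))
    coords[, , j, 1, ] <- coords[, , j, 1, ] + inter
  res <- interaction_check(annotation_set(coords), 1)
  expect_false(res$negligible)
  expect_gt(res$table$ratio[res$table$term == "O:I"], 2)
  # zero noise: degenerate but quiet
  z <- small_study(sigma = c(0, 0, 0), sigma_portrait = 0, seed = 57)
  res0 <- interaction_check(z$annotations, 1)
  expect_true(res0$negligible)
  expect_equal(max(res0$table$ms), 0)
})

test_that("degenerate designs are rejected with instructive errors", {
  sim <- small_study(seed = 12)
  one_session <- annotation_set(sim$annotations$coords[, , 1, , , drop = FALSE])
  expect_error(fit_variance_components(one_session), ">= 2")
  one_rep <- annotation_set(sim$annotations$coords[, 1, 1, , , drop = FALSE])
  expect_error(error_summary(one_rep), "replicates")
})
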