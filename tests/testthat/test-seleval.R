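make_dense_set <- function(base, np, a, b, jitter_sd = 0, seed = 1) {
  V <- nrow(base$vertices)
  arr <- array(NA_real_, c(np, a, b, V, 3))
  set.seed(seed)
  for (k in seq_len(np)) for (i in seq_len(a)) for (j in seq_len(b))
    arr[k, i, j, , ] <- base$vertices +
      matrix(rnorm(V * 3, sd = jitter_sd), V, 3)
  dense_correspondence_set(arr, base$faces)
}

test_that("dense point variance vanishes for identical replicates", {
  base <- plane_mesh(8)
  ds <- make_dense_set(base, np = 2, a = 2, b = 2, jitter_sd = 0)
  dv <- dense_point_variance(ds)
  expect_equal(max(dv$per_point), 0)
  expect_equal(dv$mean, 0)
  expect_error(dense_point_variance(
    dense_correspondence_set(ds$vertices[, 1, 1, , , drop = FALSE],
                             base$faces)), ">= 2 replicates")
})

test_that("dense point variance matches the Gaussian jitter oracle", {
  base <- plane_mesh(12)
  sigma <- 0.8
  r <- 6                     # 3 operators x 2 sessions
  ds <- make_dense_set(base, np = 8, a = 3, b = 2, jitter_sd = sigma,
                       seed = 2)
  dv <- dense_point_variance(ds)
  # per point and portrait the statistic is sqrt(mean_r ||x - xbar||^2);
  # its expectation under iid isotropic jitter follows from the chi
  # distribution with 3(r-1)/r effective variance -- evaluated by Monte Carlo
  set.seed(3)
  n_draws <- 2e5
  x <- array(rnorm(n_draws * r * 3, sd = sigma), c(n_draws, r, 3))
  ctr <- apply(x, c(1, 3), mean)
  rms <- sqrt(rowMeans((x[, , 1] - ctr[, 1])^2 + (x[, , 2] - ctr[, 2])^2 +
                         (x[, , 3] - ctr[, 3])^2))
  oracle <- mean(rms)
  expect_equal(dv$mean, oracle, tolerance = 0.02)
  # and the closed-form upper-scale sanity: sigma * sqrt(3 (r-1)/r)
  expect_lt(dv$mean, sigma * sqrt(3))
})

test_that("dense point variance ignores rigid motion of whole portraits", {
  base <- bump_mesh(20, 20, n = 10)
  ds <- make_dense_set(base, np = 3, a = 2, b = 2, jitter_sd = 0.5, seed = 4)
  dv <- dense_point_variance(ds)
  moved <- ds$vertices
  set.seed(5)
  R <- random_rotation(); tr <- c(100, -50, 20)
  for (i in 1:2) for (j in 1:2)
    moved[2, i, j, , ] <- sweep(moved[2, i, j, , ] %*% R, 2, tr, `+`)
  dv2 <- dense_point_variance(dense_correspondence_set(moved, base$faces))
  expect_equal(dv2$mean, dv$mean, tolerance = 1e-10)
})

test_that("landmark prediction error isolates a planted offset", {
  tpl <- make_template(20)
  np <- 3; a <- 2; b <- 2
  V <- n_vertices(tpl$mesh)
  true <- array(rep(tpl$mesh$vertices[tpl$landmarks, ], each = np),
                c(np, 73, 3))
  z <- annotation_noise_model(0, 0, 0, n_operators = a, n_sessions = b)
  ann <- simulate_annotations(true, z, seed = 6)
  dense <- array(rep(tpl$mesh$vertices, each = np * a * b), c(np, a, b, V, 3))
  ds <- dense_correspondence_set(dense, tpl$mesh$faces)
  err0 <- landmark_prediction_error(ds, ann, tpl$landmarks)
  expect_equal(max(err0$prediction_error), 0)
  # shift all manual annotations of landmark 5 by a (1,2,2) mm offset
  shifted <- ann$coords
  shifted[, , , 5, ] <- shifted[, , , 5, ] +
    array(rep(c(1, 2, 2), each = np * a * b), c(np, a, b, 3))
  err <- landmark_prediction_error(ds, annotation_set(shifted), tpl$landmarks)
  expect_equal(err$prediction_error[5], 3, tolerance = 1e-10)
  expect_equal(max(err$prediction_error[-5]), 0)
  expect_error(landmark_prediction_error(ds, ann, c(tpl$landmarks[-73], 1e6)),
               "out-of-range")
})

test_that("dropping a noise-free landmark does not improve its own prediction", {
  # one-sided sign test over seeded repetitions: predicting a zero-noise
  # landmark from the correspondence (excluded) should err at least as much
  # as annotating it directly (included)
  tpl <- make_template(20)
  pop <- population_model(tpl, mode_sd = c(2, 1))
  target_lm <- 33                        # zero-noise landmark under study
  sel_with <- c(17:34, 46, 50, 58, 63, 68, 73)
  sel_without <- setdiff(sel_with, target_lm)
  sigma <- rep(1, 73)
  sigma[target_lm] <- 0
  n_seeds <- 50
  worse <- 0
  for (s in seq_len(n_seeds)) {
    samp <- sample_population(pop, 1, seed = 700 + s)
    noise <- annotation_noise_model(sigma, 0, 0.2, n_operators = 2,
                                    n_sessions = 1)
    noise$sigma_residual[target_lm] <- 0
    ann <- simulate_annotations(samp$true_landmarks, noise, seed = 800 + s)
    params <- energy_params(prior_weight = 0.2, candidate_count = 8,
                            max_sweeps = 8, seed = 900 + s)
    e_in <- landmark_prediction_error(
      build_correspondences(tpl, samp$meshes, ann, sel_with, params),
      ann, tpl$landmarks)$prediction_error[target_lm]
    e_out <- landmark_prediction_error(
      build_correspondences(tpl, samp$meshes, ann, sel_without, params),
      ann, tpl$landmarks)$prediction_error[target_lm]
    if (e_out >= e_in) worse <- worse + 1
  }
  expect_lt(binom.test(worse, n_seeds, alternative = "greater")$p.value, 0.05)
})

test_that("selection comparison is deterministic and covers the full set", {
  tpl <- make_template(20)
  pop <- population_model(tpl, mode_sd = c(2, 1))
  samp <- sample_population(pop, 2, seed = 7)
  noise <- annotation_noise_model(0.5, 0.1, 0.3, n_operators = 2,
                                  n_sessions = 1)
  ann <- simulate_annotations(samp$true_landmarks, noise, seed = 8)
  params <- energy_params(prior_weight = 0.2, candidate_count = 8,
                          max_sweeps = 8, seed = 9)
  sels <- list(full = landmark_selection("full", 1:73))
  cmp <- compare_selections(sels, tpl, samp$meshes, ann, params,
                            detail_selection = "full")
  expect_equal(nrow(cmp$table), 1)
  expect_equal(cmp$table$n_landmarks, 73)
  expect_equal(nrow(cmp$per_landmark), 73)
  cmp2 <- compare_selections(sels, tpl, samp$meshes, ann, params)
  expect_identical(cmp$table, cmp2$table)
})
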