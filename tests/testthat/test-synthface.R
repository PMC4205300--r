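test_that("the template carries 73 distinct, bilaterally symmetric landmarks", {
  tpl <- make_template(40)
  expect_gte(n_vertices(tpl$mesh), 1500)
  expect_length(tpl$landmarks, 73)
  expect_false(anyDuplicated(tpl$landmarks) > 0)
  v <- tpl$mesh$vertices
  # pupils mirror each other about the sagittal plane
  expect_lt(max(abs(v[tpl$landmarks[33], ] -
                      c(-1, 1, 1) * v[tpl$landmarks[34], ])), 1e-6)
  # eyes above nose above mouth above jaw
  expect_gt(v[tpl$landmarks[33], 2], v[tpl$landmarks[46], 2])
  expect_gt(v[tpl$landmarks[46], 2], v[tpl$landmarks[50], 2])
  expect_gt(v[tpl$landmarks[50], 2], v[tpl$landmarks[68], 2])
  expect_error(make_template(10), "resolution")
})

test_that("the nose tip is a genuine high-curvature landmark", {
  tpl <- make_template(40)
  v <- tpl$mesh$vertices
  k_tip <- mean_curvature(tpl$mesh, tpl$landmarks[46])
  cheek <- which.min((v[, 1] - 45)^2 + (v[, 2] + 20)^2)
  k_cheek <- mean_curvature(tpl$mesh, cheek)
  expect_gt(abs(k_tip), abs(k_cheek))
})

test_that("population sampling is deterministic and honours mode SDs", {
  tpl <- make_template(24)
  pop0 <- population_model(tpl, mode_sd = c(0, 0))
  s0 <- sample_population(pop0, 3, seed = 5)
  for (k in 1:3)
    expect_equal(s0$meshes[[k]]$vertices, tpl$mesh$vertices)
  pop <- population_model(tpl, mode_sd = c(3, 2, 1.5))
  a <- sample_population(pop, 4, seed = 9)
  b <- sample_population(pop, 4, seed = 9)
  expect_identical(a$true_landmarks, b$true_landmarks)
  expect_identical(a$meshes[[2]]$vertices, b$meshes[[2]]$vertices)
  # modes are mutually orthogonal as flattened fields
  flat <- vapply(pop$modes, as.vector, numeric(3 * n_vertices(tpl$mesh)))
  g <- crossprod(flat)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  # empirical SD of a single-mode coefficient matches its nominal SD
  pop1 <- population_model(tpl, mode_sd = 2)
  s <- sample_population(pop1, 200, seed = 31)
  expect_gt(sd(s$coefficients[, 1]), 1.6)
  expect_lt(sd(s$coefficients[, 1]), 2.4)
})

test_that("simulated annotations follow the additive effects structure", {
  tpl <- make_template(24)
  true <- array(rep(tpl$mesh$vertices[tpl$landmarks, ], each = 3),
                c(3, 73, 3))
  z <- annotation_noise_model(0, 0, 0, n_operators = 2, n_sessions = 2)
  ann0 <- simulate_annotations(true, z, seed = 1)
  for (i in 1:2) for (j in 1:2)
    expect_equal(ann0$coords[, i, j, , ], true)
  # pure operator effect: zero within-operator spread, a fixed between-
  # operator offset shared across portraits and sessions
  op <- annotation_noise_model(1, 0, 0, n_operators = 2, n_sessions = 2)
  ann <- simulate_annotations(true, op, seed = 2)
  for (i in 1:2)
    expect_lt(max(abs(ann$coords[, i, 1, , ] - ann$coords[, i, 2, , ])), 1e-12)
  offset1 <- ann$coords[1, 1, 1, , ] - ann$coords[1, 2, 1, , ]
  offset2 <- ann$coords[3, 1, 2, , ] - ann$coords[3, 2, 2, , ]
  expect_equal(offset1, offset2, tolerance = 1e-12)
  expect_gt(max(abs(offset1)), 0)
  # determinism
  expect_identical(simulate_annotations(true, op, seed = 2)$coords,
                   ann$coords)
})

test_that("fixture sets round-trip through the documented layout", {
  tpl <- make_template(24)
  pop <- population_model(tpl, mode_sd = c(2, 1))
  samp <- sample_population(pop, 3, seed = 4)
  noise <- annotation_noise_model(1, 0.3, 0.5, n_operators = 2, n_sessions = 2)
  ann <- simulate_annotations(samp$true_landmarks, noise, seed = 6)
  d <- withr::local_tempdir()
  write_fixture_set(d, samp, ann, format = "obj")
  expect_length(list.files(d, pattern = "^lm_"), 3 * 2 * 2)
  expect_length(list.files(d, pattern = "^portrait_"), 3)
  manifest <- read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(manifest), 12)
  back <- read_fixture_set(d)
  expect_lt(max(abs(back$annotations$coords - ann$coords)), 1e-6)
  expect_lt(max(abs(back$meshes[[2]]$vertices - samp$meshes[[2]]$vertices)),
            1e-6)
})
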