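# Synthetic face population: template surface, shape modes, annotation noise.
#
# The generator stands in for real facial scans: a half-ellipsoid face sheet
# with analytic nose/brow/lip/chin bumps carries 73 designated vertices laid
# out in the standard annotation topology (bilaterally symmetric; eyes above
# nose above mouth above jaw), population variation is injected through
# smooth orthogonal displacement fields, and repeated multi-operator
# annotations follow the additive random-effects structure
# Y_ijk = mu + O_i + D_j + I_k + eps_ijk.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# face height function (mm): ellipsoid sheet plus feature bumps; even in x
.face_height <- function(x, y) {
  z <- 55 * sqrt(pmax(0, 1 - (x / 80)^2 - (y / 100)^2))
  # nose ridge and tip
  z <- z + 14 * exp(-x^2 / (2 * 9^2) - (y + 5)^2 / (2 * 16^2))
  z <- z + 8 * exp(-(x^2 + (y + 13)^2) / (2 * 6^2))
  # brow ridges (bilateral)
  z <- z + 4 * exp(-(y - 38)^2 / (2 * 6^2)) * exp(-(abs(x) - 32)^2 / (2 * 12^2))
  # lips and chin
  z <- z + 3 * exp(-(y + 45)^2 / (2 * 5^2)) * exp(-x^2 / (2 * 20^2))
  z <- z + 5 * exp(-(x^2 + (y + 75)^2) / (2 * 12^2))
  z
}

# (x, y) layout of the right-side and midline landmarks; left side is mirrored
.landmark_layout <- function() {
  ell <- function(cx, cy, a, b, k) {
    th <- (k - 1) * pi / 4
    cbind(cx + a * cos(th), cy + b * sin(th))
  }
  xy <- matrix(NA_real_, 73, 2)
  xy[1:8, ] <- ell(34, 41, 18, 3.5, 1:8)    # right eyebrow (1 lateral, 5 medial)
  xy[17:24, ] <- ell(30, 22, 12, 5, 1:8)    # right eye (17 lateral, 21 medial canthus)
  xy[33, ] <- c(30, 22)                     # right pupil center
  xy[45, ] <- c(14, -4)                     # nose side, upper
  xy[44, ] <- c(17, -13)
  xy[43, ] <- c(16, -20)                    # outer alar-facial groove
  xy[42, ] <- c(8, -23)                     # inner alar-labial groove
  xy[41, ] <- c(4, -27)
  xy[40, ] <- c(0, -27)                     # columella / upper lip
  xy[46, ] <- c(0, -13)                     # nose tip
  xy[47, ] <- c(26, -45)                    # right oral commissure
  xy[48, ] <- c(17, -41)
  xy[49, ] <- c(7, -39.5)
  xy[50, ] <- c(0, -39)                     # cupid's bow
  xy[58, ] <- c(0, -52)                     # lower lip midpoint
  xy[59, ] <- c(5, -51.5)
  xy[60, ] <- c(10, -50.5)
  xy[61, ] <- c(15, -49)
  xy[62, ] <- c(20, -47.5)
  xy[63, ] <- c(55, -20)                    # right ear attachment
  xy[64, ] <- c(50, -42)
  xy[65, ] <- c(40, -60)
  xy[66, ] <- c(28, -72)
  xy[67, ] <- c(14, -78)
  xy[68, ] <- c(0, -80)                     # central jaw
  xy
}

# (right, left) landmark pairs related by sagittal mirror symmetry
.mirror_pairs <- function() {
  rbind(cbind(1:8, 9:16),        # eyebrows
        cbind(17:24, 25:32),     # eyes
        c(33, 34),               # pupils
        cbind(c(45, 44, 43, 42, 41), c(35, 36, 37, 38, 39)),  # nose sides
        cbind(c(47, 48, 49), c(53, 52, 51)),                  # upper lip
        cbind(c(62, 61, 60, 59), c(54, 55, 56, 57)),          # lower lip
        cbind(c(63, 64, 65, 66, 67), c(73, 72, 71, 70, 69)))  # jaw/ear
}

#' Synthetic face template with designated landmarks
#'
#' Builds a face-like open surface on a regular grid: a half-ellipsoid sheet
#' with analytic bumps for the nose ridge and tip, brow ridges, lips and
#' chin, so the designated high-curvature landmarks (nose, jaw line) really
#' do sit in regions of non-trivial curvature. 73 grid vertices are
#' designated as true landmarks, laid out bilaterally symmetric about the
#' sagittal (x = 0) plane in the standard annotation topology.
#'
#' @param resolution integer number of grid subdivisions per axis (>= 20);
#'   the mesh has `(resolution + 1)^2` vertices. Odd values are rounded up so
#'   that a midline vertex column exists.
#' @return a `face_template`: list with `mesh` (a [surface_mesh()]) and
#'   `landmarks` (integer vector of 73 vertex indices).
#' @export
make_template <- function(resolution = 40) {
  if (!is.finite(resolution) || resolution < 20)
    stop("resolution must be >= 20 to place 73 distinct landmarks")
  res <- as.integer(resolution)
  if (res %% 2L == 1L) res <- res + 1L
  xs <- seq(-70, 70, length.out = res + 1L)
  ys <- seq(-90, 90, length.out = res + 1L)
  g <- expand.grid(x = xs, y = ys)      # x varies fastest: id = (iy-1)*(res+1)+ix
  v <- cbind(g$x, g$y, .face_height(g$x, g$y))
  nx <- res + 1L
  faces <- matrix(0L, 0L, 3L)
  ix <- rep(seq_len(res), res)
  iy <- rep(seq_len(res), each = res)
  a <- (iy - 1L) * nx + ix
  b <- a + 1L
  cc <- a + nx
  d <- cc + 1L
  # counter-clockwise seen from +z so normals point out of the face
  faces <- rbind(cbind(a, b, d), cbind(a, d, cc))
  mesh <- surface_mesh(v, faces)

  xy <- .landmark_layout()
  mp <- .mirror_pairs()
  mirrored_right <- mp[, 1]
  lm <- integer(73)
  occupied <- logical(nrow(v))
  mid <- (nx + 1L) %/% 2L                   # midline column (x = 0)
  # place right-side and midline landmarks on the nearest free grid vertex;
  # mirror-paired landmarks stay strictly right of the midline so their
  # mirrored partner is a distinct vertex
  for (l in which(!is.na(xy[, 1]))) {
    if (l %in% mirrored_right) {
      cols <- (mid + 1L):nx
    } else {
      cols <- mid                           # midline landmark
    }
    cand <- as.vector(outer(cols, (seq_len(nx) - 1L) * nx, `+`))
    cand <- cand[!occupied[cand]]
    d2 <- (v[cand, 1] - xy[l, 1])^2 + (v[cand, 2] - xy[l, 2])^2
    pick <- cand[which.min(d2)]
    lm[l] <- pick
    occupied[pick] <- TRUE
  }
  for (r in seq_len(nrow(mp))) {
    right <- lm[mp[r, 1]]
    ixn <- (right - 1L) %% nx + 1L
    iyn <- (right - 1L) %/% nx + 1L
    lm[mp[r, 2]] <- (iyn - 1L) * nx + (nx + 1L - ixn)   # mirrored column
  }
  if (anyDuplicated(lm))
    stop("resolution ", resolution, " too low: landmark vertices collide (",
         paste(which(duplicated(lm)), collapse = ", "), ")")
  structure(list(mesh = mesh, landmarks = lm), class = "face_template")
}

#' @export
print.face_template <- function(x, ...) {
  cat(sprintf("face_template: %d vertices, %d faces, 73 designated landmarks\n",
              n_vertices(x$mesh), n_faces(x$mesh)))
  invisible(x)
}

#' Population shape model for the synthetic faces
#'
#' Attaches smooth low-frequency displacement fields (mutually orthogonal as
#' flattened vectors, scaled to unit per-vertex RMS displacement) to a
#' template. Sampling a face draws one coefficient per mode from
#' `Normal(0, mode_sd^2)`, so `mode_sd` is the population SD of per-vertex
#' RMS displacement in mm along each mode.
#'
#' @param template a `face_template` from [make_template()].
#' @param mode_sd numeric vector of per-mode SDs (mm); its length sets the
#'   number of modes (at most 6 built-in basis fields).
#' @return a `population_model`: list with `template`, `modes` (list of
#'   n x 3 matrices) and `mode_sd`.
#' @export
population_model <- function(template, mode_sd = c(3, 2, 1.5, 1)) {
  stopifnot(inherits(template, "face_template"))
  if (any(mode_sd < 0)) stop("mode_sd must be non-negative")
  m <- length(mode_sd)
  if (m < 1 || m > 6) stop("between 1 and 6 modes are supported")
  v <- template$mesh$vertices
  n <- nrow(v)
  u <- v[, 1] / 70; w <- v[, 2] / 90
  zero <- numeric(n)
  basis <- list(
    cbind(zero, zero, cos(pi * u / 2) * cos(pi * w / 2)),        # depth
    cbind(u, zero, zero),                                        # width
    cbind(zero, w, zero),                                        # height
    cbind(zero, zero, sin(pi * u) * cos(pi * w / 2)),            # asymmetric depth
    cbind(zero, zero, cos(pi * u / 2) * sin(pi * w)),            # chin/forehead
    cbind(sin(pi * w) * 0.5, zero, cos(pi * u) * cos(pi * w)))   # shear + ripple
  flat <- vapply(basis[seq_len(m)], as.vector, numeric(3 * n))
  q <- qr.Q(qr(flat))                      # orthogonalize
  modes <- lapply(seq_len(m), function(k) {
    f <- matrix(q[, k], n, 3)
    f / sqrt(mean(rowSums(f^2)))           # unit RMS per-vertex displacement
  })
  structure(list(template = template, modes = modes, mode_sd = as.numeric(mode_sd)),
            class = "population_model")
}

#' Sample a synthetic face population
#'
#' Each sampled face is `template + sum_m b_m * mode_m` with
#' `b_m ~ Normal(0, mode_sd_m^2)`, deterministic given `seed`. True landmark
#' positions are the displaced designated vertices.
#'
#' @param model a `population_model`.
#' @param n number of faces to sample.
#' @param seed integer seed.
#' @return list with `meshes` (list of n `surface_mesh`), `true_landmarks`
#'   (n x 73 x 3 array, mm) and `coefficients` (n x n_modes matrix).
#' @export
sample_population <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "population_model"), n >= 1)
  tpl <- model$template
  m <- length(model$modes)
  b <- with_seed(seed, matrix(stats::rnorm(n * m), n, m) %*% diag(model$mode_sd, m))
  meshes <- vector("list", n)
  lms <- array(NA_real_, c(n, 73, 3))
  for (k in seq_len(n)) {
    v <- tpl$mesh$vertices
    for (j in seq_len(m)) v <- v + b[k, j] * model$modes[[j]]
    meshes[[k]] <- surface_mesh(v, tpl$mesh$faces)
    lms[k, , ] <- v[tpl$landmarks, ]
  }
  list(meshes = meshes, true_landmarks = lms, coefficients = b)
}

#' Annotation noise model for repeated landmarking
#'
#' Describes the random-effects structure of simulated annotations:
#' per-landmark SDs (mm, isotropic over x/y/z) of the operator effect `O_i`
#' (drawn once per operator and landmark, shared across portraits and
#' sessions -- a systematic per-operator bias), the session-day effect `D_j`
#' (once per session and landmark) and the residual `eps_ijk`.
#'
#' @param sigma_operator,sigma_day,sigma_residual scalar or length-73 SDs (mm).
#' @param n_operators,n_sessions design sizes.
#' @return an `annotation_noise_model`.
#' @export
annotation_noise_model <- function(sigma_operator = 1, sigma_day = 0.3,
                                   sigma_residual = 0.5,
                                   n_operators = 6L, n_sessions = 2L) {
  expand <- function(s, nm) {
    if (length(s) == 1L) s <- rep(s, 73)
    if (length(s) != 73L) stop(nm, " must be scalar or length 73")
    if (any(!is.finite(s)) || any(s < 0)) stop(nm, " must be finite and >= 0")
    as.numeric(s)
  }
  structure(list(sigma_operator = expand(sigma_operator, "sigma_operator"),
                 sigma_day = expand(sigma_day, "sigma_day"),
                 sigma_residual = expand(sigma_residual, "sigma_residual"),
                 n_operators = as.integer(n_operators),
                 n_sessions = as.integer(n_sessions)),
            class = "annotation_noise_model")
}

#' Simulate repeated multi-operator annotations
#'
#' Generates `Y_ijk(l) = true_k(l) + O_i(l) + D_j(l) + eps_ijk(l)` for every
#' portrait k, operator i, session j and landmark l, each effect drawn
#' i.i.d. Normal per coordinate with the model's per-landmark SD. Operator
#' effects are drawn once per (operator, landmark) and shared across
#' portraits and sessions; session effects once per (session, landmark).
#'
#' @param true_landmarks n_portraits x 73 x 3 array of true positions (mm).
#' @param noise an [annotation_noise_model()].
#' @param seed integer seed; equal seeds give identical annotation sets.
#' @return an [annotation_set()].
#' @export
simulate_annotations <- function(true_landmarks, noise, seed = 1L) {
  stopifnot(inherits(noise, "annotation_noise_model"))
  if (length(dim(true_landmarks)) != 3L || dim(true_landmarks)[3] != 3L)
    stop("true_landmarks must be an n x L x 3 array")
  np <- dim(true_landmarks)[1]
  nl <- dim(true_landmarks)[2]
  a <- noise$n_operators
  b <- noise$n_sessions
  coords <- with_seed(seed, {
    O <- array(stats::rnorm(a * nl * 3), c(a, nl, 3)) *
      array(rep(noise$sigma_operator[seq_len(nl)], each = a), c(a, nl, 3))
    D <- array(stats::rnorm(b * nl * 3), c(b, nl, 3)) *
      array(rep(noise$sigma_day[seq_len(nl)], each = b), c(b, nl, 3))
    eps <- array(stats::rnorm(np * a * b * nl * 3), c(np, a, b, nl, 3)) *
      aperm(array(rep(noise$sigma_residual[seq_len(nl)], each = np * a * b),
                  c(np, a, b, nl, 3)), c(1, 2, 3, 4, 5))
    out <- array(NA_real_, c(np, a, b, nl, 3))
    for (i in seq_len(a)) for (j in seq_len(b)) {
      eps_ij <- array(eps[, i, j, , ], c(np, nl, 3))   # robust to np = 1
      out[, i, j, , ] <- true_landmarks + eps_ij +
        aperm(array(O[i, , ] + D[j, , ], c(nl, 3, np)), c(3, 1, 2))
    }
    out
  })
  annotation_set(coords)
}

#' Simulate a full balanced study under the additive effects model
#'
#' Convenience wrapper reproducing the design of a repeated-annotation
#' study: portrait effects `I_k` are drawn per coordinate with SD
#' `sigma_portrait` around a common mean configuration, then operators,
#' sessions and residuals are added via [simulate_annotations()].
#'
#' @param n_portraits number of portraits (faces).
#' @param noise an [annotation_noise_model()].
#' @param sigma_portrait scalar or length-73 SD (mm) of the portrait effect.
#' @param seed integer seed.
#' @param mean_config optional 73 x 3 mean landmark configuration (mm);
#'   defaults to the template's landmark positions.
#' @return list with `true_landmarks` (n x 73 x 3) and `annotations`
#'   (an [annotation_set()]).
#' @export
simulate_study <- function(n_portraits, noise, sigma_portrait = 2,
                           seed = 1L, mean_config = NULL) {
  if (is.null(mean_config)) {
    tpl <- make_template(24)
    mean_config <- tpl$mesh$vertices[tpl$landmarks, ]
  }
  nl <- nrow(mean_config)
  if (length(sigma_portrait) == 1L) sigma_portrait <- rep(sigma_portrait, nl)
  true <- with_seed(seed * 2L + 1L, {
    I <- array(stats::rnorm(n_portraits * nl * 3), c(n_portraits, nl, 3)) *
      array(rep(sigma_portrait, each = n_portraits), c(n_portraits, nl, 3))
    I + aperm(array(mean_config, c(nl, 3, n_portraits)), c(3, 1, 2))
  })
  list(true_landmarks = true,
       annotations = simulate_annotations(true, noise, seed = seed))
}

#' Write a synthetic fixture set to disk
#'
#' Lays out one mesh per portrait (OBJ or PLY), one landmark file per
#' (portrait, operator, session) in the documented `index x y z` format,
#' and a `manifest.csv` tying them together.
#'
#' @param dir output directory (created if missing).
#' @param population output of [sample_population()] (or `NULL` to write
#'   landmark files only).
#' @param annotations an [annotation_set()].
#' @param format mesh format, `"obj"` or `"ply"`.
#' @return the manifest path, invisibly.
#' @export
write_fixture_set <- function(dir, population, annotations, format = c("obj", "ply")) {
  format <- match.arg(format)
  stopifnot(inherits(annotations, "annotation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(annotations$coords)
  np <- dm[1]; a <- dm[2]; b <- dm[3]
  mesh_paths <- rep(NA_character_, np)
  if (!is.null(population)) {
    if (length(population$meshes) != np)
      stop("population has ", length(population$meshes),
           " meshes but annotations cover ", np, " portraits")
    for (k in seq_len(np)) {
      mesh_paths[k] <- file.path(dir, sprintf("portrait_%02d.%s", k, format))
      write_mesh(population$meshes[[k]], mesh_paths[k])
    }
  }
  rows <- list()
  for (k in seq_len(np)) for (i in seq_len(a)) for (j in seq_len(b)) {
    lp <- file.path(dir, sprintf("lm_p%02d_o%02d_s%02d.txt", k, i, j))
    write_landmarks(annotations$coords[k, i, j, , ], lp)
    rows[[length(rows) + 1L]] <- data.frame(
      portrait_id = k, operator_id = i, session_id = j,
      mesh_path = basename(mesh_paths[k]), landmark_path = basename(lp),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a fixture set written by [write_fixture_set()]
#' @param dir fixture directory containing `manifest.csv`.
#' @return list with `annotations` (an [annotation_set()]), `meshes`
#'   (list per portrait, `NULL` entries when no mesh files were written)
#'   and the `manifest` data frame.
#' @export
read_fixture_set <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mp, stringsAsFactors = FALSE)
  np <- max(manifest$portrait_id); a <- max(manifest$operator_id)
  b <- max(manifest$session_id)
  first <- read_landmarks(file.path(dir, manifest$landmark_path[1]))
  nl <- nrow(first)
  coords <- array(NA_real_, c(np, a, b, nl, 3))
  for (r in seq_len(nrow(manifest))) {
    lm <- read_landmarks(file.path(dir, manifest$landmark_path[r]))
    coords[manifest$portrait_id[r], manifest$operator_id[r],
           manifest$session_id[r], , ] <- as.matrix(lm[, c("x", "y", "z")])
  }
  meshes <- vector("list", np)
  for (k in seq_len(np)) {
    f <- manifest$mesh_path[manifest$portrait_id == k][1]
    if (!is.na(f) && nzchar(f) && file.exists(file.path(dir, f)))
      meshes[[k]] <- read_mesh(file.path(dir, f))
  }
  list(annotations = annotation_set(coords), meshes = meshes, manifest = manifest)
}
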