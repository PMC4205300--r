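# Dense template-to-target correspondence: TPS initialization, closest-point
# propagation, and curvature-guided MRF refinement.
#
# The MRF energy over per-vertex displacements d_v (footpoint minus warped
# template vertex) is
#   E = prior_weight * sum_edges ||d_u - d_v||^2
#       + sum_v (H_template(v) - H_target(foot(v)))^2
# with footpoints constrained to the target surface. The prior favours
# smooth deformation fields; the observation term steers vertices towards
# target regions of similar sphere-fit mean curvature. Minimization is a
# seeded stochastic relaxation over discrete per-vertex candidate footpoints.

#' Parameters of the MRF correspondence energy
#'
#' @param prior_weight non-negative trade-off multiplying the smoothness
#'   prior relative to the (unweighted) curvature observation term.
#' @param candidate_count number of discrete footpoint candidates per vertex
#'   (the initial closest point plus the nearest surface samples).
#' @param max_sweeps maximum annealing sweeps over all vertices.
#' @param temp0,cooling initial temperature and geometric cooling factor of
#'   the simulated-annealing acceptance rule.
#' @param pool_factor number of jittered face-interior surface samples per
#'   target vertex in the candidate pool.
#' @param curvature_radius neighborhood radius (mm) for sphere-fit
#'   curvature; default 3 mean edge lengths of the mesh in question.
#' @param seed integer seed for candidate jitter and the stochastic search.
#' @return an `energy_params` list.
#' @export
energy_params <- function(prior_weight = 1, candidate_count = 10L,
                          max_sweeps = 30L, temp0 = 0.1, cooling = 0.8,
                          pool_factor = 2L, curvature_radius = NULL,
                          seed = 1L) {
  if (prior_weight < 0) stop("prior_weight must be >= 0")
  if (candidate_count < 1) stop("candidate_count must be >= 1")
  structure(list(prior_weight = prior_weight,
                 candidate_count = as.integer(candidate_count),
                 max_sweeps = as.integer(max_sweeps),
                 temp0 = temp0, cooling = cooling,
                 pool_factor = as.integer(pool_factor),
                 curvature_radius = curvature_radius,
                 seed = as.integer(seed)),
            class = "energy_params")
}

#' Closest point on a triangle mesh
#'
#' Globally nearest surface point over all triangles for each query point;
#' distance ties are broken by the lowest face index.
#'
#' @param mesh a [surface_mesh()].
#' @param points query point (length-3 vector) or m x 3 matrix.
#' @return data frame with columns `x`, `y`, `z` (footpoint), `face`
#'   (1-based), `b0`, `b1`, `b2` (barycentric coordinates) and `dist` (mm).
#' @export
closest_point <- function(mesh, points) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (n_faces(mesh) == 0) stop("mesh has no faces")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  res <- closest_point_cpp(as.matrix(points), mesh$vertices, mesh$faces - 1L)
  out <- as.data.frame(res)
  names(out) <- c("x", "y", "z", "face", "b0", "b1", "b2", "dist")
  out$face <- as.integer(out$face)
  out
}

# Precompute what mrf_refine needs about a target mesh so it can be shared
# across the replicates of one portrait: vertex curvature, the candidate
# pool of on-surface samples (target vertices + jittered face points) and
# each pool point's interpolated curvature.
#' Precomputed target-side quantities for [mrf_refine()]
#' @param target a [surface_mesh()].
#' @param params an [energy_params()].
#' @return an opaque `target_cache` list; pass via `cache=`.
#' @export
target_cache <- function(target, params = energy_params()) {
  stopifnot(inherits(target, "surface_mesh"))
  rad <- params$curvature_radius
  if (is.null(rad)) rad <- 3 * mean_edge_length(target)
  curv <- mesh_mean_curvature(target, rad)
  nvtx <- n_vertices(target)
  nf <- n_faces(target)
  # vertex part of the pool: each vertex as a corner of one incident face
  vface <- integer(nvtx)
  corner <- integer(nvtx)
  for (k in 1:3) {             # keep (face, corner) assignments in sync
    vface[target$faces[, k]] <- seq_len(nf)
    corner[target$faces[, k]] <- k
  }
  vbary <- matrix(0, nvtx, 3)
  vbary[cbind(seq_len(nvtx), corner)] <- 1
  # jittered interior samples
  ns <- params$pool_factor * nvtx
  jit <- with_seed(params$seed + 7L, {
    f <- sample.int(nf, ns, replace = TRUE)
    u <- stats::runif(ns); v <- stats::runif(ns)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    list(face = f, bary = cbind(1 - u - v, u, v))
  })
  if (any(vface == 0L)) stop("target mesh has isolated vertices")
  pool_face <- c(vface, jit$face)
  pool_bary <- rbind(vbary, jit$bary)
  tri <- target$faces[pool_face, , drop = FALSE]
  pool_xyz <- pool_bary[, 1] * target$vertices[tri[, 1], , drop = FALSE] +
    pool_bary[, 2] * target$vertices[tri[, 2], , drop = FALSE] +
    pool_bary[, 3] * target$vertices[tri[, 3], , drop = FALSE]
  pool_curv <- pool_bary[, 1] * curv[tri[, 1]] +
    pool_bary[, 2] * curv[tri[, 2]] + pool_bary[, 3] * curv[tri[, 3]]
  structure(list(curv = curv, pool_xyz = pool_xyz, pool_face = pool_face,
                 pool_bary = pool_bary, pool_curv = pool_curv, radius = rad),
            class = "target_cache")
}

#' MRF-regularized correspondence refinement
#'
#' Refines the closest-point correspondence from a TPS-warped template to a
#' target surface by minimizing the smoothness-plus-curvature MRF energy
#' with a seeded annealed relaxation over discrete candidate footpoints.
#' The returned field's energy never exceeds the initial closest-point
#' field's energy (the best labelling encountered is kept).
#'
#' @param warped_template a [surface_mesh()], already TPS-warped near the
#'   target.
#' @param target a [surface_mesh()].
#' @param params an [energy_params()].
#' @param cache optional [target_cache()] for `target` (reused across
#'   replicates sharing a target surface).
#' @return a `correspondence_field`: data frame with columns
#'   `template_vertex`, `x`, `y`, `z` (footpoint on the target surface),
#'   `face`, `b0`, `b1`, `b2`, `dx`, `dy`, `dz` (displacement from the
#'   warped template, mm); attributes `energy`, `init_energy`, `trace`,
#'   `params`.
#' @export
mrf_refine <- function(warped_template, target, params = energy_params(),
                       cache = NULL) {
  stopifnot(inherits(warped_template, "surface_mesh"),
            inherits(target, "surface_mesh"))
  if (is.null(cache)) cache <- target_cache(target, params)
  wv <- warped_template$vertices
  nv <- nrow(wv)
  rad_t <- params$curvature_radius
  if (is.null(rad_t)) rad_t <- 3 * mean_edge_length(warped_template)
  h_tpl <- mesh_mean_curvature(warped_template, rad_t)
  if (any(!is.finite(h_tpl)) || any(!is.finite(cache$curv)))
    stop("non-finite curvature encountered; the energy is undefined")

  init <- closest_point(target, wv)
  C <- params$candidate_count
  # candidate 1 is always the closest-point footpoint; the rest are the
  # nearest pool samples to the warped vertex
  cand_xyz <- matrix(NA_real_, nv * C, 3)
  cand_face <- matrix(NA_integer_, nv, C)
  cand_bary <- array(NA_real_, c(nv, C, 3))
  cand_obs <- matrix(NA_real_, nv, C)
  cand_xyz[seq(1, by = C, length.out = nv), ] <- as.matrix(init[, c("x", "y", "z")])
  cand_face[, 1] <- init$face
  cand_bary[, 1, ] <- as.matrix(init[, c("b0", "b1", "b2")])
  tri <- target$faces[init$face, , drop = FALSE]
  h_init <- init$b0 * cache$curv[tri[, 1]] + init$b1 * cache$curv[tri[, 2]] +
    init$b2 * cache$curv[tri[, 3]]
  cand_obs[, 1] <- (h_tpl - h_init)^2
  if (C > 1) {
    nn <- knn_cpp(wv, cache$pool_xyz, C - 1L)
    for (c2 in 2:C) {
      pick <- nn[, c2 - 1L]
      cand_xyz[(seq_len(nv) - 1L) * C + c2, ] <- cache$pool_xyz[pick, , drop = FALSE]
      cand_face[, c2] <- cache$pool_face[pick]
      cand_bary[, c2, ] <- cache$pool_bary[pick, , drop = FALSE]
      cand_obs[, c2] <- (h_tpl - cache$pool_curv[pick])^2
    }
  }
  edges <- mesh_edges(warped_template)
  res <- mrf_sweeps_cpp(cand_xyz, cand_obs, wv, edges - 1L,
                        params$prior_weight,
                        rep(0L, nv),         # 0-based: start at candidate 1
                        params$max_sweeps, params$temp0, params$cooling,
                        params$seed)
  pick <- res$assignment                     # 1-based candidate per vertex
  rows <- (seq_len(nv) - 1L) * C + pick
  foot <- cand_xyz[rows, , drop = FALSE]
  field <- data.frame(template_vertex = seq_len(nv),
                      x = foot[, 1], y = foot[, 2], z = foot[, 3],
                      face = cand_face[cbind(seq_len(nv), pick)],
                      b0 = cand_bary[cbind(seq_len(nv), pick, 1)],
                      b1 = cand_bary[cbind(seq_len(nv), pick, 2)],
                      b2 = cand_bary[cbind(seq_len(nv), pick, 3)],
                      dx = foot[, 1] - wv[, 1],
                      dy = foot[, 2] - wv[, 2],
                      dz = foot[, 3] - wv[, 3])
  class(field) <- c("correspondence_field", "data.frame")
  attr(field, "energy") <- res$energy
  attr(field, "init_energy") <- res$init_energy
  attr(field, "trace") <- res$trace
  attr(field, "params") <- params
  field
}

#' Recompute the MRF energy of a correspondence field
#'
#' Independent R-side evaluation of the smoothness-plus-curvature energy of
#' a field, used to verify the optimizer's bookkeeping.
#'
#' @param field a `correspondence_field`.
#' @param warped_template,target the meshes it was built from.
#' @param params an [energy_params()].
#' @param cache optional [target_cache()].
#' @return scalar energy.
#' @export
field_energy <- function(field, warped_template, target,
                         params = energy_params(), cache = NULL) {
  if (is.null(cache)) cache <- target_cache(target, params)
  rad_t <- params$curvature_radius
  if (is.null(rad_t)) rad_t <- 3 * mean_edge_length(warped_template)
  h_tpl <- mesh_mean_curvature(warped_template, rad_t)
  tri <- target$faces[field$face, , drop = FALSE]
  h_foot <- field$b0 * cache$curv[tri[, 1]] + field$b1 * cache$curv[tri[, 2]] +
    field$b2 * cache$curv[tri[, 3]]
  obs <- sum((h_tpl - h_foot)^2)
  d <- cbind(field$dx, field$dy, field$dz)
  e <- mesh_edges(warped_template)
  prior <- sum((d[e[, 1], ] - d[e[, 2], ])^2)
  params$prior_weight * prior + obs
}

#' Propagate a template mesh onto a target surface
#'
#' The full dense-correspondence pipeline for one target: volumetric TPS
#' warp driven by the sparse landmark pairs, closest-point initialization,
#' and MRF refinement. The output mesh has exactly the template's vertex
#' count and connectivity, with every vertex on the target surface.
#'
#' @param template a [surface_mesh()] (the well-formed template).
#' @param target a [surface_mesh()].
#' @param landmarks_template integer vector of k >= 5 template vertex
#'   indices.
#' @param landmarks_target k x 3 matrix of the corresponding positions on
#'   the target (mm).
#' @param params an [energy_params()].
#' @param cache optional [target_cache()] for `target`.
#' @return list with `mesh` (the dense [surface_mesh()] on the target) and
#'   `field` (the `correspondence_field`).
#' @export
propagate_template <- function(template, target, landmarks_template,
                               landmarks_target, params = energy_params(),
                               cache = NULL) {
  stopifnot(inherits(template, "surface_mesh"), inherits(target, "surface_mesh"))
  landmarks_template <- as.integer(landmarks_template)
  if (length(landmarks_template) < 5)
    stop("at least 5 landmarks are required to drive the warp")
  if (any(landmarks_template < 1 | landmarks_template > n_vertices(template)))
    stop("landmark indices out of range for the template")
  landmarks_target <- as.matrix(landmarks_target)
  if (nrow(landmarks_target) != length(landmarks_template))
    stop("landmark count mismatch between template and target")
  warped <- tps_warp(template$vertices[landmarks_template, , drop = FALSE],
                     landmarks_target, template$vertices)
  wmesh <- surface_mesh(warped, template$faces)
  field <- mrf_refine(wmesh, target, params, cache = cache)
  mesh <- surface_mesh(cbind(field$x, field$y, field$z), template$faces)
  list(mesh = mesh, field = field)
}

#' Select the MRF prior weight by shape-model compactness
#'
#' For each candidate weight, builds dense correspondences for all training
#' shapes, fits a point-distribution model to the resulting vertex sets and
#' evaluates its compactness at `n_modes` modes; the weight whose model is
#' most compact wins. Weights whose model fit fails are excluded with a
#' warning.
#'
#' @param training_shapes list of target [surface_mesh()]es.
#' @param landmarks list of k x 3 landmark matrices, one per shape.
#' @param template a [surface_mesh()].
#' @param landmarks_template template vertex indices for the k landmarks.
#' @param candidate_weights numeric vector of prior weights to try (>= 1
#'   value; >= 2 for a real selection).
#' @param n_modes mode count at which compactness is compared; default
#'   `min(5, n_shapes - 1)`.
#' @param params an [energy_params()]; its `prior_weight` is overridden.
#' @return list with `weight` (selected), `curve` (data frame weight x
#'   compactness) and `models` (fitted PDMs, one per retained weight).
#' @export
choose_prior_weight <- function(training_shapes, landmarks, template,
                                landmarks_template, candidate_weights,
                                n_modes = NULL, params = energy_params()) {
  n <- length(training_shapes)
  if (n < 3) stop("at least 3 training shapes are required")
  if (length(candidate_weights) < 1) stop("no candidate weights given")
  if (is.null(n_modes)) n_modes <- min(5L, n - 1L)
  caches <- lapply(training_shapes, target_cache, params = params)
  comp <- rep(NA_real_, length(candidate_weights))
  models <- vector("list", length(candidate_weights))
  for (w in seq_along(candidate_weights)) {
    p <- params
    p$prior_weight <- candidate_weights[w]
    fit <- tryCatch({
      shapes <- lapply(seq_len(n), function(k)
        propagate_template(template, training_shapes[[k]], landmarks_template,
                           landmarks[[k]], p, cache = caches[[k]])$mesh$vertices)
      ga <- procrustes_align(shapes)
      fit_pdm(ga)
    }, error = function(e) {
      warning("prior weight ", candidate_weights[w], " excluded: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) {
      comp[w] <- compactness(fit, n_modes)
      models[[w]] <- fit
    }
  }
  if (all(is.na(comp))) stop("model fit failed for every candidate weight")
  best <- which.max(comp)
  list(weight = candidate_weights[best],
       curve = data.frame(weight = candidate_weights, compactness = comp),
       models = models)
}

#' Write a correspondence field as CSV
#' @param field a `correspondence_field`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_correspondence_csv <- function(field, path) {
  utils::write.csv(field[, c("template_vertex", "face", "b0", "b1", "b2",
                             "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}
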