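# Evaluation of sparse landmark selections by the quality of the dense
# correspondences they drive: the dense mean point variance (within-portrait
# spread of corresponding points across annotation replicates) and the
# per-landmark prediction error of the full annotated scheme.

#' Dense correspondence set over a balanced replicate grid
#'
#' All meshes share the template's vertex count and connectivity; one mesh
#' per (portrait, operator, session) replicate.
#'
#' @param vertices array `(n_portraits, n_operators, n_sessions, V, 3)` of
#'   dense vertex positions (mm).
#' @param faces the shared face matrix.
#' @param provenance optional list (selection used, prior weight, seed, ...).
#' @return a `dense_correspondence_set`.
#' @export
dense_correspondence_set <- function(vertices, faces, provenance = list()) {
  if (length(dim(vertices)) != 5L || dim(vertices)[5] != 3L)
    stop("vertices must be a (portrait, operator, session, V, 3) array")
  if (anyNA(vertices)) stop("dense correspondence set must be complete")
  structure(list(vertices = vertices, faces = faces, provenance = provenance),
            class = "dense_correspondence_set")
}

#' @export
print.dense_correspondence_set <- function(x, ...) {
  dm <- dim(x$vertices)
  cat(sprintf(
    "dense_correspondence_set: %d portraits x %d operators x %d sessions, %d vertices\n",
    dm[1], dm[2], dm[3], dm[4]))
  invisible(x)
}

#' Dense mean point variance
#'
#' For each dense point, the within-portrait spread is the root mean squared
#' deviation (trace form, mm) of that point across the portrait's
#' operator x session replicates; the per-point value is its mean over
#' portraits, and the scalar summary the mean over points. Because the
#' spread is computed within portrait, population variance cancels and the
#' statistic isolates correspondence inconsistency. Meshes are compared in
#' the common world frame (replicates of one portrait share the same
#' physical surface); set `align = TRUE` to Procrustes-align replicates
#' first for sensitivity analysis.
#'
#' @param set a [dense_correspondence_set()] with >= 2 replicates per
#'   portrait.
#' @param align logical; Procrustes-align the replicates of each portrait
#'   before measuring (default `FALSE`).
#' @return list with `per_point` (numeric, one value per dense point, mm)
#'   and `mean` (scalar, mm).
#' @export
dense_point_variance <- function(set, align = FALSE) {
  stopifnot(inherits(set, "dense_correspondence_set"))
  dm <- dim(set$vertices)
  np <- dm[1]; a <- dm[2]; b <- dm[3]; V <- dm[4]
  r <- a * b
  if (r < 2) stop("dense point variance needs >= 2 replicates per portrait")
  per_point <- matrix(NA_real_, np, V)
  for (k in seq_len(np)) {
    reps <- array(set$vertices[k, , , , ], c(a * b, V, 3))  # collapse (i,j)
    if (align) {
      shapes <- lapply(seq_len(r), function(t) reps[t, , ])
      al <- procrustes_align(shapes)
      for (t in seq_len(r)) reps[t, , ] <- al$aligned[[t]]
    }
    ctr <- apply(reps, c(2, 3), mean)
    d2 <- matrix(0, r, V)
    for (c3 in 1:3)
      d2 <- d2 + (reps[, , c3] - matrix(ctr[, c3], r, V, byrow = TRUE))^2
    per_point[k, ] <- sqrt(colMeans(d2))
  }
  pp <- colMeans(per_point)
  list(per_point = pp, mean = mean(pp))
}

#' Per-landmark prediction error of a dense correspondence
#'
#' For each landmark, the dense meshes' designated vertex predicts the
#' landmark position; per portrait, the mean predicted position over all
#' replicates is compared with the portrait's consensus manual annotation,
#' and errors are averaged over portraits.
#'
#' @param set a [dense_correspondence_set()].
#' @param annotations the matching [annotation_set()].
#' @param template_landmarks integer vector of designated template vertex
#'   indices, one per landmark.
#' @return data frame with columns `landmark` and `prediction_error` (mm).
#' @export
landmark_prediction_error <- function(set, annotations, template_landmarks) {
  stopifnot(inherits(set, "dense_correspondence_set"),
            inherits(annotations, "annotation_set"))
  dm <- dim(set$vertices)
  nl <- length(template_landmarks)
  if (anyNA(template_landmarks) || any(template_landmarks < 1) ||
      any(template_landmarks > dm[4]))
    stop("missing or out-of-range designated template vertex")
  if (dim(annotations$coords)[4] != nl)
    stop("annotation set and template landmark count differ")
  cons <- consensus_positions(annotations)            # (np, nl, 3)
  pred <- set$vertices[, , , template_landmarks, , drop = FALSE]
  pred_mean <- apply(pred, c(1, 4, 5), mean)          # (np, nl, 3)
  err <- sqrt(apply((pred_mean - cons)^2, c(1, 2), sum))
  data.frame(landmark = seq_len(nl), prediction_error = colMeans(err))
}

#' Build dense correspondences for one landmark selection
#'
#' Runs [propagate_template()] for every (portrait, operator, session)
#' replicate, driving the warp with that replicate's annotated positions of
#' the selected landmarks. Per-portrait target quantities (curvature,
#' candidate pool) are computed once and shared across replicates.
#'
#' @param template a `face_template` (mesh + 73 designated vertices).
#' @param targets list of target [surface_mesh()]es, one per portrait.
#' @param annotations an [annotation_set()] over all 73 landmarks.
#' @param selection a `landmark_selection` (or integer indices).
#' @param params an [energy_params()].
#' @return a [dense_correspondence_set()].
#' @export
build_correspondences <- function(template, targets, annotations, selection,
                                  params = energy_params()) {
  stopifnot(inherits(template, "face_template"),
            inherits(annotations, "annotation_set"))
  idx <- if (inherits(selection, "landmark_selection")) selection$indices
         else as.integer(selection)
  dm <- dim(annotations$coords)
  np <- dm[1]; a <- dm[2]; b <- dm[3]
  if (length(targets) != np) stop("one target mesh per portrait is required")
  V <- n_vertices(template$mesh)
  out <- array(NA_real_, c(np, a, b, V, 3))
  lm_tpl <- template$landmarks[idx]
  for (k in seq_len(np)) {
    cache <- target_cache(targets[[k]], params)
    for (i in seq_len(a)) for (j in seq_len(b)) {
      lm_tgt <- annotations$coords[k, i, j, idx, ]
      pr <- propagate_template(template$mesh, targets[[k]], lm_tpl, lm_tgt,
                               params, cache = cache)
      out[k, i, j, , ] <- pr$mesh$vertices
    }
  }
  dense_correspondence_set(out, template$mesh$faces,
                           provenance = list(selection = idx,
                                             prior_weight = params$prior_weight,
                                             seed = params$seed))
}

#' Compare landmark selections by dense mean point variance
#'
#' Runs the full propagate-then-evaluate pipeline for each selection and
#' tabulates the dense mean point variance; optionally also reports the
#' per-landmark prediction error for one chosen selection.
#'
#' @param selections named list of `landmark_selection` objects (or integer
#'   vectors).
#' @param template a `face_template`.
#' @param targets list of portrait meshes.
#' @param annotations an [annotation_set()].
#' @param params an [energy_params()].
#' @param detail_selection optional name (in `selections`) for which the
#'   per-landmark prediction-error listing is produced.
#' @return list with `table` (data frame: selection, n_landmarks,
#'   dense_mean_variance), `per_landmark` (data frame or `NULL`) and
#'   `sets` (the dense correspondence sets).
#' @export
compare_selections <- function(selections, template, targets, annotations,
                               params = energy_params(),
                               detail_selection = NULL) {
  if (length(selections) < 1) stop("at least one selection is required")
  if (is.null(names(selections)))
    names(selections) <- paste0("selection_", seq_along(selections))
  sets <- vector("list", length(selections))
  names(sets) <- names(selections)
  rows <- vector("list", length(selections))
  for (s in seq_along(selections)) {
    sel <- selections[[s]]
    idx <- if (inherits(sel, "landmark_selection")) sel$indices else as.integer(sel)
    sets[[s]] <- build_correspondences(template, targets, annotations, idx,
                                       params)
    dv <- dense_point_variance(sets[[s]])
    rows[[s]] <- data.frame(selection = names(selections)[s],
                            n_landmarks = length(idx),
                            dense_mean_variance = dv$mean,
                            stringsAsFactors = FALSE)
  }
  per_landmark <- NULL
  if (!is.null(detail_selection)) {
    if (!detail_selection %in% names(sets))
      stop("detail_selection '", detail_selection, "' not among selections")
    per_landmark <- landmark_prediction_error(sets[[detail_selection]],
                                              annotations,
                                              template$landmarks)
  }
  list(table = do.call(rbind, rows), per_landmark = per_landmark, sets = sets)
}
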