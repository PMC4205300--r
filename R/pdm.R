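# Point-distribution models: generalized Procrustes alignment, PCA shape
# modes, reconstruction, compactness, and the coupled leave-one-out
# cross-validation comparing single-operator models against models built
# from randomly sampled operators.

#' Generalized Procrustes alignment
#'
#' Aligns a set of point configurations with similarity transforms
#' (translation, rotation, isotropic scale), iterating rotation/scale fits
#' to the running mean until the mean changes by less than `tol` (relative
#' Frobenius norm) or `max_iter` iterations. The scale gauge is fixed by
#' keeping the mean's centroid size equal to the average input centroid
#' size, so aligned coordinates stay in mm.
#'
#' @param shapes list of p x 3 matrices (or a p x 3 x n array), n >= 2,
#'   equal point counts, none degenerate (all points coincident).
#' @param tol convergence tolerance on the relative mean change.
#' @param max_iter maximum number of alignment iterations.
#' @return list with `aligned` (list of p x 3 matrices), `mean` (p x 3),
#'   `iterations`, and `convention` (a descriptive record).
#' @export
procrustes_align <- function(shapes, tol = 1e-9, max_iter = 100L) {
  if (is.array(shapes) && length(dim(shapes)) == 3)
    shapes <- lapply(seq_len(dim(shapes)[3]), function(i) shapes[, , i])
  n <- length(shapes)
  if (n < 2) stop("at least 2 shapes are required")
  p <- nrow(shapes[[1]])
  shapes <- lapply(shapes, function(s) {
    s <- as.matrix(s)
    if (nrow(s) != p || ncol(s) != 3) stop("all shapes must be p x 3 with equal p")
    sweep(s, 2, colMeans(s))
  })
  sizes <- vapply(shapes, function(s) sqrt(sum(s^2)), numeric(1))
  if (any(sizes < 1e-12))
    stop("degenerate shape: all points coincide (zero centroid size)")
  gauge <- mean(sizes)
  M <- shapes[[1]] * (gauge / sizes[1])
  aligned <- shapes
  it <- 0L
  repeat {
    it <- it + 1L
    for (k in seq_len(n)) {
      sim <- .procrustes_fit(shapes[[k]], M)
      aligned[[k]] <- sim$beta * shapes[[k]] %*% sim$R
    }
    Mnew <- Reduce(`+`, aligned) / n
    Mnew <- Mnew * (gauge / sqrt(sum(Mnew^2)))
    delta <- sqrt(sum((Mnew - M)^2)) / gauge
    M <- Mnew
    if (delta < tol || it >= max_iter) break
  }
  # final pass: every aligned shape exactly optimal w.r.t. the returned mean
  for (k in seq_len(n)) {
    sim <- .procrustes_fit(shapes[[k]], M)
    aligned[[k]] <- sim$beta * shapes[[k]] %*% sim$R
  }
  list(aligned = aligned, mean = M, iterations = it,
       convention = list(transform = "similarity", centering = "centroid",
                         gauge = "mean input centroid size", gauge_size = gauge,
                         tol = tol))
}

# optimal rotation R and scale beta minimizing ||beta * X R - M||_F
# (X, M centered); reflection-free.
.procrustes_fit <- function(X, M) {
  s <- svd(crossprod(X, M))
  d <- s$d
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    d[3] <- -d[3]
    R <- u %*% t(s$v)
  }
  beta <- sum(d) / sum(X^2)
  list(R = R, beta = beta)
}

#' Fit a point-distribution model
#'
#' PCA of aligned shapes about their mean: eigen-decomposition of the shape
#' covariance via SVD of the centered, flattened configurations. At most
#' n - 1 modes have non-zero variance; numerically null modes are dropped.
#'
#' @param aligned_shapes either the result of [procrustes_align()] or a
#'   list of p x 3 aligned matrices.
#' @param alignment_target optional p x 3 configuration that the shapes were
#'   aligned to (the Procrustes mean); recorded so that [reconstruct()] can
#'   place new shapes into exactly the training frame. Filled in
#'   automatically when a [procrustes_align()] result is passed.
#' @return a `point_distribution_model`: list with `mean_shape` (p x 3, the
#'   arithmetic mean about which the PCA is taken), `modes` (3p x m matrix,
#'   orthonormal columns, flattened column-major as `as.vector(shape)`),
#'   `mode_variances` (non-increasing, mm^2), `alignment_target` and
#'   `n_training`.
#' @export
fit_pdm <- function(aligned_shapes, alignment_target = NULL) {
  if (is.list(aligned_shapes) && !is.null(aligned_shapes$aligned)) {
    if (is.null(alignment_target)) alignment_target <- aligned_shapes$mean
    aligned_shapes <- aligned_shapes$aligned
  }
  n <- length(aligned_shapes)
  if (n < 2) stop("at least 2 shapes are required")
  p <- nrow(aligned_shapes[[1]])
  X <- t(vapply(aligned_shapes, as.vector, numeric(3 * p)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = 0)
  var <- s$d^2 / (n - 1)
  keep <- which(var > 1e-20 * max(var[1], 1e-20))   # drop numerically null modes
  keep <- keep[keep <= n - 1]
  structure(list(mean_shape = matrix(mu, p, 3),
                 modes = s$v[, keep, drop = FALSE],
                 mode_variances = var[keep],
                 total_variance = sum(var),
                 alignment_target = alignment_target,
                 n_training = n),
            class = "point_distribution_model")
}

#' @export
print.point_distribution_model <- function(x, ...) {
  cat(sprintf("point_distribution_model: %d points, %d modes (n = %d)\n",
              nrow(x$mean_shape), ncol(x$modes), x$n_training))
  if (length(x$mode_variances))
    cat("  mode variances (mm^2):",
        paste(signif(utils::head(x$mode_variances, 5), 3), collapse = ", "),
        if (length(x$mode_variances) > 5) "..." else "", "\n")
  invisible(x)
}

# number of modes explaining at least `frac` of total mode variance
.modes_for_variance <- function(model, frac = 0.95) {
  v <- model$mode_variances
  if (length(v) == 0 || sum(v) == 0) return(0L)
  as.integer(which(cumsum(v) / sum(v) >= frac)[1])
}

#' Reconstruct a shape with a point-distribution model
#'
#' Aligns the shape into the model frame with a similarity fit to the model
#' mean, projects onto the leading modes, and maps the reconstruction back
#' to the shape's original frame. The reported error is the mean Euclidean
#' point-to-point distance in the original frame (mm).
#'
#' @param model a `point_distribution_model`.
#' @param shape p x 3 matrix.
#' @param n_modes number of modes; `NULL` picks the count explaining 95%
#'   of variance; values beyond the available modes are clamped with a
#'   warning.
#' @return list with `reconstruction` (p x 3, original frame), `error`
#'   (mean point distance, mm), `error_rms` (root-mean-square point
#'   distance, mm; non-increasing in `n_modes` by the nesting of the
#'   projections) and `n_modes` used.
#' @export
reconstruct <- function(model, shape, n_modes = NULL) {
  stopifnot(inherits(model, "point_distribution_model"))
  shape <- as.matrix(shape)
  if (is.null(n_modes)) n_modes <- .modes_for_variance(model)
  m_avail <- ncol(model$modes)
  if (n_modes > m_avail) {
    warning("n_modes = ", n_modes, " exceeds the ", m_avail,
            " available modes; clamped")
    n_modes <- m_avail
  }
  centroid <- colMeans(shape)
  Xc <- sweep(shape, 2, centroid)
  target <- if (is.null(model$alignment_target)) model$mean_shape
            else model$alignment_target
  tc <- colMeans(target)                    # model frame need not be centered
  sim <- .procrustes_fit(Xc, sweep(target, 2, tc))
  y <- sweep(sim$beta * Xc %*% sim$R, 2, tc, `+`)
  resid <- as.vector(y) - as.vector(model$mean_shape)
  rec_flat <- as.vector(model$mean_shape)
  if (n_modes > 0) {
    B <- model$modes[, seq_len(n_modes), drop = FALSE]
    rec_flat <- rec_flat + B %*% crossprod(B, resid)
  }
  rec_aligned <- matrix(rec_flat, nrow(shape), 3)
  rec <- sweep(sweep(rec_aligned, 2, tc) %*% t(sim$R) / sim$beta, 2,
               centroid, `+`)
  d2 <- rowSums((rec - shape)^2)
  list(reconstruction = rec, error = mean(sqrt(d2)),
       error_rms = sqrt(mean(d2)), n_modes = n_modes)
}

#' Compactness of a point-distribution model
#'
#' Fraction of total shape variance captured by the first `k` modes; 1 by
#' convention when the total variance is zero.
#'
#' @param model a `point_distribution_model`.
#' @param k number of leading modes (>= 1).
#' @return scalar in `[0, 1]`.
#' @export
compactness <- function(model, k) {
  stopifnot(inherits(model, "point_distribution_model"), k >= 1)
  tot <- model$total_variance
  if (tot <= 0) return(1)
  sum(model$mode_variances[seq_len(min(k, length(model$mode_variances)))]) / tot
}

#' Coupled leave-one-out cross-validation of operator PDMs
#'
#' For every operator o and portrait i, two models are built on the
#' remaining n - 1 portraits: one from operator o's own configurations
#' ("single operator") and one from configurations sampled uniformly across
#' the other operators, one per portrait ("random sampling"). Both
#' reconstruct the held-out portrait's across-operator consensus
#' configuration; per-operator mean errors of both schemes are reported. A
#' systematic per-operator annotation bias inflates the single-operator
#' error, which is what the comparison is designed to expose.
#'
#' @param set an [annotation_set()]; each operator's configuration per
#'   portrait is the session mean.
#' @param n_modes mode count for reconstruction; `NULL` = 95% variance.
#' @param seed integer seed for the random operator sampling.
#' @return list with `table` (data frame: operator, single_error,
#'   random_error), `mean_single`, `mean_random`.
#' @export
coupled_loo_cv <- function(set, n_modes = NULL, seed = 1L) {
  stopifnot(inherits(set, "annotation_set"))
  dm <- dim(set$coords)
  np <- dm[1]; a <- dm[2]; nl <- dm[4]
  if (a < 2 || np < 3)
    stop("coupled LOO needs >= 2 operators and >= 3 portraits")
  config <- apply(set$coords, c(1, 2, 4, 5), mean)   # session mean: (k, i, l, 3)
  consensus <- apply(config, c(1, 3, 4), mean)       # (k, l, 3)
  # one random donor operator per (outer operator, held-out portrait,
  # training portrait), drawn up front so the whole scheme is seeded
  donors <- with_seed(seed, array(sample.int(a - 1L, a * np * np, replace = TRUE),
                                  c(a, np, np)))
  err_s <- matrix(NA_real_, a, np)
  err_r <- matrix(NA_real_, a, np)
  for (o in seq_len(a)) {
    others <- setdiff(seq_len(a), o)
    for (i in seq_len(np)) {
      train <- setdiff(seq_len(np), i)
      shapes_s <- lapply(train, function(k) config[k, o, , ])
      shapes_r <- lapply(seq_along(train), function(t)
        config[train[t], others[donors[o, i, t]], , ])
      target <- consensus[i, , ]
      fit_s <- fit_pdm(procrustes_align(shapes_s))
      fit_r <- fit_pdm(procrustes_align(shapes_r))
      err_s[o, i] <- reconstruct(fit_s, target, n_modes)$error
      err_r[o, i] <- reconstruct(fit_r, target, n_modes)$error
    }
  }
  tab <- data.frame(operator = seq_len(a),
                    single_error = rowMeans(err_s),
                    random_error = rowMeans(err_r))
  list(table = tab, mean_single = mean(err_s), mean_random = mean(err_r))
}

#' Serialize / load a point-distribution model as plain text
#'
#' A YAML header (counts, variances, alignment convention) plus CSV arrays
#' for the mean shape and modes -- a binary-free container.
#'
#' @param model a `point_distribution_model`.
#' @param path directory to write into (created if missing).
#' @return `path` (for `write_pdm`), the model (for `read_pdm`).
#' @export
write_pdm <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(n_points = nrow(model$mean_shape),
                        n_modes = ncol(model$modes),
                        n_training = model$n_training),
                   file.path(path, "model.yaml"))
  # variances go through CSV to keep full double precision
  utils::write.csv(data.frame(mode_variance = model$mode_variances),
                   file.path(path, "variances.csv"), row.names = FALSE)
  writeLines(format(model$total_variance, digits = 17),
             file.path(path, "total_variance.txt"))
  utils::write.csv(as.data.frame(model$mean_shape),
                   file.path(path, "mean_shape.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$modes),
                   file.path(path, "modes.csv"), row.names = FALSE)
  if (!is.null(model$alignment_target))
    utils::write.csv(as.data.frame(model$alignment_target),
                     file.path(path, "alignment_target.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pdm
#' @export
read_pdm <- function(path) {
  hdr <- yaml::read_yaml(file.path(path, "model.yaml"))
  mean_shape <- as.matrix(utils::read.csv(file.path(path, "mean_shape.csv")))
  modes <- as.matrix(utils::read.csv(file.path(path, "modes.csv")))
  dimnames(mean_shape) <- NULL; dimnames(modes) <- NULL
  at <- NULL
  at_path <- file.path(path, "alignment_target.csv")
  if (file.exists(at_path)) {
    at <- as.matrix(utils::read.csv(at_path))
    dimnames(at) <- NULL
  }
  vars <- utils::read.csv(file.path(path, "variances.csv"))$mode_variance
  tot <- as.numeric(readLines(file.path(path, "total_variance.txt")))
  structure(list(mean_shape = mean_shape, modes = modes,
                 alignment_target = at,
                 mode_variances = as.numeric(vars),
                 total_variance = tot,
                 n_training = hdr$n_training),
            class = "point_distribution_model")
}
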