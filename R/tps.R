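#' Volumetric thin-plate spline warp
#'
#' Fits the 3D thin-plate spline interpolant with kernel `U(r) = r` (the
#' biharmonic radial basis in three dimensions) plus an affine part, mapping
#' each source landmark exactly onto its paired target landmark, and
#' evaluates the warp at arbitrary query points. This is the initial
#' template deformation of the dense-correspondence pipeline.
#'
#' @param source_landmarks n x 3 matrix of source positions (mm), n >= 5,
#'   not coplanar.
#' @param target_landmarks n x 3 matrix of paired target positions.
#' @param query_points m x 3 matrix of points to warp.
#' @param lambda optional non-negative regularization added to the kernel
#'   diagonal; 0 (default) gives exact interpolation.
#' @return m x 3 matrix of warped query points.
#' @export
tps_warp <- function(source_landmarks, target_landmarks, query_points,
                     lambda = 0) {
  src <- as.matrix(source_landmarks); tgt <- as.matrix(target_landmarks)
  q <- as.matrix(query_points)
  if (ncol(src) != 3 || ncol(tgt) != 3 || ncol(q) != 3)
    stop("all inputs must have 3 columns")
  n <- nrow(src)
  if (nrow(tgt) != n) stop("source and target landmark counts differ")
  if (n < 5) stop("at least 5 landmark pairs are required")
  P <- cbind(1, src)
  if (qr(P)$rank < 4)
    stop("degenerate landmark configuration: source landmarks are coplanar ",
         "(affine part rank ", qr(P)$rank, " < 4)")
  K <- .pairwise_dist(src, src)           # U(r) = r
  if (lambda > 0) K <- K + diag(lambda, n)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgt, matrix(0, 4, 3))
  coef <- tryCatch(solve(A, rhs), error = function(e)
    stop("thin-plate spline system is singular: ", conditionMessage(e)))
  W <- coef[seq_len(n), , drop = FALSE]
  Aff <- coef[n + 1:4, , drop = FALSE]
  U <- .pairwise_dist(q, src)
  U %*% W + cbind(1, q) %*% Aff
}

# Euclidean distance matrix between row sets (m x n)
.pairwise_dist <- function(x, y) {
  m <- nrow(x); n <- nrow(y)
  d2 <- matrix(rowSums(x^2), m, n) + matrix(rowSums(y^2), m, n, byrow = TRUE) -
    2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}
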