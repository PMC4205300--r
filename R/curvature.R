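# Mean curvature from a locally fitted sphere.
#
# The curvature magnitude at a vertex is 1/R of the least-squares sphere
# through the vertices within a given Euclidean radius; the sign is positive
# where the surface is convex with respect to the outward normal (the sphere
# center lies on the opposite side of the normal).

#' Sphere-fit mean curvature at one vertex
#'
#' @param mesh a [surface_mesh()].
#' @param vertex vertex index (1-based).
#' @param neighborhood_radius inclusion radius in mm; the neighborhood must
#'   contain at least 4 non-coplanar vertices. Defaults to 3 mean edge
#'   lengths.
#' @param normals optional precomputed [vertex_normals()].
#' @return signed curvature in 1/mm (0 in the planar limit).
#' @export
mean_curvature <- function(mesh, vertex, neighborhood_radius = NULL,
                           normals = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(neighborhood_radius)) neighborhood_radius <- 3 * mean_edge_length(mesh)
  if (is.null(normals)) normals <- vertex_normals(mesh)
  v <- mesh$vertices
  p <- v[vertex, ]
  d2 <- rowSums((v - matrix(p, nrow(v), 3, byrow = TRUE))^2)
  nb <- which(d2 <= neighborhood_radius^2)
  .sphere_fit_curvature(v[nb, , drop = FALSE], p, normals[vertex, ],
                        neighborhood_radius)
}

#' Sphere-fit mean curvature at every vertex
#'
#' Vectorized driver for [mean_curvature()]; neighborhoods are gathered with
#' a chunked distance computation so meshes of a few thousand vertices stay
#' cheap.
#'
#' @inheritParams mean_curvature
#' @return numeric vector of signed curvatures (1/mm), one per vertex.
#' @export
mesh_mean_curvature <- function(mesh, neighborhood_radius = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(neighborhood_radius)) neighborhood_radius <- 3 * mean_edge_length(mesh)
  normals <- vertex_normals(mesh)
  v <- mesh$vertices
  n <- nrow(v)
  out <- numeric(n)
  r2 <- neighborhood_radius^2
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- .pairwise_dist(v[idx, , drop = FALSE], v)^2
    for (ii in seq_along(idx)) {
      nb <- which(d2[ii, ] <= r2)
      out[idx[ii]] <- .sphere_fit_curvature(v[nb, , drop = FALSE],
                                            v[idx[ii], ], normals[idx[ii], ],
                                            neighborhood_radius)
    }
  }
  out
}

# least-squares sphere through pts; signed curvature w.r.t. outward normal
.sphere_fit_curvature <- function(pts, p, normal, radius) {
  if (nrow(pts) < 4)
    stop("curvature neighborhood has only ", nrow(pts),
         " vertices; increase neighborhood_radius (", signif(radius, 4), " mm)")
  ctr <- scale(pts, center = TRUE, scale = FALSE)
  if (qr(ctr, tol = 1e-10)$rank < 3) {
    # exactly coplanar neighborhood: planar limit
    return(0)
  }
  # ||x||^2 = 2 c.x + (r^2 - ||c||^2): linear in (c, k)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  cen <- sol[1:3]
  r2 <- sol[4] + sum(cen^2)
  if (!is.finite(r2) || r2 <= 0) return(0)
  r <- sqrt(r2)
  if (r > 1e6) return(0)   # numerically planar
  side <- sum((cen - p) * normal)
  kappa <- 1 / r
  if (side > 0) -kappa else kappa
}
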