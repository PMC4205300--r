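# Shared fixtures and independent oracles, all built in code at test time.

# regular grid surface z = f(x, y) on [0, L]^2 with n subdivisions per axis
grid_mesh <- function(f, n = 20, L = 40) {
  xs <- seq(0, L, length.out = n + 1)
  g <- expand.grid(x = xs, y = xs)
  z <- f(g$x, g$y)
  nx <- n + 1L
  ix <- rep(seq_len(n), n)
  iy <- rep(seq_len(n), each = n)
  a <- (iy - 1L) * nx + ix
  b <- a + 1L
  cc <- a + nx
  d <- cc + 1L
  surface_mesh(cbind(g$x, g$y, z), rbind(cbind(a, b, d), cbind(a, d, cc)))
}

plane_mesh <- function(n = 20, L = 40) grid_mesh(function(x, y) 0 * x, n, L)

# single Gaussian bump, apex height A at (cx, cy)
bump_mesh <- function(cx, cy, n = 40, L = 40, A = 8, sig = 3) {
  grid_mesh(function(x, y) A * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sig^2)),
            n, L)
}

# tessellated sphere of radius R (poles trimmed), outward winding
sphere_mesh <- function(R, n = 40) {
  th <- seq(0.15 * pi, 0.85 * pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-1]
  g <- expand.grid(th = th, ph = ph)
  v <- R * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  idx <- matrix(seq_len(n * 2 * n), n, 2 * n)
  fs <- NULL
  for (j in seq_len(2 * n)) {
    jn <- if (j == 2 * n) 1 else j + 1
    a <- idx[-n, j]; b <- idx[-1, j]; cc <- idx[-1, jn]; d <- idx[-n, jn]
    fs <- rbind(fs, cbind(a, b, cc), cbind(a, cc, d))
  }
  surface_mesh(v, fs)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force closest point on a mesh: R-side scan over every triangle
# using an independent point-to-triangle solve (constrained barycentric
# minimization by direct enumeration of the KKT cases via quadratic fit)
brute_closest_point <- function(mesh, p) {
  best <- Inf
  bp <- NULL
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    # minimize ||a + u e1 + v e2 - p||^2 over the triangle
    e1 <- tri[2, ] - tri[1, ]
    e2 <- tri[3, ] - tri[1, ]
    w <- p - tri[1, ]
    G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
    rhs <- c(sum(e1 * w), sum(e2 * w))
    uv <- tryCatch(solve(G, rhs), error = function(e) c(0, 0))
    u <- uv[1]; v <- uv[2]
    if (!(u >= 0 && v >= 0 && u + v <= 1)) {
      # project onto each edge segment and take the best
      cand <- list()
      seg <- function(a, b) {
        t <- sum((p - a) * (b - a)) / sum((b - a)^2)
        t <- min(max(t, 0), 1)
        a + t * (b - a)
      }
      cand[[1]] <- seg(tri[1, ], tri[2, ])
      cand[[2]] <- seg(tri[1, ], tri[3, ])
      cand[[3]] <- seg(tri[2, ], tri[3, ])
      d <- vapply(cand, function(q) sum((q - p)^2), numeric(1))
      q <- cand[[which.min(d)]]
    } else {
      q <- tri[1, ] + u * e1 + v * e2
    }
    d2 <- sum((q - p)^2)
    if (d2 < best) {
      best <- d2
      bp <- q
    }
  }
  list(point = bp, dist = sqrt(best))
}

# MIVQUE0 / quadratic-form oracle for the additive three-way random model on
# a (portrait, operator, session) array: builds the balanced-ANOVA quadratic
# forms from explicit projection matrices and solves the expected-SS linear
# system numerically. Fully independent of the closed-form EMS estimator.
vc_oracle <- function(y) {
  np <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  n <- np * a * b
  O <- factor(rep(seq_len(a), each = np, times = b))
  D <- factor(rep(seq_len(b), each = np * a))
  I <- factor(rep(seq_len(np), times = a * b))
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  P1 <- matrix(1 / n, n, n)
  PO <- proj(stats::model.matrix(~ O - 1)) - P1
  PD <- proj(stats::model.matrix(~ D - 1)) - P1
  PI <- proj(stats::model.matrix(~ I - 1)) - P1
  PE <- diag(n) - P1 - PO - PD - PI
  ZO <- stats::model.matrix(~ O - 1)
  ZD <- stats::model.matrix(~ D - 1)
  ZI <- stats::model.matrix(~ I - 1)
  As <- list(PO, PD, PI, PE)
  Vs <- list(tcrossprod(ZO), tcrossprod(ZD), tcrossprod(ZI), diag(n))
  M <- matrix(0, 4, 4)
  for (q in 1:4) for (cc in 1:4) M[q, cc] <- sum(As[[q]] * Vs[[cc]])
  yy <- as.vector(y)
  ss <- vapply(As, function(A) drop(crossprod(yy, A %*% yy)), numeric(1))
  drop(solve(M, ss))   # (sigma2_O, sigma2_D, sigma2_I, sigma2_eps)
}

# Monte-Carlo expectation of the mean distance-to-replicate-mean for r
# isotropic 3D Gaussian replicates with per-coordinate SD sigma
mc_mean_error <- function(r, sigma = 1, n_draws = 1e5, seed = 404) {
  set.seed(seed)
  x <- array(stats::rnorm(n_draws * r * 3, sd = sigma), c(n_draws, r, 3))
  ctr <- apply(x, c(1, 3), mean)
  d <- sqrt((x[, , 1] - ctr[, 1])^2 + (x[, , 2] - ctr[, 2])^2 +
              (x[, , 3] - ctr[, 3])^2)
  mean(d)
}

# small synthetic study shared by several tests
small_study <- function(n_portraits = 4, n_operators = 3, n_sessions = 2,
                        sigma = c(1, 0.3, 0.5), sigma_portrait = 2,
                        seed = 1) {
  noise <- annotation_noise_model(sigma[1], sigma[2], sigma[3],
                                  n_operators = n_operators,
                                  n_sessions = n_sessions)
  simulate_study(n_portraits, noise, sigma_portrait = sigma_portrait,
                 seed = seed)
}
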