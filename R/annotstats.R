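# Per-landmark error summaries and the variance-component decomposition of a
# balanced operator x session x portrait annotation design.
#
# Model: Y_ijk = mu + O_i + D_j + I_k + eps_ijk, all effects random, fitted
# per coordinate axis by the balanced-design expected-mean-squares (ANOVA)
# estimator, which coincides with MIVQUE0 for balanced complete data. The
# per-landmark component in mm^2 is the sum over the three coordinate axes
# (the trace of the 3D component covariance), a rotation-invariant quantity.

#' Consensus landmark positions
#'
#' Arithmetic mean of each (portrait, landmark) position over all
#' operator x session replicates: the "mean annotation points for all
#' operators" used as the reconstruction target and reference elsewhere.
#'
#' @param set an [annotation_set()].
#' @return array `(n_portraits, n_landmarks, 3)` of mean positions (mm).
#' @export
consensus_positions <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  apply(set$coords, c(1, 4, 5), mean)
}

#' Per-landmark annotation error summary
#'
#' For every annotation, the error is its Euclidean distance (mm) to the
#' consensus position of the same portrait and landmark. Per landmark,
#' `mean_error` is the grand mean of these distances over all portraits,
#' operators and sessions and `sd_error` their pooled standard deviation --
#' the "combined variance" summary of a repeated-annotation study.
#'
#' @param set an [annotation_set()] with at least 2 replicates per portrait.
#' @return data frame with columns `landmark`, `mean_error`, `sd_error`.
#' @export
error_summary <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  dm <- dim(set$coords)
  if (dm[2] * dm[3] < 2)
    stop("error_summary needs at least 2 replicates (operators x sessions) ",
         "per portrait")
  cons <- consensus_positions(set)                  # (np, nl, 3)
  np <- dm[1]; a <- dm[2]; b <- dm[3]; nl <- dm[4]
  d2 <- array(0, c(np, a, b, nl))
  for (c3 in 1:3) {
    obs <- array(set$coords[, , , , c3, drop = FALSE], c(np, a, b, nl))
    dev <- obs - aperm(array(cons[, , c3], c(np, nl, a, b)), c(1, 3, 4, 2))
    d2 <- d2 + dev^2
  }
  dist <- sqrt(d2)
  data.frame(landmark = seq_len(nl),
             mean_error = apply(dist, 4, mean),
             sd_error = apply(dist, 4, stats::sd))
}

#' Variance-component decomposition of annotation variability
#'
#' Decomposes per-landmark annotation variance into operator, session-day,
#' portrait and residual components under the additive random-effects model
#' `Y_ijk = mu + O_i + D_j + I_k + eps_ijk`, estimated per coordinate axis by
#' the balanced-design expected-mean-squares equations and summed over the
#' three axes. For a balanced complete design this estimator is identical to
#' MIVQUE0. Negative component estimates are truncated to zero and flagged.
#'
#' @param set an [annotation_set()] with at least 2 operators, 2 sessions
#'   and 2 portraits, balanced and complete.
#' @param landmark optional single landmark index; default all landmarks.
#' @return data frame with columns `landmark`, `var_operator`, `var_day`,
#'   `var_portrait`, `var_residual` (mm^2, summed over x/y/z), `truncated`
#'   (logical: any component clipped at zero), plus attribute
#'   `"grand_mean"` (n_landmarks x 3).
#' @export
fit_variance_components <- function(set, landmark = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  dm <- dim(set$coords)
  np <- dm[1]; a <- dm[2]; b <- dm[3]; nl <- dm[4]
  if (a < 2 || b < 2 || np < 2)
    stop("variance decomposition needs a balanced complete design with ",
         ">= 2 operators, >= 2 sessions and >= 2 portraits")
  lms <- if (is.null(landmark)) seq_len(nl) else as.integer(landmark)
  if (any(lms < 1 | lms > nl)) stop("landmark index out of range")
  out <- data.frame(landmark = lms, var_operator = 0, var_day = 0,
                    var_portrait = 0, var_residual = 0, truncated = FALSE)
  gm <- matrix(NA_real_, length(lms), 3)
  for (r in seq_along(lms)) {
    l <- lms[r]
    raw <- c(0, 0, 0, 0)
    for (c3 in 1:3) {
      y <- set$coords[, , , l, c3]                  # (np, a, b): k, i, j
      raw <- raw + .ems_components(y)
      gm[r, c3] <- mean(y)
    }
    trunc <- raw < 0
    est <- pmax(raw, 0)
    out$var_operator[r] <- est[1]
    out$var_day[r] <- est[2]
    out$var_portrait[r] <- est[3]
    out$var_residual[r] <- est[4]
    out$truncated[r] <- any(trunc)
  }
  attr(out, "grand_mean") <- gm
  out
}

# EMS estimator for the additive 3-way crossed random model with one
# observation per cell; y is (portrait k, operator i, session j).
# Returns c(sigma2_O, sigma2_D, sigma2_I, sigma2_eps), untruncated.
.ems_components <- function(y) {
  np <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  gbar <- mean(y)
  ybar_i <- apply(y, 2, mean)       # operator means
  ybar_j <- apply(y, 3, mean)       # session means
  ybar_k <- apply(y, 1, mean)       # portrait means
  ms_o <- np * b * sum((ybar_i - gbar)^2) / (a - 1)
  ms_d <- np * a * sum((ybar_j - gbar)^2) / (b - 1)
  ms_i <- a * b * sum((ybar_k - gbar)^2) / (np - 1)
  fit <- array(ybar_k, c(np, a, b)) +
    array(rep(ybar_i, each = np), c(np, a, b)) +
    array(rep(ybar_j, each = np * a), c(np, a, b)) - 2 * gbar
  ss_e <- sum((y - fit)^2)
  df_e <- np * a * b - np - a - b + 2
  ms_e <- ss_e / df_e
  c((ms_o - ms_e) / (np * b),
    (ms_d - ms_e) / (np * a),
    (ms_i - ms_e) / (a * b),
    ms_e)
}

#' Check for two-way interaction structure
#'
#' Fits the model with all two-way interaction terms
#' (operator:session, operator:portrait, session:portrait) per coordinate
#' axis and reports each interaction's mean square relative to the residual
#' mean square (sums of squares pooled over x/y/z). Interactions are flagged
#' negligible when no ratio exceeds `threshold` -- the operational version of
#' rejecting the interaction model because it "does not contribute further
#' explanation".
#'
#' @param set an [annotation_set()], balanced with all factors >= 2 levels.
#' @param landmark single landmark index.
#' @param threshold flag interactions non-negligible when any
#'   `MS_interaction / MS_residual` exceeds this (default 2).
#' @return list with `table` (data frame: term, ss, df, ms, ratio) and
#'   `negligible` (logical).
#' @export
interaction_check <- function(set, landmark, threshold = 2) {
  stopifnot(inherits(set, "annotation_set"), length(landmark) == 1L)
  dm <- dim(set$coords)
  np <- dm[1]; a <- dm[2]; b <- dm[3]
  if (a < 2 || b < 2 || np < 2)
    stop("interaction check needs >= 2 levels of every factor")
  O <- factor(rep(seq_len(a), each = np, times = b))
  D <- factor(rep(seq_len(b), each = np * a))
  I <- factor(rep(seq_len(np), times = a * b))
  terms <- c("O", "D", "I", "O:D", "O:I", "D:I", "Residuals")
  ss <- setNames(numeric(7), terms)
  df <- setNames(numeric(7), terms)
  for (c3 in 1:3) {
    y <- as.vector(set$coords[, , , landmark, c3])   # (k,i,j) order
    # only sums of squares are used, so the F-test warning on a perfect
    # (zero-residual) fit is irrelevant here
    an <- suppressWarnings(stats::anova(stats::lm(y ~ O + D + I + O:D + O:I + D:I)))
    rn <- rownames(an)
    for (t in terms) {
      row <- match(t, rn)
      if (!is.na(row)) {
        ss[t] <- ss[t] + an[row, "Sum Sq"]
        df[t] <- an[row, "Df"]
      }
    }
  }
  ms <- ifelse(df > 0, ss / df, 0)
  ms_res <- ms[["Residuals"]]
  inter <- c("O:D", "O:I", "D:I")
  ratio <- setNames(rep(0, 7), terms)
  if (ms_res > 0) ratio[inter] <- ms[inter] / ms_res
  tab <- data.frame(term = terms, ss = unname(ss), df = unname(df),
                    ms = unname(ms), ratio = unname(ratio))
  list(table = tab, negligible = all(ratio[inter] <= threshold))
}

#' Export annotation-variability tables
#'
#' Writes the [error_summary()] and [fit_variance_components()] tables as
#' CSV keyed by landmark index.
#'
#' @param set an [annotation_set()].
#' @param dir output directory.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_annotation_reports <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  es <- file.path(dir, "error_summary.csv")
  vc <- file.path(dir, "variance_components.csv")
  utils::write.csv(error_summary(set), es, row.names = FALSE)
  utils::write.csv(fit_variance_components(set), vc, row.names = FALSE)
  invisible(c(error_summary = es, variance_components = vc))
}
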