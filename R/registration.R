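#' Labeled fiducial point set
#'
#' A fiducial set is an ordered collection of labeled 3-D marker
#' positions (mm) expressed in one named coordinate space. It is the
#' input to point-to-point registration: the seven markers on the patient
#' reference frame, the metallic test beads, or lesion centroids.
#'
#' At least 3 non-collinear points are required (collinearity is judged
#' from the singular values of the centered point matrix), and labels
#' must be unique.
#'
#' @param labels character vector of unique marker identifiers.
#' @param points n x 3 matrix of positions (mm).
#' @param space the coordinate space the positions are expressed in.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(labels, points, space = "IMAGE") {
  points <- .as_point_matrix(points)
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) {
    stop("need one label per point", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("fiducial labels must be unique", call. = FALSE)
  if (nrow(points) < 3L) stop("a fiducial set needs at least 3 points",
                              call. = FALSE)
  sv <- svd(scale(points, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300)) {
    stop("degenerate fiducial configuration: points are collinear",
         call. = FALSE)
  }
  rownames(points) <- labels
  colnames(points) <- c("x_mm", "y_mm", "z_mm")
  structure(list(labels = labels, points = points,
                 space = .check_space(space)),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("Fiducial set:", nrow(x$points), "markers in", x$space, "space\n")
  print(round(x$points, 3))
  invisible(x)
}

#' @export
as.data.frame.fiducial_set <- function(x, ...) {
  data.frame(label = x$labels,
             x_mm = x$points[, 1], y_mm = x$points[, 2], z_mm = x$points[, 3],
             space = x$space, row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write fiducial sets as CSV
#'
#' The CSV dialect has a mandatory header `label,x_mm,y_mm,z_mm,space`,
#' comma separation and '.' decimals; one row per marker.
#'
#' @param path CSV file path.
#' @return `read_fiducial_csv`: a `fiducial_set`.
#' @export
read_fiducial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("label", "x_mm", "y_mm", "z_mm", "space")
  if (!all(need %in% names(df))) {
    stop("fiducial CSV must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  space <- unique(df$space)
  if (length(space) != 1L) stop("fiducial CSV mixes coordinate spaces",
                                call. = FALSE)
  fiducial_set(df$label, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), space)
}

#' @rdname read_fiducial_csv
#' @param fs a `fiducial_set`.
#' @export
write_fiducial_csv <- function(fs, path) {
  stopifnot(inherits(fs, "fiducial_set"))
  utils::write.csv(as.data.frame(fs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Core least-squares rigid fit (Kabsch/Umeyama, rotation-only scale).
## X, Y: n x 3 matrices of corresponding points; returns R, t minimizing
## sum || R x_i + t - y_i ||^2, with reflection correction via sign of det.
.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- crossprod(Xc, Yc)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cy - R %*% cx))
}

#' Point-to-point rigid registration of two fiducial sets
#'
#' Fits the rigid transform that maps the `source` fiducials onto the
#' `target` fiducials in the least-squares sense (Kabsch/Umeyama SVD
#' solution with reflection correction), with correspondence established
#' by label. The fiducial registration error (FRE) is the root mean
#' square of the per-fiducial residual distances after the fit.
#'
#' The returned object is a fitted model: use [coef()], [predict()],
#' [residuals()], [fitted()], [summary()] and [simulate()] on it.
#'
#' @param source,target `fiducial_set` objects carrying the same labels
#'   (order may differ; points are matched by label).
#' @return An object of class `rigid_registration` with components
#'   `transform` (a [rigid_transform] from `source$space` to
#'   `target$space`), `fre_mm`, `per_fiducial_residuals_mm`, and the
#'   matched input sets.
#' @examples
#' src <- fiducial_set(letters[1:4],
#'                     rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10)),
#'                     "IMAGE")
#' tgt <- fiducial_set(letters[1:4],
#'                     transform_points(rigid_transform(rotation_about("z", 30),
#'                                                      c(5, -2, 1),
#'                                                      "IMAGE", "PATIENT_FRAME"),
#'                                      src$points),
#'                     "PATIENT_FRAME")
#' fit <- register_fiducials(src, tgt)
#' fit$fre_mm   # ~0: noise-free correspondence
#' @export
register_fiducials <- function(source, target) {
  stopifnot(inherits(source, "fiducial_set"), inherits(target, "fiducial_set"))
  if (!setequal(source$labels, target$labels) ||
      length(source$labels) != length(target$labels)) {
    stop("label mismatch: source and target fiducial sets must carry ",
         "the same labels", call. = FALSE)
  }
  ord <- match(source$labels, target$labels)
  X <- source$points
  Y <- target$points[ord, , drop = FALSE]
  fit <- .kabsch(X, Y)
  tr <- rigid_transform(fit$R, fit$t, source$space, target$space)
  res_vec <- transform_points(tr, X) - Y
  res <- sqrt(rowSums(res_vec^2))
  structure(list(transform = tr,
                 fre_mm = sqrt(mean(res^2)),
                 per_fiducial_residuals_mm = stats::setNames(res, source$labels),
                 residual_vectors_mm = res_vec,
                 source = source, target = target,
                 n_fiducials = nrow(X)),
            class = "rigid_registration")
}

#' @export
print.rigid_registration <- function(x, digits = 4, ...) {
  cat("Rigid point-to-point registration (", x$source$space, " -> ",
      x$target$space, ")\n", sep = "")
  cat("  fiducials:", x$n_fiducials,
      " FRE:", format(round(x$fre_mm, digits)), "mm\n")
  invisible(x)
}

#' @export
summary.rigid_registration <- function(object, ...) {
  structure(list(fit = object,
                 rotation_angle_deg = rotation_angle_deg(object$transform$rotation),
                 translation_norm_mm = sqrt(sum(object$transform$translation^2)),
                 fle_est_mm = estimate_fle_from_fre(object$fre_mm,
                                                    object$n_fiducials)),
            class = "summary.rigid_registration")
}

#' @export
print.summary.rigid_registration <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  rotation %.3f deg, translation %.3f mm\n",
              x$rotation_angle_deg, x$translation_norm_mm))
  cat(sprintf("  FLE estimated from FRE: %.4f mm\n", x$fle_est_mm))
  cat("  per-fiducial residuals (mm):\n")
  print(round(x$fit$per_fiducial_residuals_mm, digits))
  invisible(x)
}

#' @export
coef.rigid_registration <- function(object, ...) {
  tr <- object$transform
  ang <- rotation_angle_deg(tr$rotation)
  ## rotation as scaled axis-angle (degrees); axis undefined at 0 deg
  R <- tr$rotation
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nx <- sqrt(sum(ax^2))
  ax <- if (nx > 1e-12) ax / nx * ang else c(0, 0, 0)
  c(tx_mm = tr$translation[1], ty_mm = tr$translation[2],
    tz_mm = tr$translation[3],
    rx_deg = ax[1], ry_deg = ax[2], rz_deg = ax[3])
}

#' @export
fitted.rigid_registration <- function(object, ...) {
  transform_points(object$transform, object$source$points)
}

#' @export
residuals.rigid_registration <- function(object, type = c("norm", "vector"),
                                         ...) {
  type <- match.arg(type)
  if (type == "norm") object$per_fiducial_residuals_mm
  else object$residual_vectors_mm
}

#' Map new points through a fitted registration
#' @param object a `rigid_registration`.
#' @param newdata a length-3 vector, n x 3 matrix or `fiducial_set` in the
#'   registration's source space; defaults to the source fiducials.
#' @param ... unused.
#' @return n x 3 matrix of mapped points in the target space.
#' @export
predict.rigid_registration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (inherits(newdata, "fiducial_set")) newdata <- newdata$points
  transform_points(object$transform, newdata)
}

#' @export
plot.rigid_registration <- function(x, ...) {
  res <- x$per_fiducial_residuals_mm
  graphics::barplot(res, ylab = "residual (mm)", xlab = "fiducial",
                    main = sprintf("FRE %.3f mm", x$fre_mm), ...)
  graphics::abline(h = x$fre_mm, lty = 2)
  invisible(x)
}

#' Simulate registration replicates from a fitted registration
#'
#' Draws `nsim` noisy re-registrations of the fitted configuration, with
#' isotropic Gaussian fiducial localization noise calibrated from the
#' fit's own FRE (or an explicit `fle_mm`), and returns the simulated FRE
#' values. This is the Monte-Carlo engine behind FRE/FLE consistency
#' checks.
#'
#' @param object a `rigid_registration`.
#' @param nsim number of replicates.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param fle_mm fiducial localization error to simulate with; default
#'   calibrates it from the fitted FRE via [estimate_fle_from_fre()].
#' @param ... unused.
#' @return Numeric vector of `nsim` simulated FRE values (mm).
#' @export
simulate.rigid_registration <- function(object, nsim = 1000, seed = NULL,
                                        fle_mm = NULL, ...) {
  if (is.null(fle_mm)) {
    fle_mm <- estimate_fle_from_fre(object$fre_mm, object$n_fiducials)
  }
  simulate_fre(object$source, fle_mm, n_reps = nsim, seed = seed)
}

#' Estimate FLE from a printed FRE
#'
#' For N fiducials with isotropic localization noise, the expected
#' squared fiducial registration error satisfies
#' `E[FRE^2] = (1 - 2/N) FLE^2`, so a printed FRE is inverted to the
#' fiducial localization error as `FLE = FRE * sqrt(N / (N - 2))`.
#'
#' @param fre_mm fiducial registration error (mm), >= 0.
#' @param n_fiducials number of fiducials N (>= 4 for a stable estimate;
#'   N <= 2 is undefined).
#' @return FLE in mm.
#' @examples
#' estimate_fle_from_fre(0.81, 7)   # ~0.958 mm
#' @export
estimate_fle_from_fre <- function(fre_mm, n_fiducials) {
  if (fre_mm < 0) stop("fre_mm must be non-negative", call. = FALSE)
  if (n_fiducials <= 2) stop("FLE estimate undefined for n <= 2", call. = FALSE)
  fre_mm * sqrt(n_fiducials / (n_fiducials - 2))
}

#' Monte-Carlo FRE replicates for a fiducial configuration
#'
#' Perturbs the configuration with zero-mean isotropic Gaussian noise
#' (per-axis sigma = `fle_mm / sqrt(3)`), registers the noisy copy back
#' onto the true positions, and records the FRE, `n_reps` times.
#'
#' @param fiducials a `fiducial_set` (the true configuration).
#' @param fle_mm fiducial localization error (mm); `FLE^2 = 3 sigma^2`.
#' @param n_reps number of replicates.
#' @param seed integer seed; RNG state is restored afterwards.
#' @return Numeric vector of FRE values (mm), length `n_reps`.
#' @export
simulate_fre <- function(fiducials, fle_mm, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  X <- fiducials$points
  run <- function() {
    sig <- fle_mm / sqrt(3)
    vapply(seq_len(n_reps), function(i) {
      Xn <- X + matrix(stats::rnorm(length(X), sd = sig), nrow(X), 3L)
      fit <- .kabsch(Xn, X)
      res2 <- rowSums((sweep(Xn %*% t(fit$R), 2L, fit$t, "+") - X)^2)
      sqrt(mean(res2))
    }, numeric(1))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Principal-axis decomposition of a configuration: eigenvectors of the
## second-moment matrix and the per-axis RMS extents f_k.
.principal_axes <- function(points) {
  C <- scale(points, scale = FALSE)
  M <- crossprod(C) / nrow(C)
  e <- eigen(M, symmetric = TRUE)
  list(centroid = colMeans(points), axes = e$vectors,
       rms_extent = sqrt(pmax(e$values, 0)))
}

#' Predict target registration error (TRE) at a point
#'
#' Estimates the RMS displacement of a target point induced by fiducial
#' localization error, for a given fiducial configuration. Two methods:
#'
#' * `"MONTE_CARLO"` (default): `n_reps` seeded replicates of the noisy
#'   registration; the RMS distance between the mapped and true target is
#'   returned. Valid for any non-collinear configuration, including the
#'   coplanar patient-frame plate.
#' * `"CLOSED_FORM"`: the standard anisotropic first-order formula
#'   `TRE^2(r) = FLE^2/N * (1 + (1/3) * sum_k d_k^2 / f_k^2)`, where
#'   `d_k` is the target's distance from the k-th principal axis of the
#'   fiducials and `f_k` the RMS fiducial distance from that axis. The
#'   formula divides by the out-of-plane extent and is therefore refused
#'   for (near-)coplanar configurations — use `"MONTE_CARLO"` for those.
#'
#' @param fiducials a `fiducial_set`.
#' @param fle_mm fiducial localization error (mm), >= 0.
#' @param target length-3 target position (mm), same space as `fiducials`.
#' @param method `"MONTE_CARLO"` or `"CLOSED_FORM"`.
#' @param n_reps Monte-Carlo replicates.
#' @param seed integer seed for the Monte-Carlo path.
#' @return A list of class `tre_prediction` with `target_point`,
#'   `tre_rms_mm` and `method`.
#' @export
predict_tre <- function(fiducials, fle_mm, target,
                        method = c("MONTE_CARLO", "CLOSED_FORM"),
                        n_reps = 10000, seed = NULL) {
  stopifnot(inherits(fiducials, "fiducial_set"), fle_mm >= 0)
  method <- match.arg(method)
  target <- as.numeric(target)
  if (length(target) != 3L) stop("target must be a 3-vector (mm)", call. = FALSE)
  tre <- if (method == "CLOSED_FORM") {
    pa <- .principal_axes(fiducials$points)
    if (any(pa$rms_extent <= 1e-6)) {
      stop("degenerate (coplanar or thinner) fiducial configuration: the ",
           "closed-form TRE formula is ill-conditioned; use method = ",
           "\"MONTE_CARLO\"", call. = FALSE)
    }
    N <- nrow(fiducials$points)
    proj <- as.numeric(crossprod(pa$axes, target - pa$centroid))
    d2 <- sum(proj^2) - proj^2          # squared distance from each axis
    f2 <- sum(pa$rms_extent^2) - pa$rms_extent^2
    sqrt(fle_mm^2 / N * (1 + sum(d2 / f2) / 3))
  } else {
    errs <- .mc_target_errors(fiducials$points, fle_mm,
                              matrix(target, 1L), n_reps, seed)
    sqrt(mean(errs^2))
  }
  structure(list(target_point = target, tre_rms_mm = tre, method = method,
                 fle_mm = fle_mm, n_reps = if (method == "MONTE_CARLO") n_reps else NA_integer_),
            class = "tre_prediction")
}

#' @export
print.tre_prediction <- function(x, ...) {
  cat(sprintf("Predicted TRE (%s): %.4f mm RMS at (%s) mm, FLE %.4f mm\n",
              x$method, x$tre_rms_mm,
              paste(round(x$target_point, 2), collapse = ", "), x$fle_mm))
  invisible(x)
}

## Per-replicate displacement of target points under noisy registration.
## Returns an n_reps x n_targets matrix of distances (mm).
.mc_target_errors <- function(X, fle_mm, targets, n_reps, seed = NULL) {
  targets <- .as_point_matrix(targets)
  run <- function() {
    sig <- fle_mm / sqrt(3)
    out <- matrix(0, n_reps, nrow(targets))
    for (i in seq_len(n_reps)) {
      Xn <- X + matrix(stats::rnorm(length(X), sd = sig), nrow(X), 3L)
      fit <- .kabsch(Xn, X)
      mapped <- sweep(targets %*% t(fit$R), 2L, fit$t, "+")
      out[i, ] <- sqrt(rowSums((mapped - targets)^2))
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Monte-Carlo TRE at several targets for a fiducial configuration
#'
#' Vectorized variant of [predict_tre()] (`method = "MONTE_CARLO"`) over
#' a set of target points; used by the error-budget analyses of the
#' phantom experiments.
#'
#' @inheritParams predict_tre
#' @param targets n x 3 matrix or `fiducial_set` of target points.
#' @return A list with `per_target_rms_mm` (named when targets carry
#'   labels), `pooled_rms_mm` (RMS over all targets and replicates) and
#'   `n_reps`.
#' @export
mc_tre <- function(fiducials, fle_mm, targets, n_reps = 2000, seed = NULL) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  labs <- NULL
  if (inherits(targets, "fiducial_set")) {
    labs <- targets$labels
    targets <- targets$points
  }
  errs <- .mc_target_errors(fiducials$points, fle_mm, targets, n_reps, seed)
  per <- sqrt(colMeans(errs^2))
  if (!is.null(labs)) names(per) <- labs
  list(per_target_rms_mm = per, pooled_rms_mm = sqrt(mean(errs^2)),
       n_reps = n_reps)
}
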