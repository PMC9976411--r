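#' @keywords internal
"_PACKAGE"

## Closed enumeration of coordinate spaces. Transforms are keyed by an
## ordered (source, destination) pair drawn from this set.
COORDINATE_SPACES <- c("IMAGE", "PATIENT_FRAME", "NEEDLE_FRAME", "WORLD",
                       "CAMERA", "SNAPSHOT_2D")

.check_space <- function(space) {
  if (!is.character(space) || length(space) != 1L ||
      !(space %in% COORDINATE_SPACES)) {
    stop("unknown coordinate space '", paste(space, collapse = ","),
         "'; must be one of: ", paste(COORDINATE_SPACES, collapse = ", "),
         call. = FALSE)
  }
  space
}

.as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("a 3-D point needs 3 coordinates", call. = FALSE)
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix (mm)", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

## Project a near-rotation onto SO(3); errors if it is not close to one.
.orthonormalize <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  }
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > tol) stop("rotation matrix is not orthonormal (deviation ",
                      format(err), ")", call. = FALSE)
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) stop("rotation matrix has determinant -1 (reflection)",
                       call. = FALSE)
  R
}

#' Rigid transform between two named coordinate spaces
#'
#' A rigid transform maps the coordinates of a point from its `source`
#' space to its `destination` space as `p' = R p + t`. Rotations are
#' stored as 3x3 orthonormal matrices (det +1); translations are in mm.
#' A matrix that is within `1e-6` of orthonormal is projected onto the
#' nearest rotation, so quaternion- or file-derived inputs are cleaned up
#' on construction.
#'
#' @param rotation 3x3 rotation matrix (dimensionless).
#' @param translation length-3 numeric translation (mm).
#' @param source,destination coordinate space names; one of
#'   `"IMAGE"`, `"PATIENT_FRAME"`, `"NEEDLE_FRAME"`, `"WORLD"`,
#'   `"CAMERA"`, `"SNAPSHOT_2D"`.
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(rotation_about("z", 90), c(1, 0, 0),
#'                       "IMAGE", "PATIENT_FRAME")
#' transform_points(t1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            source = "IMAGE", destination = "IMAGE") {
  rotation <- .orthonormalize(rotation)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must have length 3 (mm)",
                                      call. = FALSE)
  structure(list(rotation = rotation, translation = translation,
                 source = .check_space(source),
                 destination = .check_space(destination)),
            class = "rigid_transform")
}

#' Identity transform on a space (or between two aligned spaces)
#' @param source,destination coordinate space names.
#' @return A `rigid_transform` with unit rotation and zero translation.
#' @export
identity_transform <- function(source = "IMAGE", destination = source) {
  rigid_transform(diag(3), c(0, 0, 0), source, destination)
}

#' Elementary rotation matrices
#'
#' `rotation_about()` builds the rotation matrix for a right-handed
#' rotation about one of the coordinate axes; `rotation_axis_angle()`
#' rotates about an arbitrary axis (Rodrigues formula). Angles are taken
#' in degrees, matching the convention used throughout the API surface.
#'
#' @param axis `"x"`, `"y"` or `"z"`, or for `rotation_axis_angle` a
#'   length-3 direction vector (need not be normalized).
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' @rdname rotation_about
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  k <- axis / n
  a <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Quaternions are accepted at I/O boundaries in (w, x, y, z) order and
#' normalized on read.
#'
#' @param q length-4 numeric quaternion (w, x, y, z).
#' @return A 3x3 rotation matrix.
#' @export
quaternion_to_rotation <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L) stop("quaternion must have length 4 (w,x,y,z)",
                            call. = FALSE)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("quaternion must be non-zero", call. = FALSE)
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Compose two rigid transforms along a chain of spaces
#'
#' `compose(first, second)` returns the transform that applies `first`
#' and then `second`, i.e. the total map from `first$source` to
#' `second$destination`. The endpoints must chain:
#' `first$destination == second$source`.
#'
#' @param first,second `rigid_transform` objects with chaining endpoints.
#' @return A `rigid_transform` from `first$source` to `second$destination`.
#' @export
compose <- function(first, second) {
  stopifnot(inherits(first, "rigid_transform"),
            inherits(second, "rigid_transform"))
  if (!identical(first$destination, second$source)) {
    stop("space mismatch: cannot chain ", first$source, "->",
         first$destination, " with ", second$source, "->",
         second$destination, call. = FALSE)
  }
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation,
                  first$source, second$destination)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse transform, with source and destination swapped.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation),
                  t$destination, t$source)
}

#' Apply a rigid transform to 3-D points
#'
#' @param t a `rigid_transform`.
#' @param points a length-3 vector or an n x 3 matrix of points (mm),
#'   expressed in `t$source` coordinates.
#' @return An n x 3 matrix of points in `t$destination` coordinates.
#' @export
transform_points <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  p <- .as_point_matrix(points)
  sweep(p %*% t(t$rotation), 2L, t$translation, "+")
}

#' @export
print.rigid_transform <- function(x, digits = 4, ...) {
  cat("Rigid transform ", x$source, " -> ", x$destination, "\n", sep = "")
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("  rotation angle: %.*f deg, translation: (%s) mm\n",
              digits, ang,
              paste(formatC(x$translation, digits = digits, format = "fg"),
                    collapse = ", ")))
  invisible(x)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return The rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Serialize a rigid transform to/from JSON
#'
#' The JSON layout is a flat object with `source`, `destination`, the 9
#' rotation entries in row-major order, and `translation_mm`.
#'
#' @param t a `rigid_transform`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `transform_to_json`: a JSON string (or writes a file);
#'   `transform_from_json`: a `rigid_transform`.
#' @export
transform_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "rigid_transform"))
  obj <- list(source = t$source, destination = t$destination,
              rotation = as.numeric(t(t$rotation)),   # row-major
              translation_mm = t$translation)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname transform_to_json
#' @param json a JSON string or a path to a JSON file.
#' @export
transform_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json, warn = FALSE)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  R <- matrix(as.numeric(obj$rotation), 3, 3, byrow = TRUE)
  rigid_transform(R, as.numeric(obj$translation_mm), obj$source, obj$destination)
}
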