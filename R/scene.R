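## Patient-frame coordinate convention: origin at the center of the
## working-window base edge; x lateral (+right), y up along the lower
## plate, z into the phantom (depth). The upper, fiducial-bearing plate
## is hinged to the top edge of the working window and tilted 60 deg
## away from the phantom, so points on it are
##   p(a, b) = (a, hinge_y + b cos60, -b sin60),  a in [-45, 45], b in [0, 80].

## Default 7-fiducial layout, in upper-plate (a, b) coordinates.
## Deliberately asymmetric: no two pairwise distances are equal, so label
## correspondence is geometrically unambiguous and registration has no
## symmetric degeneracy. Overridable through build_patient_frame(config).
.default_fiducial_layout <- function() {
  m <- rbind(F1 = c(-43.4,  1.0), F2 = c(36.5,  7.7), F3 = c(-14.2, 24.4),
             F4 = c( 18.7, 44.5), F5 = c(-31.6, 55.0), F6 = c( 10.2, 68.1),
             F7 = c( 38.2, 71.1))
  colnames(m) <- c("a_mm", "b_mm")
  m
}

#' Physical model of the tracked patient reference frame
#'
#' Builds the fiducial-bearing frame that links image space to the AR
#' device: a lower plate carrying a 95 x 70 mm working access window,
#' and an upper 90 x 80 mm plate hinged to it at 60 degrees, carrying 7
#' coplanar 6-mm fiducial markers.
#'
#' @param config optional list with elements `fiducial_layout` (7 x 2
#'   matrix of in-plate (a, b) mm coordinates, a lateral in
#'   `[-45, 45]`, b up-plate in `[0, 80]`), `window_mm` (default
#'   `c(95, 70)`), `upper_plate_mm` (default `c(90, 80)`) and
#'   `plate_angle_deg` (default 60).
#' @return An object of class `patient_frame` with the fiducials as a
#'   `fiducial_set` in PATIENT_FRAME coordinates, the plate geometry and
#'   the unit normals of both plates.
#' @examples
#' frame <- build_patient_frame()
#' frame$fiducials
#' @export
build_patient_frame <- function(config = list()) {
  window <- config$window_mm %||% c(95, 70)
  plate <- config$upper_plate_mm %||% c(90, 80)
  angle <- config$plate_angle_deg %||% 60
  layout <- config$fiducial_layout %||% .default_fiducial_layout()
  layout <- as.matrix(layout)
  if (ncol(layout) != 2L || nrow(layout) != 7L) {
    stop("fiducial_layout must be a 7 x 2 matrix of in-plate (a, b) mm",
         call. = FALSE)
  }
  half_w <- plate[1] / 2
  if (any(abs(layout[, 1]) > half_w) ||
      any(layout[, 2] < 0) || any(layout[, 2] > plate[2])) {
    stop("fiducial layout violates the ", plate[1], "x", plate[2],
         " mm upper-plate bounds", call. = FALSE)
  }
  th <- angle * pi / 180
  hinge_y <- window[2]
  ## in-plate basis: a along x, b along (0, cos th, -sin th)
  b_dir <- c(0, cos(th), -sin(th))
  pts <- cbind(layout[, 1],
               hinge_y + layout[, 2] * b_dir[2],
               layout[, 2] * b_dir[3])
  labs <- rownames(layout) %||% paste0("F", seq_len(nrow(layout)))
  fid <- fiducial_set(labs, pts, "PATIENT_FRAME")
  upper_normal <- c(0, sin(th), cos(th))   # lower-plate normal is +z
  structure(list(fiducials = fid,
                 working_window_mm = window,
                 upper_plate_mm = plate,
                 plate_angle_deg = angle,
                 hinge_y_mm = hinge_y,
                 lower_normal = c(0, 0, 1),
                 upper_normal = upper_normal,
                 window_center = c(0, window[2] / 2, 0)),
            class = "patient_frame")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.patient_frame <- function(x, ...) {
  cat(sprintf(paste0("Patient reference frame: %g x %g mm working window, ",
                     "%g x %g mm fiducial plate at %g deg, %d fiducials\n"),
              x$working_window_mm[1], x$working_window_mm[2],
              x$upper_plate_mm[1], x$upper_plate_mm[2],
              x$plate_angle_deg, nrow(x$fiducials$points)))
  invisible(x)
}

#' Physical model of the tracked needle and its reference frame
#'
#' The needle reference frame is a 50 x 50 mm flat plate attached to the
#' needle shaft at 45 degrees. In NEEDLE_FRAME coordinates the plate
#' lies in the x-y plane (normal +z); the needle axis makes a 45-degree
#' angle with both the plate and its normal, and the tip sits at
#' `tip_offset` from the frame origin.
#'
#' @param needle_length_mm shaft length; default 200 (a 20-cm placement
#'   needle).
#' @param plate_mm plate edge lengths; default `c(50, 50)`.
#' @param plate_angle_deg angle between plate and needle axis; default 45.
#' @param length_marker_offset_mm distance of the depth marker from the
#'   tip along the shaft; must lie in `(0, needle_length_mm]`.
#' @return An object of class `needle_model` with fields
#'   `axis_direction` (unit vector in NEEDLE_FRAME) and `tip_offset`.
#' @export
build_needle <- function(needle_length_mm = 200, plate_mm = c(50, 50),
                         plate_angle_deg = 45,
                         length_marker_offset_mm = 100) {
  if (length_marker_offset_mm <= 0 ||
      length_marker_offset_mm > needle_length_mm) {
    stop("length marker must lie on the shaft: 0 < offset <= needle length",
         call. = FALSE)
  }
  th <- plate_angle_deg * pi / 180
  axis <- c(0, cos(th), sin(th))           # 45 deg to the plate (x-y plane)
  structure(list(needle_length_mm = needle_length_mm,
                 plate_mm = plate_mm,
                 plate_angle_deg = plate_angle_deg,
                 plate_normal = c(0, 0, 1),
                 axis_direction = axis,
                 tip_offset = needle_length_mm * axis,
                 length_marker_offset_mm = length_marker_offset_mm),
            class = "needle_model")
}

#' @export
print.needle_model <- function(x, ...) {
  cat(sprintf(paste0("Needle: %g mm shaft, %g x %g mm reference plate at ",
                     "%g deg, depth marker %g mm from tip\n"),
              x$needle_length_mm, x$plate_mm[1], x$plate_mm[2],
              x$plate_angle_deg, x$length_marker_offset_mm))
  invisible(x)
}

#' Insertion plan: target, skin entry and planned depth
#'
#' @param target,entry length-3 positions (mm), IMAGE space by
#'   convention.
#' @param planned_depth_mm insertion depth; defaults to
#'   `||target - entry||`.
#' @param id plan identifier.
#' @return An object of class `insertion_plan` with the unit `direction`
#'   from entry to target.
#' @export
insertion_plan <- function(target, entry, planned_depth_mm = NULL, id = "plan1") {
  target <- as.numeric(target); entry <- as.numeric(entry)
  stopifnot(length(target) == 3L, length(entry) == 3L)
  d <- sqrt(sum((target - entry)^2))
  if (d < 1e-9) stop("entry and target coincide", call. = FALSE)
  depth <- planned_depth_mm %||% d
  if (depth <= 0) stop("planned depth must be positive", call. = FALSE)
  structure(list(id = id, target = target, entry = entry,
                 planned_depth_mm = depth,
                 direction = (target - entry) / d),
            class = "insertion_plan")
}

#' @export
print.insertion_plan <- function(x, ...) {
  cat(sprintf("Insertion plan %s: depth %.1f mm, target (%s) mm\n",
              x$id, x$planned_depth_mm,
              paste(round(x$target, 1), collapse = ", ")))
  invisible(x)
}

.phantom_scene <- function(name, targets, frame_pose, description = "",
                           lesion_radii_mm = NULL, max_depth_mm = 120) {
  stopifnot(inherits(targets, "fiducial_set"),
            inherits(frame_pose, "rigid_transform"))
  ## reachability: every target within max depth of the working-window
  ## plane (z = 0 in PATIENT_FRAME)
  in_frame <- transform_points(invert(frame_pose), targets$points)
  if (any(in_frame[, 3] > max_depth_mm)) {
    stop("unreachable target: deeper than ", max_depth_mm,
         " mm behind the working window", call. = FALSE)
  }
  structure(list(name = name, targets = targets, frame_pose = frame_pose,
                 description = description,
                 lesion_radii_mm = lesion_radii_mm,
                 max_depth_mm = max_depth_mm),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("Phantom scene '%s': %d targets. %s\n", x$name,
              nrow(x$targets$points), x$description))
  invisible(x)
}

#' Bead plate for the system-accuracy experiment
#'
#' Four 1-mm metallic beads at the corners of a 40 x 40 mm square,
#' centered on the working window and placed at a given depth from the
#' base of the patient reference frame (the protocol uses 50 and
#' 100 mm). Bead coordinates are reported in IMAGE space through the
#' scene's frame pose (identity by default: image and frame axes
#' aligned, which is sufficient for the accuracy simulations since the
#' registration chain is exercised with noise, not with a hidden true
#' pose).
#'
#' @param distance_from_base_mm depth of the bead plane behind the
#'   working window (mm); 0 puts the beads in the window plane.
#' @param frame optional `patient_frame` (for the window center).
#' @return A `phantom_scene` with 4 bead targets.
#' @export
build_exp1_plate <- function(distance_from_base_mm, frame = build_patient_frame()) {
  if (distance_from_base_mm < 0) stop("distance must be >= 0", call. = FALSE)
  ctr <- frame$window_center
  half <- 20
  corners <- rbind(c(-half, -half), c(half, -half), c(half, half),
                   c(-half, half))
  pts <- cbind(ctr[1] + corners[, 1], ctr[2] + corners[, 2],
               distance_from_base_mm)
  labs <- sprintf("B%d_%g", 1:4, distance_from_base_mm)
  .phantom_scene(sprintf("bead_plate_%gmm", distance_from_base_mm),
                 fiducial_set(labs, pts, "IMAGE"),
                 identity_transform("PATIENT_FRAME", "IMAGE"),
                 sprintf("4-bead 40x40 mm test plate, %g mm from frame base",
                         distance_from_base_mm))
}

## truncated-normal draw by rejection, bounds at mean +/- 3 sd
.rnorm_trunc3 <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (abs(x - mean) <= 3 * sd) break
    }
    out[i] <- x
  }
  out
}

#' Gel-phantom scene and insertion plans for the needle-placement task
#'
#' Reproduces the placement-experiment geometry: a cylindrical gel
#' phantom (diameter 100 mm, length 120 mm) with four 1-mm metallic
#' beads embedded at 60-80 mm depth, and four randomized entry points on
#' the exposed surface chosen so the planned insertion depths are
#' 79.6 +/- 3.1 mm and the insertion angles from the surface normal are
#' 12.8 +/- 6.8 degrees (draws truncated at 3 sd).
#'
#' @param seed integer seed; the same seed reproduces the identical
#'   scene.
#' @param frame optional `patient_frame`.
#' @return A list with `scene` (a `phantom_scene`) and `plans` (list of
#'   four `insertion_plan`s).
#' @export
build_exp2_scene <- function(seed = 1, frame = build_patient_frame()) {
  gen <- function() {
    ctr <- frame$window_center
    depth_mean <- 79.6; depth_sd <- 3.1
    ang_mean <- 12.8; ang_sd <- 6.8
    targets <- matrix(0, 4, 3)
    entries <- matrix(0, 4, 3)
    depths <- numeric(4)
    for (i in 1:4) {
      repeat {
        depth <- .rnorm_trunc3(1, depth_mean, depth_sd)
        ang <- abs(.rnorm_trunc3(1, ang_mean, ang_sd)) * pi / 180
        tz <- depth * cos(ang)
        if (tz < 60 || tz > 80) next
        ## bead x-y within 30 mm of the cylinder axis
        r <- 30 * sqrt(stats::runif(1)); phi <- stats::runif(1, 0, 2 * pi)
        txy <- ctr[1:2] + r * c(cos(phi), sin(phi))
        az <- stats::runif(1, 0, 2 * pi)
        dir <- c(sin(ang) * cos(az), sin(ang) * sin(az), cos(ang))
        exy <- txy - depth * dir[1:2]
        if (sqrt(sum((exy - ctr[1:2])^2)) > 48) next   # entry on the face
        targets[i, ] <- c(txy, tz)
        entries[i, ] <- c(exy, 0)
        depths[i] <- depth
        break
      }
    }
    labs <- paste0("T", 1:4)
    scene <- .phantom_scene("gel_cylinder",
                            fiducial_set(labs, targets, "IMAGE"),
                            identity_transform("PATIENT_FRAME", "IMAGE"),
                            "gel phantom, D=100 mm L=120 mm cylinder, 4 beads")
    plans <- lapply(1:4, function(i)
      insertion_plan(targets[i, ], entries[i, ], id = labs[i]))
    list(scene = scene, plans = plans)
  }
  withr::with_seed(seed, gen())
}

#' Pelvic-phantom fixture scene (synthetic)
#'
#' A guidance-scenario fixture mimicking an anthropomorphic pelvic
#' phantom: two seminal-vesicle surrogate targets and three spherical
#' pseudolesion centroids with volumes between 0.5 and 0.7 cm^3
#' (radii from `r = (3V / 4 pi)^(1/3)`). Target coordinates are
#' synthetic — invented at anatomically plausible depths behind the
#' working window; they are a fixture, not measured data.
#'
#' @return A `phantom_scene` with 5 targets and `lesion_radii_mm` set
#'   for the three pseudolesions.
#' @export
build_pelvic_scene <- function() {
  vol_cm3 <- c(0.5, 0.6, 0.7)
  radii <- (3 * vol_cm3 * 1000 / (4 * pi))^(1 / 3)
  pts <- rbind(SV_L = c(-14, 52, 68),
               SV_R = c( 13, 53, 70),
               PL1 = c( -8, 38, 62),
               PL2 = c(  6, 30, 75),
               PL3 = c( -2, 44, 88))
  .phantom_scene("pelvic_phantom_synthetic",
                 fiducial_set(rownames(pts), pts, "IMAGE"),
                 identity_transform("PATIENT_FRAME", "IMAGE"),
                 paste("synthetic pelvic fixture: 2 seminal-vesicle",
                       "surrogates + 3 pseudolesions"),
                 lesion_radii_mm = stats::setNames(radii,
                                                   c("PL1", "PL2", "PL3")))
}

#' Serialize a phantom scene to/from JSON
#'
#' Layout: `{name, description, frame_pose, targets: [rows], lesion_radii_mm?}`
#' with the frame pose in the flat transform-JSON layout.
#'
#' @param scene a `phantom_scene`.
#' @param path file path, or `NULL` to return the JSON string.
#' @export
scene_to_json <- function(scene, path = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  obj <- list(name = scene$name, description = scene$description,
              frame_pose = jsonlite::fromJSON(transform_to_json(scene$frame_pose)),
              targets = as.data.frame(scene$targets),
              max_depth_mm = scene$max_depth_mm)
  if (!is.null(scene$lesion_radii_mm)) {
    obj$lesion_radii_mm <- as.list(scene$lesion_radii_mm)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname scene_to_json
#' @param json JSON string or file path.
#' @export
scene_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json, warn = FALSE)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  tg <- obj$targets
  pose_json <- jsonlite::toJSON(obj$frame_pose, auto_unbox = TRUE, digits = NA)
  radii <- if (!is.null(obj$lesion_radii_mm)) unlist(obj$lesion_radii_mm)
  .phantom_scene(obj$name,
                 fiducial_set(tg$label,
                              as.matrix(tg[, c("x_mm", "y_mm", "z_mm")]),
                              tg$space[1]),
                 transform_from_json(as.character(pose_json)),
                 obj$description %||% "",
                 lesion_radii_mm = radii,
                 max_depth_mm = obj$max_depth_mm %||% 120)
}

#' Read / write insertion plans as CSV
#'
#' Header: `plan_id,tx,ty,tz,ex,ey,ez,depth_mm` (mm).
#'
#' @param plans list of `insertion_plan`s.
#' @param path CSV file path.
#' @export
write_plans_csv <- function(plans, path) {
  df <- do.call(rbind, lapply(plans, function(p)
    data.frame(plan_id = p$id, tx = p$target[1], ty = p$target[2],
               tz = p$target[3], ex = p$entry[1], ey = p$entry[2],
               ez = p$entry[3], depth_mm = p$planned_depth_mm)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plans_csv
#' @export
read_plans_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i)
    insertion_plan(c(df$tx[i], df$ty[i], df$tz[i]),
                   c(df$ex[i], df$ey[i], df$ez[i]),
                   df$depth_mm[i], id = df$plan_id[i]))
}
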