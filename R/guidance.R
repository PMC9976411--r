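#' Guidance display thresholds
#'
#' Thresholds driving the display states of the free-hand guidance
#' feedback. The 5-mm proximity band reproduces the digital-target color
#' change when the needle tip is within 5 mm of the target; the hit and
#' alignment thresholds are configurable design additions (the display
#' itself only distinguishes the 5-mm band), giving simulated operators
#' a stop criterion and a shaft-color state.
#'
#' @param proximity_threshold_mm distance (mm) below which the target is
#'   shown as "near"; default 5.
#' @param hit_threshold_mm distance (mm) at or below which the target
#'   counts as hit; default 1; must be `< proximity_threshold_mm`.
#' @param alignment_threshold_deg angular deviation (degrees) below
#'   which the shaft shows the "correct angle" state; default 3.
#' @param depth_tolerance_mm tolerance (mm) on the depth stop; default 1.
#' @param extension_length_mm length of the optional digital needle
#'   extension line; default 100.
#' @return An object of class `guidance_config`.
#' @export
guidance_config <- function(proximity_threshold_mm = 5,
                            hit_threshold_mm = 1,
                            alignment_threshold_deg = 3,
                            depth_tolerance_mm = 1,
                            extension_length_mm = 100) {
  if (!(hit_threshold_mm > 0 && hit_threshold_mm < proximity_threshold_mm)) {
    stop("need 0 < hit threshold < proximity threshold", call. = FALSE)
  }
  if (alignment_threshold_deg <= 0) stop("alignment threshold must be > 0",
                                         call. = FALSE)
  structure(list(proximity_threshold_mm = proximity_threshold_mm,
                 hit_threshold_mm = hit_threshold_mm,
                 alignment_threshold_deg = alignment_threshold_deg,
                 depth_tolerance_mm = depth_tolerance_mm,
                 extension_length_mm = extension_length_mm),
            class = "guidance_config")
}

## tip position and axis direction of a posed needle, in the pose's
## destination space
.needle_tip_axis <- function(needle_pose, needle) {
  stopifnot(inherits(needle_pose, "rigid_transform"),
            inherits(needle, "needle_model"))
  tip <- as.numeric(transform_points(needle_pose, needle$tip_offset))
  axis <- as.numeric(needle_pose$rotation %*% needle$axis_direction)
  list(tip = tip, axis = axis)
}

#' Free-hand guidance feedback for one tracked needle pose
#'
#' Computes the per-tick digital feedback of the free-hand guidance
#' method: tip-to-target distance, angular deviation of the needle axis
#' from the tip-to-target direction, the predicted miss (closest
#' approach of the extended needle line to the target), the remaining
#' depth along the current axis, and the display states. A pure,
#' deterministic function of its inputs.
#'
#' @param target length-3 target position in WORLD coordinates (mm).
#' @param needle_pose `rigid_transform` NEEDLE_FRAME -> WORLD.
#' @param needle a `needle_model`.
#' @param config a `guidance_config`.
#' @return An object of class `guidance_state` with fields
#'   `tip_position`, `tip_target_distance_mm`, `angular_deviation_deg`,
#'   `predicted_miss_mm`, `depth_remaining_mm`, `proximity_state`
#'   (`"FAR"`, `"NEAR"` or `"HIT"`) and `alignment_state` (`"ALIGNED"`
#'   or `"OFF_AXIS"`).
#' @export
free_hand_update <- function(target, needle_pose, needle,
                             config = guidance_config()) {
  ta <- .needle_tip_axis(needle_pose, needle)
  target <- as.numeric(target)
  v <- target - ta$tip
  dist <- sqrt(sum(v^2))
  along <- sum(v * ta$axis)
  perp2 <- max(0, sum(v^2) - along^2)
  miss <- sqrt(perp2)
  ang <- if (dist < 1e-12) 0 else {
    ct <- along / dist
    acos(min(1, max(-1, ct))) * 180 / pi
  }
  prox <- if (dist <= config$hit_threshold_mm) "HIT"
          else if (dist <= config$proximity_threshold_mm) "NEAR" else "FAR"
  structure(list(tip_position = ta$tip,
                 tip_target_distance_mm = dist,
                 angular_deviation_deg = ang,
                 predicted_miss_mm = miss,
                 depth_remaining_mm = along,
                 proximity_state = prox,
                 alignment_state = if (ang <= config$alignment_threshold_deg)
                   "ALIGNED" else "OFF_AXIS"),
            class = "guidance_state")
}

#' @export
print.guidance_state <- function(x, ...) {
  cat(sprintf(paste0("Guidance: tip-target %.2f mm [%s], deviation %.2f deg ",
                     "[%s], predicted miss %.2f mm, depth remaining %.2f mm\n"),
              x$tip_target_distance_mm, x$proximity_state,
              x$angular_deviation_deg, x$alignment_state,
              x$predicted_miss_mm, x$depth_remaining_mm))
  invisible(x)
}

#' Score a needle pose against a planned path
#'
#' Compares the posed needle with a displayed insertion plan:
#' the lateral offset between the needle axis line and the planned path
#' line (their common-perpendicular distance; perpendicular distance
#' when parallel), the angle between the two directions, and the depth
#' error (insertion depth of the tip along the plan minus the planned
#' depth, i.e. how far the length marker has passed its planned stop).
#'
#' @param plan an `insertion_plan` (same space as the pose destination).
#' @param needle_pose `rigid_transform` posing the needle in that space.
#' @param needle a `needle_model`.
#' @return Named numeric vector `c(lateral_offset_mm, axis_angle_deg,
#'   depth_error_mm)`.
#' @export
planned_path_score <- function(plan, needle_pose, needle) {
  stopifnot(inherits(plan, "insertion_plan"))
  ta <- .needle_tip_axis(needle_pose, needle)
  u <- plan$direction; v <- ta$axis
  w <- ta$tip - plan$entry
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  ncr <- sqrt(sum(cr^2))
  lateral <- if (ncr < 1e-9) {
    ## parallel lines: perpendicular distance from the plan line
    sqrt(max(0, sum(w^2) - sum(w * u)^2))
  } else {
    abs(sum(w * cr)) / ncr
  }
  ct <- min(1, max(-1, sum(u * v)))
  ang <- acos(ct) * 180 / pi
  depth_err <- sum((ta$tip - plan$entry) * u) - plan$planned_depth_mm
  c(lateral_offset_mm = lateral, axis_angle_deg = ang,
    depth_error_mm = depth_err)
}

#' Simulated-operator policy
#'
#' Bundles the behavioural parameters of a simulated operator: step
#' length of the insertion, the per-method aiming and stopping noise,
#' and a step budget. Angular noise perturbs the aim direction, lateral
#' noise the entry point (in the plane normal to the approach), and
#' depth noise the stopping decision.
#'
#' @param step_mm advance per tick (mm); default 2.
#' @param max_steps step budget before a non-convergence error; default 500.
#' @param angle_sd_deg,lateral_sd_mm,depth_sd_mm operator noise sigmas.
#' @return An object of class `operator_policy`.
#' @export
operator_policy <- function(step_mm = 2, max_steps = 500,
                            angle_sd_deg = 0, lateral_sd_mm = 0,
                            depth_sd_mm = 0) {
  stopifnot(step_mm > 0, max_steps >= 1)
  structure(list(step_mm = step_mm, max_steps = max_steps,
                 angle_sd_deg = angle_sd_deg, lateral_sd_mm = lateral_sd_mm,
                 depth_sd_mm = depth_sd_mm),
            class = "operator_policy")
}

## unit vector orthogonal pair spanning the plane normal to d
.orthobasis <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  cbind(e1, e2)
}

## rotate direction d by a random small angle (sd in degrees)
.perturb_direction <- function(d, sd_deg) {
  if (sd_deg <= 0) return(d)
  ang <- stats::rnorm(1, 0, sd_deg)
  az <- stats::runif(1, 0, 2 * pi)
  B <- .orthobasis(d)
  axis <- as.numeric(B %*% c(cos(az), sin(az)))
  as.numeric(rotation_axis_angle(axis, ang) %*% d)
}

## pose a needle so its tip is at `tip` with axis along `dir` (unit)
.pose_needle <- function(needle, tip, dir) {
  a <- needle$axis_direction
  v <- c(a[2] * dir[3] - a[3] * dir[2],
         a[3] * dir[1] - a[1] * dir[3],
         a[1] * dir[2] - a[2] * dir[1])
  s <- sqrt(sum(v^2)); c_ <- sum(a * dir)
  R <- if (s < 1e-12) {
    if (c_ > 0) diag(3) else rotation_axis_angle(.orthobasis(a)[, 1], 180)
  } else {
    V <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + V + V %*% V * ((1 - c_) / s^2)
  }
  t <- tip - as.numeric(R %*% needle$tip_offset)
  rigid_transform(R, t, "NEEDLE_FRAME", "WORLD")
}

#' Simulate one needle insertion under AR guidance
#'
#' Runs a simulated operator from skin entry to the stopping decision
#' and returns the tick-by-tick guidance states. Two methods:
#'
#' * `"PLANNED_PATH"`: the operator aligns to the displayed plan with
#'   angular and lateral noise drawn once, advances along the resulting
#'   fixed axis, and stops when the insertion depth along the plan
#'   reaches the planned depth plus a depth-noise draw (the length
#'   marker reaching its planned stop).
#' * `"FREE_HAND"`: the operator aims at the displayed target, re-aims
#'   each tick with fresh angular noise (continuous digital feedback),
#'   and stops at the point of closest approach plus a depth-noise draw.
#'
#' With an all-zero-noise policy either method ends with the tip on the
#' target. The trajectory is a deterministic function of the seed.
#'
#' @param controller an `operator_policy`.
#' @param plan an `insertion_plan` in WORLD coordinates (the displayed
#'   plan/target).
#' @param needle a `needle_model`.
#' @param method `"PLANNED_PATH"` or `"FREE_HAND"`.
#' @param config a `guidance_config`.
#' @param seed integer seed; RNG state is restored afterwards.
#' @return A list of class `insertion_trajectory`: `states` (list of
#'   `guidance_state`, one per tick), `final_state`, `method` and
#'   `seed`. Errors if the step budget is exhausted before the stop
#'   criterion.
#' @export
insertion_trajectory <- function(controller, plan, needle,
                                 method = c("PLANNED_PATH", "FREE_HAND"),
                                 config = guidance_config(), seed = NULL) {
  stopifnot(inherits(controller, "operator_policy"),
            inherits(plan, "insertion_plan"))
  method <- match.arg(method)
  run <- function() {
    target <- plan$target
    dir0 <- plan$direction
    B <- .orthobasis(dir0)
    entry <- plan$entry +
      as.numeric(B %*% stats::rnorm(2, 0, controller$lateral_sd_mm))
    states <- list()
    if (method == "PLANNED_PATH") {
      dir <- .perturb_direction(dir0, controller$angle_sd_deg)
      stop_depth <- plan$planned_depth_mm +
        stats::rnorm(1, 0, controller$depth_sd_mm)
      tip <- entry
      for (k in seq_len(controller$max_steps)) {
        depth <- sum((tip - plan$entry) * dir0)
        step <- min(controller$step_mm, stop_depth - depth)
        if (step <= 1e-9) {
          states[[length(states) + 1L]] <-
            free_hand_update(target, .pose_needle(needle, tip, dir), needle,
                             config)
          return(states)
        }
        tip <- tip + step * dir
        states[[length(states) + 1L]] <-
          free_hand_update(target, .pose_needle(needle, tip, dir), needle,
                           config)
      }
    } else {
      tip <- entry
      for (k in seq_len(controller$max_steps)) {
        aim <- target - tip
        d <- sqrt(sum(aim^2))
        dir <- .perturb_direction(aim / d, controller$angle_sd_deg)
        st <- free_hand_update(target, .pose_needle(needle, tip, dir),
                               needle, config)
        if (st$depth_remaining_mm <= controller$step_mm) {
          ## stopping decision: advance to the point of closest approach
          ## plus the operator's depth-decision noise, then stop
          adv <- st$depth_remaining_mm +
            stats::rnorm(1, 0, controller$depth_sd_mm)
          tip <- tip + adv * dir
          states[[length(states) + 1L]] <-
            free_hand_update(target, .pose_needle(needle, tip, dir), needle,
                             config)
          return(states)
        }
        tip <- tip + controller$step_mm * dir
        states[[length(states) + 1L]] <-
          free_hand_update(target, .pose_needle(needle, tip, dir), needle,
                           config)
      }
    }
    stop("insertion did not converge within ", controller$max_steps,
         " steps", call. = FALSE)
  }
  states <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(states = states, final_state = states[[length(states)]],
                 method = method, seed = seed),
            class = "insertion_trajectory")
}

#' @export
print.insertion_trajectory <- function(x, ...) {
  cat(sprintf("%s insertion: %d ticks, final tip-target %.3f mm [%s]\n",
              x$method, length(x$states),
              x$final_state$tip_target_distance_mm,
              x$final_state$proximity_state))
  invisible(x)
}

#' Write a guidance-state stream as CSV
#'
#' One row per tick:
#' `tick,tip_x,tip_y,tip_z,dist_mm,angle_deg,miss_mm,depth_rem_mm,prox_state,align_state`.
#'
#' @param trajectory an `insertion_trajectory` (or list of
#'   `guidance_state`).
#' @param path CSV file path.
#' @export
write_guidance_csv <- function(trajectory, path) {
  states <- if (inherits(trajectory, "insertion_trajectory"))
    trajectory$states else trajectory
  df <- do.call(rbind, lapply(seq_along(states), function(i) {
    s <- states[[i]]
    data.frame(tick = i, tip_x = s$tip_position[1], tip_y = s$tip_position[2],
               tip_z = s$tip_position[3], dist_mm = s$tip_target_distance_mm,
               angle_deg = s$angular_deviation_deg,
               miss_mm = s$predicted_miss_mm,
               depth_rem_mm = s$depth_remaining_mm,
               prox_state = s$proximity_state,
               align_state = s$alignment_state)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
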