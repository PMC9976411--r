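test_that("guidance config enforces its threshold ordering", {
  expect_error(guidance_config(proximity_threshold_mm = 5,
                               hit_threshold_mm = 5), "hit threshold")
  expect_error(guidance_config(alignment_threshold_deg = 0), "alignment")
})

test_that("free-hand feedback: contact, proximity band and colinear aim", {
  ndl <- build_needle()
  target <- c(10, 20, 30)
  # tip exactly on target
  st <- free_hand_update(target, pose_needle(ndl, target, c(0, 0, 1)), ndl)
  expect_equal(st$tip_target_distance_mm, 0)
  expect_identical(st$proximity_state, "HIT")
  expect_equal(st$predicted_miss_mm, 0)
  # tip 4.9 mm away: inside the 5-mm vicinity band
  st2 <- free_hand_update(target,
                          pose_needle(ndl, target - c(0, 0, 4.9), c(0, 0, 1)),
                          ndl)
  expect_equal(st2$tip_target_distance_mm, 4.9)
  expect_identical(st2$proximity_state, "NEAR")
  # 5.1 mm away: FAR
  st3 <- free_hand_update(target,
                          pose_needle(ndl, target - c(0, 0, 5.1), c(0, 0, 1)),
                          ndl)
  expect_identical(st3$proximity_state, "FAR")
  # axis pointing exactly at the target from 50 mm
  st4 <- free_hand_update(target,
                          pose_needle(ndl, target - 50 * c(0, 0, 1),
                                      c(0, 0, 1)),
                          ndl)
  expect_equal(st4$angular_deviation_deg, 0, tolerance = 1e-9)
  expect_identical(st4$alignment_state, "ALIGNED")
  expect_equal(st4$predicted_miss_mm, 0, tolerance = 1e-9)
  expect_equal(st4$depth_remaining_mm, 50, tolerance = 1e-9)
})

test_that("predicted miss never exceeds the tip-target distance", {
  ndl <- build_needle()
  set.seed(141)
  for (i in 1:50) {
    tip <- runif(3, -50, 50)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    st <- free_hand_update(c(0, 0, 0), pose_needle(ndl, tip, dir), ndl)
    expect_lte(st$predicted_miss_mm, st$tip_target_distance_mm + 1e-12)
  }
})

test_that("proximity state is a monotone step function of distance", {
  ndl <- build_needle()
  cfg <- guidance_config()
  dists <- c(0.2, 0.999, 1.001, 3, 4.999, 5.001, 40)
  states <- vapply(dists, function(d) {
    free_hand_update(c(0, 0, 0), pose_needle(ndl, c(0, 0, -d), c(0, 0, 1)),
                     ndl, cfg)$proximity_state
  }, character(1))
  expect_identical(states,
                   c("HIT", "HIT", "NEAR", "NEAR", "NEAR", "FAR", "FAR"))
})

test_that("free-hand feedback is invariant to a common world transform", {
  ndl <- build_needle()
  set.seed(151)
  target <- c(12, -8, 60)
  pose <- pose_needle(ndl, c(0, 5, -20), c(0.1, 0.05, 1) / sqrt(1.0125))
  w <- random_transform("WORLD", "WORLD")
  st <- free_hand_update(target, pose, ndl)
  st2 <- free_hand_update(as.numeric(transform_points(w, target)),
                          compose(pose, w), ndl)
  for (f in c("tip_target_distance_mm", "angular_deviation_deg",
              "predicted_miss_mm", "depth_remaining_mm")) {
    expect_equal(st2[[f]], st[[f]], tolerance = 1e-9)
  }
  expect_identical(st2$proximity_state, st$proximity_state)
})

test_that("planned-path scoring: on-plan, lateral shift and overshoot", {
  ndl <- build_needle()
  plan <- insertion_plan(target = c(0, 0, 80), entry = c(0, 0, 0))
  on_plan <- pose_needle(ndl, c(0, 0, 80), c(0, 0, 1))
  expect_equal(unname(planned_path_score(plan, on_plan, ndl)), c(0, 0, 0),
               tolerance = 1e-9)
  shifted <- pose_needle(ndl, c(2, 0, 40), c(0, 0, 1))
  sc <- planned_path_score(plan, shifted, ndl)
  expect_equal(unname(sc["lateral_offset_mm"]), 2, tolerance = 1e-9)
  expect_equal(unname(sc["axis_angle_deg"]), 0, tolerance = 1e-9)
  over <- pose_needle(ndl, c(0, 0, 83), c(0, 0, 1))
  expect_equal(unname(planned_path_score(plan, over, ndl)["depth_error_mm"]),
               3, tolerance = 1e-9)
  tilted <- pose_needle(ndl, c(0, 0, 80),
                        c(sin(10 * pi / 180), 0, cos(10 * pi / 180)))
  expect_equal(unname(planned_path_score(plan, tilted, ndl)["axis_angle_deg"]),
               10, tolerance = 1e-9)
})

test_that("a noise-free operator reaches the target with either method", {
  ndl <- build_needle()
  plan <- insertion_plan(target = c(5, 30, 75), entry = c(-10, 25, 0))
  cfg <- guidance_config()
  for (m in c("PLANNED_PATH", "FREE_HAND")) {
    traj <- insertion_trajectory(operator_policy(), plan, ndl, method = m,
                                 config = cfg, seed = 1)
    expect_lt(traj$final_state$tip_target_distance_mm, cfg$hit_threshold_mm)
    expect_identical(traj$final_state$proximity_state, "HIT")
  }
})

test_that("trajectories are reproducible under a fixed seed", {
  ndl <- build_needle()
  plan <- insertion_plan(target = c(0, 35, 78), entry = c(6, 20, 0))
  pol <- operator_policy(angle_sd_deg = 2, lateral_sd_mm = 1, depth_sd_mm = 2)
  t1 <- insertion_trajectory(pol, plan, ndl, "FREE_HAND", seed = 42)
  t2 <- insertion_trajectory(pol, plan, ndl, "FREE_HAND", seed = 42)
  expect_identical(t1$final_state, t2$final_state)
  expect_equal(length(t1$states), length(t2$states))
  t3 <- insertion_trajectory(pol, plan, ndl, "FREE_HAND", seed = 43)
  expect_false(identical(t1$final_state$tip_position,
                         t3$final_state$tip_position))
})

test_that("mean depth error increases with operator depth noise", {
  ndl <- build_needle()
  plan <- insertion_plan(target = c(0, 35, 78), entry = c(0, 30, 0))
  mean_err <- vapply(c(0.5, 1, 2), function(sd) {
    errs <- vapply(1:500, function(s) {
      insertion_trajectory(operator_policy(depth_sd_mm = sd), plan, ndl,
                           "FREE_HAND",
                           seed = s)$final_state$tip_target_distance_mm
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("a step budget that is too small raises a clear error", {
  ndl <- build_needle()
  plan <- insertion_plan(target = c(0, 35, 78), entry = c(0, 30, 0))
  expect_error(insertion_trajectory(operator_policy(max_steps = 3), plan,
                                    ndl, "FREE_HAND", seed = 1),
               "did not converge")
})

test_that("guidance streams serialize to the tick CSV layout", {
  ndl <- build_needle()
  plan <- insertion_plan(target = c(0, 35, 78), entry = c(0, 30, 0))
  traj <- insertion_trajectory(operator_policy(), plan, ndl, "PLANNED_PATH",
                               seed = 1)
  f <- tempfile(fileext = ".csv")
  write_guidance_csv(traj, f)
  df <- utils::read.csv(f)
  expect_identical(names(df),
                   c("tick", "tip_x", "tip_y", "tip_z", "dist_mm",
                     "angle_deg", "miss_mm", "depth_rem_mm", "prox_state",
                     "align_state"))
  expect_equal(nrow(df), length(traj$states))
})
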