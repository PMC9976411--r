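test_that("noise model validates and the zero model is all zeros", {
  nm <- noise_model()
  expect_true(all(unlist(nm) == 0))
  expect_error(noise_model(fle_sigma_mm = -1), ">= 0")
  nm2 <- noise_model(operator_depth_mm = c(PLANNED_PATH = 1, FREE_HAND = 2))
  expect_equal(nm2$operator_depth_mm[["FREE_HAND"]], 2)
})

test_that("FRE calibration round-trips through the simulator", {
  nm <- calibrate_noise_from_fre(0.81, 7)
  expect_equal(nm$fle_sigma_mm, 0.9584 / sqrt(3), tolerance = 1e-4)
  expect_true(all(unlist(calibrate_noise_from_fre(0, 7)) == 0))
  frame <- build_patient_frame()
  fres <- simulate_fre(frame$fiducials, nm$fle_sigma_mm * sqrt(3),
                       n_reps = 5000, seed = 11)
  expect_equal(sqrt(mean(fres^2)), 0.81, tolerance = 0.03)
})

test_that("snapshot camera is calibrated on the 40-mm square", {
  cam <- camera_model(position = c(0, 0, -450), look_at = c(0, 0, 0))
  p <- rbind(c(-20, 0, 0), c(20, 0, 0), c(0, -20, 0), c(0, 20, 0))
  uv <- project_snapshot(cam, p)
  expect_equal(sqrt(sum((uv[1, ] - uv[2, ])^2)), 40, tolerance = 1e-6)
  expect_equal(sqrt(sum((uv[3, ] - uv[4, ])^2)), 40, tolerance = 1e-6)
  expect_error(project_snapshot(cam, c(0, 0, -500)), "behind")
})

test_that("zero noise yields identically zero error in all experiments", {
  ov <- simulate_overlay_experiment(seed = 2)
  expect_lt(max(ov$error_mm), 1e-9)
  tg <- simulate_targeting_experiment(seed = 2)
  expect_lt(max(tg$error_mm), 1e-9)
  pl <- simulate_placement_experiment(seed = 2)
  expect_lt(max(pl$error_mm), guidance_config()$hit_threshold_mm)
})

test_that("protocol counts: 8 x n positions, 24 targeting, 8 per operator", {
  ov3 <- simulate_overlay_experiment(n_positions = 3, seed = 1)
  expect_equal(nrow(ov3), 24L)
  ov <- simulate_overlay_experiment(seed = 1)   # default 7 positions
  expect_equal(nrow(ov), 56L)
  ov9 <- simulate_overlay_experiment(n_positions = 9, seed = 1)
  expect_equal(nrow(ov9), 72L)
  tg <- simulate_targeting_experiment(seed = 1)
  expect_equal(nrow(tg), 24L)
  expect_equal(length(unique(tg$target_id)), 8L)
  pl <- simulate_placement_experiment(seed = 1)
  expect_equal(nrow(pl), 24L)
  counts <- table(pl$operator, pl$method)
  expect_true(all(counts == 4L))
  expect_equal(rowSums(counts), c(OP1 = 8, OP2 = 8, OP3 = 8))
})

test_that("experiments are seed-reproducible and seed-sensitive", {
  a <- simulate_overlay_experiment(noise = calibrated_noise_model(), seed = 5)
  b <- simulate_overlay_experiment(noise = calibrated_noise_model(), seed = 5)
  expect_identical(a, b)
  c_ <- simulate_overlay_experiment(noise = calibrated_noise_model(), seed = 6)
  expect_false(identical(a$error_mm, c_$error_mm))
})

test_that("2-D overlay error never exceeds 3-D TRE at the same targets", {
  frame <- build_patient_frame()
  fle <- estimate_fle_from_fre(0.81, 7)
  nm <- noise_model(fle_sigma_mm = fle / sqrt(3))
  ov <- simulate_overlay_experiment(frame, noise = nm, n_positions = 250,
                                    seed = 8)
  rms_2d <- sqrt(mean(ov$error_mm^2))
  beads <- rbind(build_exp1_plate(50, frame)$targets$points,
                 build_exp1_plate(100, frame)$targets$points)
  rms_3d <- mc_tre(frame$fiducials, fle, beads, n_reps = 2000,
                   seed = 8)$pooled_rms_mm
  expect_lt(rms_2d, rms_3d)
})

test_that("overlay RMS error is monotone in each noise sigma", {
  grids <- list(fle_sigma_mm = c(0, 0.5, 1.5),
                caliper_sigma_mm = c(0, 0.5, 1.5),
                frame_track_rot_deg = c(0, 0.2, 0.6),
                frame_track_trans_mm = c(0, 0.7, 2))
  for (param in names(grids)) {
    rms <- vapply(grids[[param]], function(v) {
      nm <- do.call(noise_model, stats::setNames(list(v), param))
      ov <- simulate_overlay_experiment(noise = nm, n_positions = 125,
                                        seed = 13)
      sqrt(mean(ov$error_mm^2))
    }, numeric(1))
    expect_true(all(diff(rms) > 0), label = paste("monotone in", param))
  }
})

test_that("independent frame and needle noise add in variance", {
  base <- list(n_poses = 400, seed = 17)
  nm_frame <- noise_model(frame_track_rot_deg = 0.3,
                          frame_track_trans_mm = 1)
  nm_needle <- noise_model(needle_track_rot_deg = 0.3,
                           needle_track_trans_mm = 1)
  nm_both <- noise_model(frame_track_rot_deg = 0.3, frame_track_trans_mm = 1,
                         needle_track_rot_deg = 0.3,
                         needle_track_trans_mm = 1)
  msq <- function(nm) {
    tg <- simulate_targeting_experiment(noise = nm, n_poses = base$n_poses,
                                        seed = base$seed)
    mean(tg$error_mm^2)
  }
  va <- msq(nm_frame); vb <- msq(nm_needle); vc <- msq(nm_both)
  expect_equal(vc, va + vb, tolerance = 0.1)
})

test_that("placement error dominates targeting error under shared noise", {
  nm <- calibrated_noise_model()
  tg <- do.call(rbind, lapply(1:6, function(s)
    simulate_targeting_experiment(noise = nm, seed = s)))
  pl <- do.call(rbind, lapply(1:6, function(s)
    simulate_placement_experiment(noise = nm, seed = s)))
  expect_gte(sqrt(mean(pl$error_mm^2)), sqrt(mean(tg$error_mm^2)))
})

test_that("out-of-plane lever arm increases TRE for the coplanar plate", {
  frame <- build_patient_frame()
  ctr <- colMeans(frame$fiducials$points)
  n <- frame$upper_normal
  targets <- t(vapply(c(10, 50, 100, 150), function(d) ctr + d * n,
                      numeric(3)))
  m <- mc_tre(frame$fiducials, 1, targets, n_reps = 2000, seed = 19)
  expect_true(all(diff(m$per_target_rms_mm) > 0))
})

test_that("trial tables round-trip through CSV with embedded comments", {
  tr <- simulate_targeting_experiment(noise = calibrated_noise_model(),
                                      seed = 23)
  f <- tempfile(fileext = ".csv")
  write_trials_csv(tr, f, header_comments = c("seed: 23", "config_md5: x"))
  expect_true(startsWith(readLines(f, n = 1), "# seed"))
  tr2 <- read_trials_csv(f)
  expect_equal(tr2$error_mm, tr$error_mm, tolerance = 1e-12)
  expect_identical(tr2$target_id, tr$target_id)
})
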