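test_that("fiducial sets validate their invariants", {
  expect_error(fiducial_set(c("a", "b"), rbind(c(0, 0, 0), c(1, 0, 0))),
               "at least 3")
  expect_error(fiducial_set(c("a", "a", "b"),
                            rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "unique")
  expect_error(fiducial_set(c("a", "b", "c"),
                            rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("registration is exact on noise-free correspondences", {
  set.seed(71)
  src <- random_fiducials(7)
  fit <- register_fiducials(src, src)
  expect_transform_equal(fit$transform, identity_transform("IMAGE"))
  expect_lt(fit$fre_mm, 1e-9)

  t <- random_transform("IMAGE", "PATIENT_FRAME")
  tgt <- fiducial_set(src$labels, transform_points(t, src$points),
                      "PATIENT_FRAME")
  fit2 <- register_fiducials(src, tgt)
  expect_transform_equal(fit2$transform, t)
  expect_lt(fit2$fre_mm, 1e-9)
})

test_that("correspondence is by label, invariant to row order", {
  set.seed(81)
  src <- random_fiducials(7)
  t <- random_transform("IMAGE", "PATIENT_FRAME")
  perm <- sample(7)
  tgt <- fiducial_set(src$labels[perm],
                      transform_points(t, src$points)[perm, ],
                      "PATIENT_FRAME")
  fit <- register_fiducials(src, tgt)
  expect_transform_equal(fit$transform, t)
  bad <- fiducial_set(paste0("Q", 1:7), src$points, "PATIENT_FRAME")
  expect_error(register_fiducials(src, bad), "label mismatch")
})

test_that("FRE equals the RMS of the per-fiducial residuals", {
  set.seed(91)
  src <- random_fiducials(7)
  noisy <- fiducial_set(src$labels, src$points + rnorm(21, 0, 0.5),
                        "PATIENT_FRAME")
  fit <- register_fiducials(src, noisy)
  expect_equal(fit$fre_mm,
               sqrt(mean(fit$per_fiducial_residuals_mm^2)),
               tolerance = 1e-12)
  expect_gt(fit$fre_mm, 0)
})

test_that("the SVD fit matches a brute-force optimizer on small sets", {
  set.seed(101)
  for (n in c(4, 5, 7)) {
    src <- random_fiducials(n)
    t <- random_transform("IMAGE", "PATIENT_FRAME")
    tgt <- fiducial_set(src$labels,
                        transform_points(t, src$points) +
                          matrix(rnorm(3 * n, 0, 1), n, 3),
                        "PATIENT_FRAME")
    fit <- register_fiducials(src, tgt)
    fre_bf <- brute_force_register(src$points, tgt$points)
    expect_lt(abs(fit$fre_mm - fre_bf), 1e-6)
    expect_lte(fit$fre_mm, fre_bf + 1e-6)  # SVD optimum never worse
  }
})

test_that("model-object methods expose the fit coherently", {
  set.seed(111)
  src <- random_fiducials(7)
  t <- random_transform("IMAGE", "PATIENT_FRAME")
  tgt <- fiducial_set(src$labels,
                      transform_points(t, src$points) + rnorm(21, 0, 0.3),
                      "PATIENT_FRAME")
  fit <- register_fiducials(src, tgt)
  expect_equal(unname(fitted(fit)), unname(predict(fit)))
  expect_equal(predict(fit, c(0, 0, 0)),
               transform_points(fit$transform, c(0, 0, 0)))
  expect_length(residuals(fit), 7)
  expect_equal(dim(residuals(fit, type = "vector")), c(7L, 3L))
  expect_named(coef(fit),
               c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg"))
  s <- summary(fit)
  expect_equal(s$fle_est_mm, estimate_fle_from_fre(fit$fre_mm, 7))
  expect_output(print(s), "per-fiducial residuals")
  sims <- simulate(fit, nsim = 50, seed = 3)
  expect_length(sims, 50)
  expect_true(all(sims >= 0))
})

test_that("FLE inversion follows FLE = FRE * sqrt(N/(N-2))", {
  expect_equal(estimate_fle_from_fre(0, 7), 0)
  expect_equal(estimate_fle_from_fre(0.81, 7), 0.81 * sqrt(7 / 5))
  expect_equal(estimate_fle_from_fre(0.81, 7), 0.9584, tolerance = 1e-4)
  expect_error(estimate_fle_from_fre(1, 2), "undefined")
  expect_error(estimate_fle_from_fre(-1, 7), "non-negative")
})

test_that("simulated FRE follows the (N-2)/N identity", {
  frame <- build_patient_frame()
  fle <- 1.2
  fres <- simulate_fre(frame$fiducials, fle, n_reps = 20000, seed = 5)
  ratio <- mean(fres^2) / fle^2
  expect_equal(ratio, 5 / 7, tolerance = 0.02)
})

test_that("TRE prediction: centroid limit, zero-FLE limit, method agreement", {
  set.seed(121)
  fs <- random_fiducials(7, spread = 40)
  centroid <- colMeans(fs$points)
  cf <- predict_tre(fs, 1.5, centroid, "CLOSED_FORM")
  expect_equal(cf$tre_rms_mm, 1.5 / sqrt(7), tolerance = 1e-9)
  expect_equal(predict_tre(fs, 0, c(50, 50, 50), "MONTE_CARLO",
                           n_reps = 10, seed = 1)$tre_rms_mm, 0)
  target <- c(30, 90, -20)
  cf2 <- predict_tre(fs, 1, target, "CLOSED_FORM")
  mc2 <- predict_tre(fs, 1, target, "MONTE_CARLO", n_reps = 20000, seed = 2)
  expect_equal(mc2$tre_rms_mm, cf2$tre_rms_mm, tolerance = 0.03)
})

test_that("closed-form TRE refuses the coplanar frame plate", {
  frame <- build_patient_frame()
  expect_error(predict_tre(frame$fiducials, 1, c(0, 35, 80), "CLOSED_FORM"),
               "MONTE_CARLO")
  mc <- predict_tre(frame$fiducials, 1, c(0, 35, 80), "MONTE_CARLO",
                    n_reps = 2000, seed = 3)
  expect_gt(mc$tre_rms_mm, 0)
})

test_that("TRE grows with distance from the fiducial centroid along a ray", {
  frame <- build_patient_frame()
  ctr <- colMeans(frame$fiducials$points)
  dir <- c(0, -0.3, 1); dir <- dir / sqrt(sum(dir^2))
  targets <- t(vapply(c(20, 60, 100, 140), function(d) ctr + d * dir,
                      numeric(3)))
  # one call shares the noise draws across targets, so the comparison is paired
  m <- mc_tre(frame$fiducials, 1, targets, n_reps = 3000, seed = 7)
  expect_true(all(diff(m$per_target_rms_mm) > 0))
})

test_that("fiducial CSV round-trips losslessly", {
  set.seed(131)
  fs <- random_fiducials(7, space = "PATIENT_FRAME")
  f <- tempfile(fileext = ".csv")
  write_fiducial_csv(fs, f)
  fs2 <- read_fiducial_csv(f)
  expect_identical(fs2$labels, fs$labels)
  expect_identical(fs2$space, "PATIENT_FRAME")
  expect_equal(unname(fs2$points), unname(fs$points), tolerance = 1e-9)
})
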