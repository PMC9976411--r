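# shared fixtures and independent oracles, all generated in code

random_rotation <- function() {
  rotation_axis_angle(stats::rnorm(3), stats::runif(1, 0, 180))
}

random_transform <- function(source = "IMAGE", destination = "PATIENT_FRAME") {
  rigid_transform(random_rotation(), stats::runif(3, -50, 50),
                  source, destination)
}

random_fiducials <- function(n = 7, space = "IMAGE", spread = 40) {
  fiducial_set(paste0("P", seq_len(n)),
               matrix(stats::runif(3 * n, -spread, spread), n, 3),
               space)
}

# Independent brute-force rigid fit: numerical minimization of the sum of
# squared residuals over an axis-angle + translation parameterization,
# multi-started. Deliberately shares no code with the SVD solver.
brute_force_register <- function(X, Y, n_starts = 5) {
  obj <- function(par) {
    ang <- sqrt(sum(par[1:3]^2))
    R <- if (ang < 1e-12) diag(3) else
      rotation_axis_angle(par[1:3], ang * 180 / pi)
    sum((sweep(X %*% t(R), 2L, par[4:6], "+") - Y)^2)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- c(stats::rnorm(3, 0, 1), colMeans(Y) - colMeans(X))
    fit <- stats::optim(p0, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  sqrt(best$value / nrow(X))   # FRE of the brute-force optimum
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}

pose_needle <- needlenav:::.pose_needle
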