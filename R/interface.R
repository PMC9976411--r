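## Versioned run-configuration schema. Unknown keys are errors
## (fail-fast); angles are degrees, lengths mm throughout.

.known_config_keys <- list(
  top = c("schema_version", "seed", "n_positions", "n_poses", "n_operators",
          "noise", "guidance", "frame", "fre_mm", "n_fiducials"),
  noise = c("fle_sigma_mm", "caliper_sigma_mm", "frame_track_rot_deg",
            "frame_track_trans_mm", "needle_track_rot_deg",
            "needle_track_trans_mm", "operator_angle_deg",
            "operator_lateral_mm", "operator_depth_mm"),
  guidance = c("proximity_threshold_mm", "hit_threshold_mm",
               "alignment_threshold_deg", "depth_tolerance_mm",
               "extension_length_mm"),
  frame = c("window_mm", "upper_plate_mm", "plate_angle_deg",
            "fiducial_layout"))

.check_keys <- function(block, name) {
  unknown <- setdiff(names(block), .known_config_keys[[name]])
  if (length(unknown)) {
    stop("unknown config key(s) in ", name, " block: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  block
}

#' Default run configuration
#'
#' The defaults reproduce the accuracy-experiment protocols: 7 device
#' positions (so the overlay run emits 56 records), 3 needle poses per
#' bead (24 targeting trials), 3 operators (8 insertions each), and a
#' the calibrated full-chain noise model of [calibrated_noise_model()].
#'
#' @param seed integer seed stored in the config.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  nm <- calibrated_noise_model()
  structure(list(schema_version = 1, seed = seed,
                 n_positions = 7, n_poses = 3, n_operators = 3,
                 noise = unclass(nm)[.known_config_keys$noise],
                 guidance = unclass(guidance_config()),
                 frame = list()),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Validates the versioned schema and rejects unknown keys. Missing
#' blocks fall back to the defaults of [default_run_config()].
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  .check_keys(raw, "top")
  if (!identical(as.integer(raw$schema_version %||% 1L), 1L)) {
    stop("unsupported config schema_version: ", raw$schema_version,
         call. = FALSE)
  }
  cfg <- default_run_config(seed = raw$seed %||% 1L)
  for (k in c("n_positions", "n_poses", "n_operators")) {
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  }
  if (!is.null(raw$noise)) {
    .check_keys(raw$noise, "noise")
    cfg$noise[names(raw$noise)] <- raw$noise
  }
  if (!is.null(raw$guidance)) {
    .check_keys(raw$guidance, "guidance")
    cfg$guidance[names(raw$guidance)] <- raw$guidance
  }
  if (!is.null(raw$frame)) {
    .check_keys(raw$frame, "frame")
    cfg$frame <- raw$frame
  }
  cfg
}

#' Write a run configuration as YAML
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  ## yaml drops names on atomic vectors; promote named vectors to maps
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
    else x
  }
  yaml::write_yaml(namify(unclass(config)), path)
  invisible(path)
}

#' MD5 hash of a run configuration
#'
#' Embedded in every simulator output so a run can be reproduced from
#' its own files.
#'
#' @param config a `run_config`.
#' @return Hex MD5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.cfg_noise <- function(config) do.call(noise_model, config$noise)
.cfg_guidance <- function(config) do.call(guidance_config, config$guidance)

#' Run a registration between two fiducial CSV files
#'
#' @param source_csv,target_csv fiducial CSV paths (same labels).
#' @param out optional path for the transform JSON; when `NULL` the JSON
#'   is printed to standard output.
#' @return The `rigid_registration` fit, invisibly.
#' @export
run_register <- function(source_csv, target_csv, out = NULL) {
  src <- read_fiducial_csv(source_csv)
  tgt <- read_fiducial_csv(target_csv)
  fit <- register_fiducials(src, tgt)
  js <- transform_to_json(fit$transform)
  payload <- sprintf('{"transform": %s, "fre_mm": %s}', js,
                     jsonlite::toJSON(fit$fre_mm, auto_unbox = TRUE,
                                      digits = NA))
  if (is.null(out)) cat(payload, "\n", sep = "") else writeLines(payload, out)
  message(sprintf("registered %d fiducials: FRE %.4f mm",
                  fit$n_fiducials, fit$fre_mm))
  invisible(fit)
}

#' Run one simulated experiment from a run configuration
#'
#' @param experiment `"overlay"`, `"targeting"` or `"placement"`.
#' @param config a `run_config` (default [default_run_config()]).
#' @param seed overrides the config seed when given.
#' @param out optional trial-CSV path; the file embeds the seed and
#'   config hash as `#` comments.
#' @param summary_out optional path for a JSON file of per-grouping
#'   summary statistics.
#' @return The trial data.frame, invisibly.
#' @export
run_simulate <- function(experiment = c("overlay", "targeting", "placement"),
                         config = default_run_config(), seed = NULL,
                         out = NULL, summary_out = NULL) {
  experiment <- match.arg(experiment)
  seed <- as.integer(seed %||% config$seed)
  config$seed <- seed
  frame <- build_patient_frame(config$frame)
  noise <- .cfg_noise(config)
  trials <- switch(experiment,
    overlay = simulate_overlay_experiment(frame, noise = noise,
                                          n_positions = config$n_positions,
                                          seed = seed),
    targeting = simulate_targeting_experiment(frame, noise = noise,
                                              n_poses = config$n_poses,
                                              seed = seed),
    placement = simulate_placement_experiment(
      exp2 = build_exp2_scene(seed = seed, frame = frame),
      noise = noise, n_operators = config$n_operators, frame = frame,
      config = .cfg_guidance(config), seed = seed))
  h <- config_hash(config)
  if (!is.null(out)) {
    write_trials_csv(trials, out,
                     header_comments = c(paste0("seed: ", seed),
                                         paste0("config_md5: ", h)))
  }
  if (!is.null(summary_out)) {
    grp <- if (experiment == "placement") trials$method else trials$target_id
    sums <- lapply(split(trials$error_mm, grp), function(v) {
      s <- summarize_values(v); list(mean = s$mean, sd = s$sd, n = s$n)
    })
    all_s <- summarize_values(trials$error_mm)
    jsonlite::write_json(list(experiment = experiment, seed = seed,
                              config_md5 = h,
                              overall = list(mean = all_s$mean, sd = all_s$sd,
                                             n = all_s$n),
                              by_group = sums),
                         summary_out, auto_unbox = TRUE, digits = NA)
  }
  message(sprintf("%s: %d trials, error %.3f +/- %.3f mm", experiment,
                  nrow(trials), mean(trials$error_mm),
                  stats::sd(trials$error_mm)))
  invisible(trials)
}

#' Compare trial groups, or printed summaries, per the analysis plan
#'
#' @param trials_csv trial CSV path (ignored in summary mode).
#' @param compare column of the trial table defining the two groups;
#'   default `"method"`.
#' @param alpha normality-gate level.
#' @param summary optional numeric vector
#'   `c(mean_a, sd_a, n_a, mean_b, sd_b, n_b)`: recompute a Student's
#'   t-test from printed summaries instead of reading trials.
#' @param out optional JSON report path; otherwise printed to stdout.
#' @return The `comparison_result`, invisibly.
#' @export
run_stats <- function(trials_csv = NULL, compare = "method", alpha = 0.05,
                      summary = NULL, out = NULL) {
  res <- if (!is.null(summary)) {
    s <- as.numeric(summary)
    if (length(s) != 6L) stop("--summary needs 6 numbers: ",
                              "mean_a,sd_a,n_a,mean_b,sd_b,n_b", call. = FALSE)
    t_test_from_summary(s[1], s[2], s[3], s[4], s[5], s[6])
  } else {
    trials <- read_trials_csv(trials_csv)
    if (!compare %in% names(trials)) {
      stop("no column '", compare, "' in trial table", call. = FALSE)
    }
    groups <- split(trials$error_mm, trials[[compare]])
    if (length(groups) != 2L) {
      stop("comparison column must define exactly 2 groups, got ",
           length(groups), call. = FALSE)
    }
    compare_groups(groups[[1]], groups[[2]], alpha = alpha)
  }
  report <- list(test_name = res$test_name, statistic = res$statistic,
                 df = res$df, p_value = res$p_value, gate = res$gate)
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(out)) cat(as.character(js), "\n", sep = "")
  else writeLines(as.character(js), out)
  invisible(res)
}

#' Build and serialize a named fixture scene
#'
#' @param name `"pelvic"`, `"exp1-50"`, `"exp1-100"` or `"exp2"`.
#' @param out output JSON path (scene) — for `"exp2"` a second file
#'   `<out>.plans.csv` receives the insertion plans.
#' @param seed seed for the seeded scenes.
#' @return The scene, invisibly.
#' @export
run_make_scene <- function(name = c("pelvic", "exp1-50", "exp1-100", "exp2"),
                           out, seed = 1) {
  name <- match.arg(name)
  scene <- switch(name,
                  "pelvic" = build_pelvic_scene(),
                  "exp1-50" = build_exp1_plate(50),
                  "exp1-100" = build_exp1_plate(100),
                  "exp2" = {
                    e <- build_exp2_scene(seed = seed)
                    write_plans_csv(e$plans, paste0(out, ".plans.csv"))
                    e$scene
                  })
  scene_to_json(scene, out)
  message("wrote scene '", scene$name, "' to ", out)
  invisible(scene)
}

## --- minimal CLI argument handling -----------------------------------

.cli_opts <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

.cli_usage <- function() {
  paste(
    "usage: needlenav <command> [args]",
    "",
    "commands:",
    "  register <source.csv> <target.csv> [--out transform.json]",
    "  simulate <overlay|targeting|placement> [--config cfg.yaml]",
    "           [--seed N] [--out trials.csv] [--summary-out summary.json]",
    "  calibrate-fle --fre <mm> --n <fiducials>",
    "  stats [trials.csv] [--compare column] [--alpha a]",
    "        [--summary m1,s1,n1,m2,s2,n2] [--out report.json]",
    "  make-scene <pelvic|exp1-50|exp1-100|exp2> --out scene.json [--seed N]",
    sep = "\n")
}

#' Command-line entry point
#'
#' Dispatches the `register`, `simulate`, `calibrate-fle`, `stats` and
#' `make-scene` subcommands; the installed `inst/cli/needlenav` script
#' is a thin wrapper around this function. Data goes to files or
#' standard output; log messages go to standard error.
#'
#' @param argv character vector of command-line arguments (without the
#'   program name).
#' @return Integer exit status, invisibly (0 on success).
#' @export
needlenav_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L) {
      cat(.cli_usage(), "\n")
      return(invisible(2L))
    }
    cmd <- argv[[1]]
    parsed <- .cli_opts(argv[-1])
    opts <- parsed$opts; pos <- parsed$pos
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
           else default_run_config()
    switch(cmd,
      register = {
        if (length(pos) != 2L) stop("register needs 2 CSV paths", call. = FALSE)
        run_register(pos[1], pos[2], out = opts$out)
      },
      simulate = {
        if (length(pos) != 1L) stop("simulate needs an experiment name",
                                    call. = FALSE)
        run_simulate(pos[1], config = cfg, seed = opts$seed,
                     out = opts$out, summary_out = opts[["summary-out"]])
      },
      `calibrate-fle` = {
        if (is.null(opts$fre) || is.null(opts$n)) {
          stop("calibrate-fle needs --fre and --n", call. = FALSE)
        }
        fle <- estimate_fle_from_fre(as.numeric(opts$fre),
                                     as.integer(opts$n))
        cat(jsonlite::toJSON(list(fre_mm = as.numeric(opts$fre),
                                  n_fiducials = as.integer(opts$n),
                                  fle_mm = fle,
                                  per_axis_sigma_mm = fle / sqrt(3)),
                             auto_unbox = TRUE, digits = NA), "\n", sep = "")
      },
      stats = {
        smry <- if (!is.null(opts$summary))
          as.numeric(strsplit(opts$summary, ",")[[1]])
        run_stats(trials_csv = if (length(pos)) pos[1],
                  compare = opts$compare %||% "method",
                  alpha = as.numeric(opts$alpha %||% 0.05),
                  summary = smry, out = opts$out)
      },
      `make-scene` = {
        if (length(pos) != 1L || is.null(opts$out)) {
          stop("make-scene needs a scene name and --out", call. = FALSE)
        }
        run_make_scene(pos[1], out = opts$out,
                       seed = as.integer(opts$seed %||% 1L))
      },
      {
        cat(.cli_usage(), "\n")
        stop("unknown command: ", cmd, call. = FALSE)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
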