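#' Analyze a batch of trial logs
#'
#' Reads every trial CSV, computes the full metric bundle per trial, and
#' optionally writes the metrics table, per-trial episode/bite/TE tables and
#' a YAML run manifest (config snapshot, inputs, seeds, timing) so a run can
#' be reproduced exactly.
#'
#' @param paths character vector of trial CSV paths.
#' @param config an [arena_config()].
#' @param seed base seed; trial i uses \code{seed + i - 1} for its
#'   attraction shuffles.
#' @param out_dir optional output directory for CSV tables and the manifest.
#' @param eye_frames passed to [trial_metrics()].
#' @return Data frame of per-(trial, fish) metric rows (invisibly also
#'   written to \code{out_dir}). Unreadable files are skipped with a
#'   warning; an empty input set is an error.
#' @export
analyze_trials <- function(paths, config = arena_config(), seed = 1,
                           out_dir = NULL, eye_frames = "all") {
  if (!length(paths)) stop("analyze_trials: empty input set")
  t0 <- Sys.time()
  rows <- list(); used <- character()
  for (i in seq_along(paths)) {
    tm <- tryCatch({
      trial <- read_trial(paths[i], config)
      trial$pair_id <- basename(paths[i])
      trial_metrics(trial, config, seed = seed + i - 1,
                    eye_frames = eye_frames)
    }, error = function(e) {
      warning("analyze_trials: skipping '", paths[i], "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(tm)) next
    rows[[length(rows) + 1L]] <- as.data.frame(tm)
    used <- c(used, paths[i])
  }
  if (!length(rows)) stop("analyze_trials: no readable trials")
  metrics <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "trial_metrics.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("dyadvr")),
      inputs = used, seed = seed, eye_frames = eye_frames,
      config = lapply(unclass(config), function(v)
        if (is.matrix(v)) apply(v, 1, as.numeric, simplify = FALSE) else v),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  metrics
}

#' Simulate and write a batch of synthetic trials
#'
#' @param n number of trials (>= 1).
#' @param params a [sim_params()]; trial i is generated with seed
#'   \code{params$seed + i - 1}.
#' @param out_dir output directory for the trial CSVs.
#' @param config an [arena_config()].
#' @return Character vector of written paths.
#' @export
simulate_trials <- function(n, params = sim_params(), out_dir,
                            config = arena_config()) {
  if (n < 1L) stop("simulate_trials: n must be at least 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_len(n), function(i) {
    p <- params; p$seed <- params$seed + i - 1
    trial <- generate_dyad(p, config)
    path <- file.path(out_dir, sprintf("trial_%03d.csv", i))
    write_trial(trial, path)
    path
  }, "")
}

#' Write the standard fixture suite
#'
#' Emits small trial CSVs with known ground truth: a null dyad (independent
#' walks), a follower dyad (speed coupling a to b), a left-biased dyad, the
#' two scripted approach fixtures (a successful binocular strike and a
#' persistent left-eye miss), and a bite-block trajectory holding a
#' multi-frame collision.
#'
#' @param out_dir output directory.
#' @param config an [arena_config()].
#' @param n_frames length of the stochastic fixtures (default 2000).
#' @return Named character vector of written paths.
#' @export
write_fixtures <- function(out_dir, config = arena_config(),
                           n_frames = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(
    null = write_trial(
      generate_dyad(sim_params(n_frames = n_frames, seed = 101), config),
      file.path(out_dir, "null_dyad.csv")),
    follower = write_trial(
      generate_dyad(sim_params(n_frames = n_frames, seed = 102,
                               coupling_gain = 0.8), config),
      file.path(out_dir, "follower_dyad.csv")),
    left_biased = write_trial(
      generate_dyad(sim_params(n_frames = n_frames, seed = 103,
                               attraction_gain = 0.2, lateral_bias = 60),
                    config),
      file.path(out_dir, "left_biased_dyad.csv")),
    strike = write_trial(
      generate_scripted_approach(90, 13, "binocular_homing", config = config),
      file.path(out_dir, "scripted_strike.csv")),
    miss = write_trial(
      generate_scripted_approach(90, 30, "left_persistent", config = config),
      file.path(out_dir, "scripted_miss.csv")),
    bite_block = write_trial(bite_block_trial(config),
                             file.path(out_dir, "bite_block.csv"))
  )
  out
}

# hand-built trajectory holding one contiguous multi-frame mouth/mid-body
# collision (frames 5..9) for rising-edge bite tests
bite_block_trial <- function(config = arena_config()) {
  n <- 15
  half <- config$avatar_length / 2
  # victim at origin, body along +y; biter approaches along +x, heading 180
  xs <- c(seq(40, half + 1, length.out = 5),
          rep(half + 1, 5),
          seq(half + 6, 40, length.out = 5))
  a <- data.frame(t = 0:(n - 1), x = xs, y = 0, heading = 180,
                  speed = 10, turn = 0)
  b <- data.frame(t = 0:(n - 1), x = 0, y = 0, heading = 90,
                  speed = 0, turn = 0)
  dyad_trial(a, b, frame_interval_ms = config$frame_interval_ms)
}
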