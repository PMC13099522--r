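#' Construct a dyadic trial from two frame-aligned trajectories
#'
#' A trial holds the per-frame logs of the two interacting agents. Each
#' trajectory is a data frame with one row per frame and columns \code{t}
#' (0-based frame index), \code{x}, \code{y} (arena coordinates, origin at the
#' arena center), \code{heading} (degrees, counterclockwise from the +x axis,
#' wrapped to (-180, 180]), \code{speed} (VR units/s, nonnegative) and
#' \code{turn} (degrees/s, signed).
#'
#' @param fish_a,fish_b trajectory data frames as described above, with
#'   identical frame indices.
#' @param pair_id identifier of the fish pair.
#' @param condition \code{"no_shock"} or \code{"shock"}.
#' @param genotype_pair \code{"WT_WT"} or \code{"WT_TG"}.
#' @param frame_interval_ms frame interval in milliseconds.
#' @return An object of class \code{"dyad_trial"}.
#' @export
dyad_trial <- function(fish_a, fish_b, pair_id = "pair1",
                       condition = c("no_shock", "shock"),
                       genotype_pair = c("WT_WT", "WT_TG"),
                       frame_interval_ms = 100) {
  condition <- match.arg(condition)
  genotype_pair <- match.arg(genotype_pair)
  fish_a <- as_traj(fish_a, "fish_a")
  fish_b <- as_traj(fish_b, "fish_b")
  if (nrow(fish_a) == 0L) stop("dyad_trial: trial must contain at least one frame")
  if (nrow(fish_a) != nrow(fish_b) || any(fish_a$t != fish_b$t))
    stop("dyad_trial: fish_a and fish_b must have identical frame indices")
  structure(
    list(pair_id = pair_id, condition = condition,
         genotype_pair = genotype_pair, fish_a = fish_a, fish_b = fish_b,
         frame_interval_ms = frame_interval_ms),
    class = "dyad_trial"
  )
}

traj_cols <- c("t", "x", "y", "heading", "speed", "turn")

as_traj <- function(df, what) {
  df <- as.data.frame(df)
  missing <- setdiff(traj_cols, names(df))
  if (length(missing))
    stop("dyad_trial: ", what, " is missing columns: ",
         paste(missing, collapse = ", "))
  df <- df[order(df$t), traj_cols, drop = FALSE]
  rownames(df) <- NULL
  df$heading <- wrap_angle(df$heading)
  df
}

#' Wrap angles (degrees) to the interval (-180, 180]
#'
#' @param a numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- a %% 360
  ifelse(w > 180, w - 360, w)
}

#' @export
print.dyad_trial <- function(x, ...) {
  cat(sprintf("Dyadic VR trial '%s' (%s, %s): %d frames @ %g ms\n",
              x$pair_id, x$condition, x$genotype_pair,
              nrow(x$fish_a), x$frame_interval_ms))
  invisible(x)
}

#' @export
summary.dyad_trial <- function(object, config = arena_config(), ...) {
  d <- mutual_distance_series(object)
  cat(sprintf("Trial '%s': %d frames (%.1f min), condition %s\n",
              object$pair_id, length(d),
              length(d) * object$frame_interval_ms / 60000, object$condition))
  cat(sprintf("  mutual distance: mean %.2f, range [%.2f, %.2f]\n",
              mean(d), min(d), max(d)))
  cat(sprintf("  near rate %.1f%%, attraction-ready frames %d\n",
              near_rate(object, config), length(d)))
  invisible(object)
}

#' Number of frames in a trial
#' @param trial a \code{dyad_trial}.
#' @return Integer frame count.
#' @export
n_frames <- function(trial) nrow(trial$fish_a)

#' Read a dyadic trial log
#'
#' Trial logs are long-form CSV with header columns \code{frame, fish_id, x,
#' y, heading, speed, turn} and exactly two fish ids; \code{speed} and
#' \code{turn} are per-second quantities. Rows are sorted by frame and
#' headings wrapped to (-180, 180] on read.
#'
#' @param path path to a CSV trial log.
#' @param config an [arena_config()]; supplies the frame interval.
#' @param ... further fields passed to [dyad_trial()] (pair_id, condition,
#'   genotype_pair).
#' @return A \code{"dyad_trial"}.
#' @export
read_trial <- function(path, config = arena_config(), ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "fish_id", "x", "y", "heading", "speed", "turn")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_trial: missing columns: ", paste(missing, collapse = ", "))
  num_cols <- c("frame", "x", "y", "heading", "speed", "turn")
  for (cc in num_cols) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(!is.finite(df[[cc]])))
      stop("read_trial: non-finite values in column '", cc, "'")
  }
  ids <- sort(unique(df$fish_id))
  if (length(ids) != 2L)
    stop("read_trial: expected exactly two fish ids, found ", length(ids))
  split_one <- function(id) {
    sub <- df[df$fish_id == id, , drop = FALSE]
    data.frame(t = sub$frame, x = sub$x, y = sub$y, heading = sub$heading,
               speed = sub$speed, turn = sub$turn)
  }
  a <- split_one(ids[1]); b <- split_one(ids[2])
  if (nrow(a) != nrow(b) || !setequal(a$t, b$t))
    stop("read_trial: frame sets differ between fish '", ids[1], "' and '",
         ids[2], "'")
  dyad_trial(a, b, frame_interval_ms = config$frame_interval_ms, ...)
}

#' Write a dyadic trial log
#'
#' Emits the long-form CSV accepted by [read_trial()], numeric fields at six
#' decimal places so that a written trial reads back bit-identically at that
#' precision.
#'
#' @param trial a \code{dyad_trial}.
#' @param path output path.
#' @param fish_ids character ids written for the two fish; must sort in
#'   (fish_a, fish_b) order so the round trip preserves identity.
#' @return Invisibly, \code{path}.
#' @export
write_trial <- function(trial, path, fish_ids = c("a", "b")) {
  stopifnot(inherits(trial, "dyad_trial"))
  if (n_frames(trial) == 0L) stop("write_trial: empty trial")
  if (length(fish_ids) != 2L || is.unsorted(fish_ids))
    stop("write_trial: fish_ids must be two ids in sorted order")
  fmt <- function(traj, id)
    data.frame(frame = traj$t, fish_id = id,
               x = sprintf("%.6f", traj$x), y = sprintf("%.6f", traj$y),
               heading = sprintf("%.6f", traj$heading),
               speed = sprintf("%.6f", traj$speed),
               turn = sprintf("%.6f", traj$turn))
  out <- rbind(fmt(trial$fish_a, fish_ids[1]), fmt(trial$fish_b, fish_ids[2]))
  out <- out[order(out$frame, out$fish_id), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trial against the arena geometry
#'
#' Report-only: returns a data frame of violations (possibly empty) and never
#' raises. Checked: all numeric fields finite, positions inside the arena,
#' headings within (-180, 180], nonnegative speeds.
#'
#' @param trial a \code{dyad_trial}.
#' @param config an [arena_config()].
#' @return Data frame with columns \code{fish}, \code{t}, \code{field},
#'   \code{problem}.
#' @export
validate_trial <- function(trial, config = arena_config()) {
  out <- list()
  add <- function(fish, t, field, problem)
    out[[length(out) + 1L]] <<- data.frame(fish = fish, t = t, field = field,
                                           problem = problem)
  for (fish in c("fish_a", "fish_b")) {
    traj <- trial[[fish]]
    for (cc in c("x", "y", "heading", "speed", "turn")) {
      bad <- which(!is.finite(traj[[cc]]))
      for (i in bad) add(fish, traj$t[i], cc, "non-finite value")
    }
    r <- sqrt(traj$x^2 + traj$y^2)
    for (i in which(is.finite(r) & r > config$arena_radius))
      add(fish, traj$t[i], "pos", "outside arena")
    h <- traj$heading
    for (i in which(is.finite(h) & (h <= -180 | h > 180)))
      add(fish, traj$t[i], "heading", "outside (-180, 180]")
    for (i in which(is.finite(traj$speed) & traj$speed < 0))
      add(fish, traj$t[i], "speed", "negative speed")
  }
  if (!length(out))
    return(data.frame(fish = character(), t = numeric(),
                      field = character(), problem = character()))
  do.call(rbind, out)
}
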