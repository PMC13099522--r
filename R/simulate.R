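#' Simulation parameters for synthetic dyads
#'
#' Defaults reproduce the study's trial structure: 18000 frames of 100 ms
#' (30 min at 10 Hz) in the 100-unit arena with starts at (50, 0) and
#' (-50, 0).
#'
#' @param n_frames trial length in frames.
#' @param seed integer RNG seed (R's default Mersenne-Twister).
#' @param attraction_gain nonnegative heading-relaxation gain toward the
#'   opponent (0 = ignore opponent; 1 = face it instantly).
#' @param coupling_gain in [0, 1]: fish b's speed tracks fish a's previous
#'   frame speed with this weight (directional coupling for TE recovery).
#' @param lateral_bias degrees; > 0 biases the preferred bearing so the
#'   opponent is kept on the LEFT (negative bearings).
#' @param base_speed mean autonomous forward speed, units/s.
#' @param speed_noise_sd,heading_noise_sd Gaussian noise SDs (units/s,
#'   degrees/frame).
#' @param wall_mode \code{"steer_away"} (turn toward the arena center on
#'   contact) or \code{"reflect"} (mirror the heading across the wall
#'   tangent).
#' @return A \code{"sim_params"} list.
#' @export
sim_params <- function(n_frames = 18000, seed = 1, attraction_gain = 0,
                       coupling_gain = 0, lateral_bias = 0,
                       base_speed = 20, speed_noise_sd = 5,
                       heading_noise_sd = 10,
                       wall_mode = c("steer_away", "reflect")) {
  wall_mode <- match.arg(wall_mode)
  stopifnot(n_frames >= 2, attraction_gain >= 0,
            coupling_gain >= 0, coupling_gain <= 1,
            speed_noise_sd >= 0, heading_noise_sd >= 0, base_speed > 0)
  structure(list(n_frames = n_frames, seed = seed,
                 attraction_gain = attraction_gain,
                 coupling_gain = coupling_gain, lateral_bias = lateral_bias,
                 base_speed = base_speed, speed_noise_sd = speed_noise_sd,
                 heading_noise_sd = heading_noise_sd, wall_mode = wall_mode),
            class = "sim_params")
}

#' Generate a synthetic dyadic trial
#'
#' Kinematic point-agents with heading: per frame each fish turns by
#' \code{attraction_gain} times the wrapped angle from its heading to the
#' (laterally biased) direction of the opponent, plus Gaussian noise, then
#' advances along its heading at its current speed. Fish a's speed is
#' autonomous noise around \code{base_speed}; fish b's speed mixes fish a's
#' previous-frame speed with weight \code{coupling_gain} into its own
#' autonomous speed, giving a known direction of information flow. Agents
#' stay inside the arena via \code{wall_mode}. Deterministic given the seed.
#'
#' @param params a [sim_params()] list.
#' @param config an [arena_config()].
#' @param ... metadata passed to [dyad_trial()].
#' @return A \code{"dyad_trial"}.
#' @export
generate_dyad <- function(params = sim_params(), config = arena_config(),
                          ...) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  n <- params$n_frames
  dt <- config$frame_interval_ms / 1000
  R <- config$arena_radius
  # pre-draw all noise so the per-frame loop is cheap
  hn <- matrix(stats::rnorm(2 * n, 0, params$heading_noise_sd), n, 2)
  sn <- matrix(stats::rnorm(2 * n, 0, params$speed_noise_sd), n, 2)
  x <- matrix(0, n, 2); y <- matrix(0, n, 2)
  h <- matrix(0, n, 2); sp <- matrix(0, n, 2)
  x[1, ] <- config$start_positions[, 1]
  y[1, ] <- config$start_positions[, 2]
  h[1, ] <- c(90, 90)                      # start side by side, parallel
  sp[1, ] <- pmax(0, params$base_speed + sn[1, ])
  g <- params$attraction_gain
  cg <- params$coupling_gain
  bias <- params$lateral_bias
  for (t in 2:n) {
    for (i in 1:2) {
      j <- 3 - i
      dx <- x[t - 1, j] - x[t - 1, i]; dy <- y[t - 1, j] - y[t - 1, i]
      turn <- if (g > 0 && (dx != 0 || dy != 0)) {
        theta <- atan2(dy, dx) * 180 / pi
        g * wrap_angle(theta - h[t - 1, i] - bias)
      } else 0
      hh <- wrap_angle(h[t - 1, i] + turn + hn[t, i])
      auto <- params$base_speed + sn[t, i]
      s <- if (i == 2L && cg > 0) cg * sp[t - 1, 1] + (1 - cg) * auto else auto
      s <- max(0, s)
      nx <- x[t - 1, i] + s * dt * cos(hh * pi / 180)
      ny <- y[t - 1, i] + s * dt * sin(hh * pi / 180)
      r <- sqrt(nx^2 + ny^2)
      if (r > R) {
        phi <- atan2(ny, nx) * 180 / pi
        scl <- (R - 1e-9) / r        # strictly inside under floating round-off
        nx <- nx * scl; ny <- ny * scl
        hh <- if (params$wall_mode == "steer_away")
          wrap_angle(phi + 180)
        else                                   # reflect across wall tangent
          wrap_angle(2 * phi + 180 - hh)
      }
      x[t, i] <- nx; y[t, i] <- ny; h[t, i] <- hh; sp[t, i] <- s
    }
  }
  mk <- function(i) data.frame(
    t = 0:(n - 1), x = x[, i], y = y[, i], heading = h[, i], speed = sp[, i],
    turn = c(0, wrap_angle(diff(h[, i]))) / dt)
  dyad_trial(mk(1), mk(2), frame_interval_ms = config$frame_interval_ms, ...)
}

#' Generate a scripted approach fragment
#'
#' One agent homes in on a static target standing at the arena center
#' (body axis along +y) while its bearing to the target follows a specified
#' profile, producing exactly one detectable approach with a known view-label
#' sequence. Profiles: \code{"binocular_homing"} starts with the target in
#' the RIGHT monocular field and swings it into the BINOCULAR field for the
#' second half (a successful strike when \code{stop_distance} is small
#' enough to trigger the mouth/mid-body collision); \code{"left_persistent"}
#' keeps the target in the LEFT field throughout and misses. A custom
#' profile may be given as a numeric vector of per-frame bearings (degrees,
#' within the +/-90 toward cone).
#'
#' @param start_distance,stop_distance initial and final distance to the
#'   target; \code{stop_distance < start_distance}.
#' @param profile \code{"binocular_homing"}, \code{"left_persistent"}, or a
#'   numeric bearing vector of length \code{n_frames}.
#' @param n_frames number of frames (default 40).
#' @param config an [arena_config()].
#' @param ... metadata passed to [dyad_trial()].
#' @return A \code{"dyad_trial"} (approacher = fish a, target = fish b).
#' @export
generate_scripted_approach <- function(start_distance, stop_distance,
                                       profile = "binocular_homing",
                                       n_frames = 40,
                                       config = arena_config(), ...) {
  if (stop_distance >= start_distance)
    stop("generate_scripted_approach: stop_distance must be below start_distance")
  if (is.character(profile)) {
    profile <- match.arg(profile, c("binocular_homing", "left_persistent"))
    half <- floor(n_frames / 2)
    bearing <- switch(profile,
      binocular_homing = c(seq(60, 31, length.out = half),
                           seq(25, 0, length.out = n_frames - half)),
      left_persistent = rep(-60, n_frames))
  } else {
    bearing <- as.numeric(profile)
    if (length(bearing) != n_frames)
      stop("generate_scripted_approach: profile length must equal n_frames")
    if (any(abs(bearing) > config$toward_range_halfwidth))
      stop("generate_scripted_approach: infeasible profile (outside toward cone)")
  }
  d <- seq(start_distance, stop_distance, length.out = n_frames)
  dt <- config$frame_interval_ms / 1000
  # approacher advances along +x toward the target at the origin
  ax <- d; ay <- rep(0, n_frames)
  theta_to_target <- 180                     # target seen along -x
  heading <- wrap_angle(theta_to_target + bearing)
  speed <- c(-diff(d) / dt, (d[n_frames - 1] - d[n_frames]) / dt)
  appr <- data.frame(t = 0:(n_frames - 1), x = ax, y = ay, heading = heading,
                     speed = speed,
                     turn = c(0, wrap_angle(diff(heading))) / dt)
  tgt <- data.frame(t = 0:(n_frames - 1), x = 0, y = 0, heading = 90,
                    speed = 0, turn = 0)
  dyad_trial(appr, tgt, frame_interval_ms = config$frame_interval_ms, ...)
}

#' Generate directionally coupled symbol series
#'
#' The leader is i.i.d. uniform on \code{0..K-1}; the follower copies the
#' leader's previous symbol with probability \code{coupling} and otherwise
#' draws uniformly. The true leader-to-follower transfer entropy of this
#' channel is available in closed form via [coupled_symbols_te()].
#'
#' @param K alphabet size (>= 2).
#' @param n series length.
#' @param coupling copy probability in [0, 1].
#' @param seed integer seed.
#' @return List with integer symbol vectors \code{leader} and
#'   \code{follower} (attribute \code{K} set on both).
#' @export
generate_coupled_symbols <- function(K, n, coupling, seed = 1) {
  stopifnot(K >= 2, coupling >= 0, coupling <= 1, n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  leader <- sample.int(K, n, replace = TRUE) - 1L
  copy <- stats::runif(n) < coupling
  rand <- sample.int(K, n, replace = TRUE) - 1L
  follower <- ifelse(copy, c(0L, leader[-n]), rand)
  follower[1] <- rand[1]                     # no predecessor to copy
  attr(leader, "K") <- as.integer(K); attr(follower, "K") <- as.integer(K)
  list(leader = leader, follower = follower)
}

#' Closed-form channel transfer entropy of the coupled-symbol generator
#'
#' For the copy-with-probability-c channel over a uniform i.i.d. leader the
#' follower's marginal is uniform and independent of its own past, so
#' \eqn{T = \log_2 K - H(F_t | L_{t-1})} with the conditional distribution
#' putting mass \eqn{c + (1-c)/K} on the copied symbol and \eqn{(1-c)/K}
#' elsewhere.
#'
#' @param K alphabet size.
#' @param coupling copy probability.
#' @return True transfer entropy in bits.
#' @export
coupled_symbols_te <- function(K, coupling) {
  p_copy <- coupling + (1 - coupling) / K
  p_other <- (1 - coupling) / K
  plog <- function(p) ifelse(p > 0, p * log2(p), 0)
  h_cond <- -(plog(p_copy) + (K - 1) * plog(p_other))
  log2(K) - h_cond
}
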