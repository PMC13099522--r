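#' Signed relative bearing from an observer to a target
#'
#' The bearing is the angle from the observer's heading to the
#' observer-to-target direction, wrapped to (-180, 180]. Negative bearings
#' put the target on the observer's LEFT, matching the left monocular field
#' being the interval [-135, -30).
#'
#' @param x,y observer position (vectors allowed).
#' @param heading observer heading, degrees CCW from +x.
#' @param tx,ty target position.
#' @return Bearing(s) in degrees in (-180, 180].
#' @export
relative_bearing <- function(x, y, heading, tx, ty) {
  dx <- tx - x; dy <- ty - y
  if (any(dx == 0 & dy == 0))
    stop("relative_bearing: observer and target positions coincide")
  theta <- atan2(dy, dx) * 180 / pi
  wrap_angle(heading - theta)
}

#' Classify a bearing into the view-field partition
#'
#' The horizontal 270-degree view is split into LEFT [-135, -30), BINOCULAR
#' [-30, 30] and RIGHT (30, 135]; everything else is the BLIND spot. Each
#' bearing receives exactly one label.
#'
#' @param bearing numeric vector of bearings in (-180, 180].
#' @param config an [arena_config()].
#' @return Factor with levels LEFT, BINOCULAR, RIGHT, BLIND.
#' @export
classify_view <- function(bearing, config = arena_config()) {
  l <- config$left_eye_range; b <- config$binocular_range
  r <- config$right_eye_range
  lab <- rep("BLIND", length(bearing))
  lab[bearing >= l[1] & bearing < l[2]] <- "LEFT"
  lab[bearing >= b[1] & bearing <= b[2]] <- "BINOCULAR"
  lab[bearing > r[1] & bearing <= r[2]] <- "RIGHT"
  factor(lab, levels = c("LEFT", "BINOCULAR", "RIGHT", "BLIND"))
}

#' Per-frame view labels of one fish toward its opponent
#'
#' @param trial a \code{dyad_trial}.
#' @param fish \code{"a"} or \code{"b"}: the observer.
#' @param config an [arena_config()].
#' @return Data frame with columns \code{t}, \code{bearing}, \code{view}.
#' @export
view_track <- function(trial, fish = c("a", "b"), config = arena_config()) {
  fish <- match.arg(fish)
  obs <- if (fish == "a") trial$fish_a else trial$fish_b
  tgt <- if (fish == "a") trial$fish_b else trial$fish_a
  bearing <- relative_bearing(obs$x, obs$y, obs$heading, tgt$x, tgt$y)
  data.frame(t = obs$t, bearing = bearing,
             view = classify_view(bearing, config))
}

# forward ray from (px,py) along unit direction (ux,uy) intersects the disk
# of radius r centred at (cx,cy)?  vectorized.
ray_hits_disk <- function(px, py, ux, uy, cx, cy, r) {
  dx <- cx - px; dy <- cy - py
  d2 <- dx^2 + dy^2
  along <- dx * ux + dy * uy               # projection onto the ray
  perp2 <- d2 - along^2                    # squared distance off the ray axis
  d2 <= r^2 | (along > 0 & perp2 <= r^2)
}

#' Attack-posture test for one frame
#'
#' True when the forward ray from the observer's mouth (a point half an
#' avatar length ahead of the logged body centre, along the heading) passes
#' through the disk of radius \code{attack_circle_radius} centred at the
#' opponent's body centre.
#'
#' @param x,y,heading observer body centre and heading (vectors allowed).
#' @param tx,ty opponent body centre.
#' @param config an [arena_config()].
#' @return Logical vector.
#' @export
is_attack_posture <- function(x, y, heading, tx, ty, config = arena_config()) {
  if (any(x == tx & y == ty))
    stop("is_attack_posture: coincident positions")
  h <- heading * pi / 180
  ux <- cos(h); uy <- sin(h)
  mx <- x + config$avatar_length / 2 * ux
  my <- y + config$avatar_length / 2 * uy
  ray_hits_disk(mx, my, ux, uy, tx, ty, config$attack_circle_radius)
}

#' Attack posture rate of one fish over a trial
#'
#' Percentage of frames in which the fish holds an attack posture toward its
#' opponent.
#'
#' @param trial a \code{dyad_trial}.
#' @param fish \code{"a"} or \code{"b"}.
#' @param config an [arena_config()].
#' @return Percentage in [0, 100].
#' @export
attack_posture_rate <- function(trial, fish = c("a", "b"),
                                config = arena_config()) {
  fish <- match.arg(fish)
  obs <- if (fish == "a") trial$fish_a else trial$fish_b
  tgt <- if (fish == "a") trial$fish_b else trial$fish_a
  100 * mean(is_attack_posture(obs$x, obs$y, obs$heading, tgt$x, tgt$y, config))
}

# candidate bite collision of `biter` on `victim` at every frame: the biter's
# mouth point lies within midbody_halfwidth of the victim's mid-body segment
# AND the biter's heading is within bite_angle_halfwidth of the perpendicular
# to the victim's body axis.
bite_candidate <- function(biter, victim, config) {
  h <- biter$heading * pi / 180
  mx <- biter$x + config$avatar_length / 2 * cos(h)
  my <- biter$y + config$avatar_length / 2 * sin(h)
  # victim mid-body segment: central fraction of the body axis
  vh <- victim$heading * pi / 180
  half <- config$avatar_length * config$midbody_fraction / 2
  ax <- victim$x - half * cos(vh); ay <- victim$y - half * sin(vh)
  bx <- victim$x + half * cos(vh); by <- victim$y + half * sin(vh)
  # distance from mouth point to segment [a, b]
  abx <- bx - ax; aby <- by - ay
  len2 <- abx^2 + aby^2
  tt <- pmin(1, pmax(0, ((mx - ax) * abx + (my - ay) * aby) / len2))
  qx <- ax + tt * abx; qy <- ay + tt * aby
  near_seg <- sqrt((mx - qx)^2 + (my - qy)^2) <= config$midbody_halfwidth
  # inclination: angle between biter heading and the victim body axis LINE,
  # folded to [0, 90]; the angle to the perpendicular is its complement.
  diff <- abs(wrap_angle(biter$heading - victim$heading))
  axis_angle <- pmin(diff, 180 - diff)
  incl_ok <- (90 - axis_angle) <= config$bite_angle_halfwidth
  near_seg & incl_ok
}

#' Detect rising-edge bite events
#'
#' A candidate collision exists at frame t when one fish's mouth touches the
#' opponent's mid-body segment with an approach inclination within
#' \code{bite_angle_halfwidth} of the perpendicular to the opponent's body
#' axis. A bite is scored at t only if no candidate existed at t-1 for the
#' same (biter, bitten) pair, so a contiguous collision block counts once.
#'
#' @param trial a \code{dyad_trial}.
#' @param config an [arena_config()].
#' @return Data frame with columns \code{t}, \code{biter}, \code{bitten}.
#' @export
detect_bites <- function(trial, config = arena_config()) {
  rising <- function(cand) cand & !c(FALSE, cand[-length(cand)])
  ca <- bite_candidate(trial$fish_a, trial$fish_b, config)
  cb <- bite_candidate(trial$fish_b, trial$fish_a, config)
  ta <- trial$fish_a$t[rising(ca)]
  tb <- trial$fish_b$t[rising(cb)]
  out <- data.frame(
    t = c(ta, tb),
    biter = c(rep("a", length(ta)), rep("b", length(tb))),
    bitten = c(rep("b", length(ta)), rep("a", length(tb)))
  )
  out[order(out$t, out$biter), , drop = FALSE]
}

#' Near rate of a trial
#'
#' Percentage of frames in which the inter-fish distance is at or below
#' \code{near_threshold} (default 50 units).
#'
#' @param trial a \code{dyad_trial}.
#' @param config an [arena_config()].
#' @return Percentage in [0, 100].
#' @export
near_rate <- function(trial, config = arena_config()) {
  d <- mutual_distance_series(trial)
  100 * mean(d <= config$near_threshold)
}

#' Center occupancy rate of one fish
#'
#' Percentage of frames the fish spends strictly inside the inner circle
#' (radius \code{inner_radius}, half the arena's area at the defaults).
#'
#' @param trial a \code{dyad_trial}.
#' @param fish \code{"a"} or \code{"b"}.
#' @param config an [arena_config()].
#' @return Percentage in [0, 100].
#' @export
center_occupancy_rate <- function(trial, fish = c("a", "b"),
                                  config = arena_config()) {
  fish <- match.arg(fish)
  traj <- if (fish == "a") trial$fish_a else trial$fish_b
  100 * mean(sqrt(traj$x^2 + traj$y^2) < config$inner_radius)
}
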