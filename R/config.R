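#' Arena and stimulation-protocol configuration
#'
#' Collects every geometric and stimulus constant of the dyadic VR task in one
#' validated object: arena geometry, the avatar's collision model, the angular
#' view-field partition, approach/bite thresholds, and the timing and voltages
#' of the closed-loop shock protocol.
#'
#' Angles are degrees. A relative bearing is measured from the observer's
#' heading to the observer-to-target direction, wrapped to (-180, 180], with
#' negative values meaning the target lies to the observer's LEFT (so the left
#' monocular field is the interval \code{[-135, -30)}). Lengths are VR units,
#' durations milliseconds unless the name says otherwise.
#'
#' @param arena_radius radius of the circular arena (VR units).
#' @param inner_radius radius of the invisible center circle used for the
#'   center occupancy rate; the default 70 gives the inner circle half the
#'   arena's area.
#' @param avatar_length body length of the 3D fish avatar.
#' @param near_threshold inter-fish distance at or below which a frame counts
#'   as "near".
#' @param left_eye_range,binocular_range,right_eye_range two-element numeric
#'   bearing intervals (degrees) for the three visual fields. Endpoint
#'   membership is fixed by the classifier: left is closed-open, binocular
#'   closed-closed, right open-closed, so each bearing gets exactly one label.
#' @param toward_range_halfwidth half-width (degrees) of the "moving toward"
#'   cone used by approach detection.
#' @param bite_angle_halfwidth maximal angle (degrees) between the biter's
#'   heading and the perpendicular to the opponent's body axis for a collision
#'   to count as a bite.
#' @param attack_circle_radius radius of the disk around the opponent's body
#'   center that the forward head-direction ray must cross for an attack
#'   posture.
#' @param midbody_fraction fraction of the body axis, centered on the body
#'   center, forming the bitable "mid-body" segment.
#' @param midbody_halfwidth half-width (VR units) of the mid-body collision
#'   region around the body-axis segment.
#' @param mild_voltage,mild_on_ms,mild_period_ms periodic mild stimulus:
#'   voltage, on-duration per cycle, cycle period.
#' @param transient_voltage,transient_ms transient shock delivered to the
#'   bitten fish.
#' @param relief_s duration (seconds) for which the biter's periodic stimulus
#'   is suppressed after a bite.
#' @param frame_interval_ms frame interval of the trajectory logs.
#' @param start_positions 2x2 matrix (rows = fish) of start positions.
#' @param high_proximity_threshold,low_proximity_threshold remaining-distance
#'   cutoffs splitting approaches into high- (<= 20) and low- (> 100)
#'   proximity subsets.
#' @param fbv_bin_width,fbv_n_bins width and count of the mutual-distance bins
#'   for distance-resolved eye-use profiles (defaults: 20 bins of 10 covering
#'   0-200).
#'
#' @return An object of class \code{"arena_config"} (a named list).
#' @examples
#' cfg <- arena_config()
#' cfg$arena_radius
#' @export
arena_config <- function(arena_radius = 100,
                         inner_radius = 70,
                         avatar_length = 25,
                         near_threshold = 50,
                         left_eye_range = c(-135, -30),
                         binocular_range = c(-30, 30),
                         right_eye_range = c(30, 135),
                         toward_range_halfwidth = 90,
                         bite_angle_halfwidth = 75,
                         attack_circle_radius = 25,
                         midbody_fraction = 1 / 3,
                         midbody_halfwidth = 2,
                         mild_voltage = 0.5,
                         mild_on_ms = 300,
                         mild_period_ms = 1000,
                         transient_voltage = 4,
                         transient_ms = 100,
                         relief_s = 120,
                         frame_interval_ms = 100,
                         start_positions = rbind(c(50, 0), c(-50, 0)),
                         high_proximity_threshold = 20,
                         low_proximity_threshold = 100,
                         fbv_bin_width = 10,
                         fbv_n_bins = 20) {
  cfg <- list(
    arena_radius = arena_radius, inner_radius = inner_radius,
    avatar_length = avatar_length, near_threshold = near_threshold,
    left_eye_range = as.numeric(left_eye_range),
    binocular_range = as.numeric(binocular_range),
    right_eye_range = as.numeric(right_eye_range),
    toward_range_halfwidth = toward_range_halfwidth,
    bite_angle_halfwidth = bite_angle_halfwidth,
    attack_circle_radius = attack_circle_radius,
    midbody_fraction = midbody_fraction,
    midbody_halfwidth = midbody_halfwidth,
    mild_voltage = mild_voltage, mild_on_ms = mild_on_ms,
    mild_period_ms = mild_period_ms,
    transient_voltage = transient_voltage, transient_ms = transient_ms,
    relief_s = relief_s, frame_interval_ms = frame_interval_ms,
    start_positions = matrix(as.numeric(start_positions), nrow = 2),
    high_proximity_threshold = high_proximity_threshold,
    low_proximity_threshold = low_proximity_threshold,
    fbv_bin_width = fbv_bin_width, fbv_n_bins = fbv_n_bins
  )
  class(cfg) <- "arena_config"
  validate_arena_config(cfg)
  cfg
}

validate_arena_config <- function(cfg) {
  pos_fields <- c(
    "arena_radius", "inner_radius", "avatar_length", "near_threshold",
    "toward_range_halfwidth", "bite_angle_halfwidth", "attack_circle_radius",
    "midbody_fraction", "midbody_halfwidth", "mild_on_ms", "mild_period_ms",
    "transient_ms", "relief_s", "frame_interval_ms", "fbv_bin_width",
    "fbv_n_bins", "high_proximity_threshold", "low_proximity_threshold"
  )
  for (f in pos_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("arena_config: '", f, "' must be a single positive finite number")
  }
  if (cfg$inner_radius >= cfg$arena_radius)
    stop("arena_config: inner_radius must be smaller than arena_radius")
  l <- cfg$left_eye_range; b <- cfg$binocular_range; r <- cfg$right_eye_range
  for (rng in list(l, b, r))
    if (length(rng) != 2L || rng[1] >= rng[2])
      stop("arena_config: view ranges must be increasing 2-vectors")
  # contiguity: [-135,-30) [-30,30] (30,135] must tile [-135, 135]
  if (l[2] != b[1] || b[2] != r[1])
    stop("arena_config: eye ranges must be contiguous (disjoint, shared endpoints)")
  sp <- cfg$start_positions
  if (!is.matrix(sp) || any(dim(sp) != c(2L, 2L)) || any(!is.finite(sp)))
    stop("arena_config: start_positions must be a finite 2x2 matrix")
  if (any(sqrt(rowSums(sp^2)) > cfg$arena_radius))
    stop("arena_config: start positions must lie inside the arena")
  if (any(abs(sp[1, ] + sp[2, ]) > 1e-9))
    stop("arena_config: start positions must be symmetric about the origin")
  invisible(cfg)
}

#' @export
print.arena_config <- function(x, ...) {
  cat("Dyadic VR arena/protocol configuration\n")
  cat(sprintf("  arena radius %g, inner circle %g, avatar length %g\n",
              x$arena_radius, x$inner_radius, x$avatar_length))
  cat(sprintf("  view fields: left [%g, %g), binocular [%g, %g], right (%g, %g]\n",
              x$left_eye_range[1], x$left_eye_range[2],
              x$binocular_range[1], x$binocular_range[2],
              x$right_eye_range[1], x$right_eye_range[2]))
  cat(sprintf("  shock: %gV for %g ms per %g ms cycle; bite -> %gV/%g ms, relief %g s\n",
              x$mild_voltage, x$mild_on_ms, x$mild_period_ms,
              x$transient_voltage, x$transient_ms, x$relief_s))
  cat(sprintf("  frame interval %g ms\n", x$frame_interval_ms))
  invisible(x)
}

#' Read an arena configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [arena_config()]; keys absent from
#' the file keep their defaults. \code{start_positions} may be given as a list
#' of two 2-vectors.
#'
#' @param path path to a YAML file.
#' @return An \code{"arena_config"} object.
#' @export
read_arena_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(arena_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_arena_config: unknown keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$start_positions))
    raw$start_positions <- do.call(rbind, lapply(raw$start_positions, as.numeric))
  do.call(arena_config, raw)
}
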