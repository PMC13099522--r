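#' Shuffle-null attraction between two fish
#'
#' The observed mean inter-fish distance is compared with the mean distance
#' after randomly permuting the whole position frames of one fish, repeated
#' \code{n_shuffles} times:
#' \deqn{Attraction = (mean(dist_{shuffled}) - dist_{real}) / mean(dist_{shuffled})}
#' Positive values mean the pair is closer than chance expects; the statistic
#' is bounded above by 1. Shuffling is a uniform permutation of frames of the
#' position series (not blocks), seeded for reproducibility.
#'
#' @param trial a \code{dyad_trial}.
#' @param n_shuffles number of random permutations (default 10).
#' @param seed integer seed for the permutations.
#' @param shuffle_fish which fish's positions to permute: \code{"b"}
#'   (default), \code{"a"}, or \code{"both"} to average the statistic over
#'   the two choices.
#' @return Unitless attraction value (<= 1).
#' @export
attraction <- function(trial, n_shuffles = 10, seed = 1,
                       shuffle_fish = c("b", "a", "both")) {
  shuffle_fish <- match.arg(shuffle_fish)
  if (n_frames(trial) < 2L) stop("attraction: trial must have >= 2 frames")
  if (shuffle_fish == "both") {
    return(mean(c(attraction(trial, n_shuffles, seed, "a"),
                  attraction(trial, n_shuffles, seed, "b"))))
  }
  a <- trial$fish_a; b <- trial$fish_b
  mov <- if (shuffle_fish == "a") a else b
  fix <- if (shuffle_fish == "a") b else a
  dist_real <- mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2))
  n <- nrow(mov)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dist_shuf <- vapply(seq_len(n_shuffles), function(i) {
    p <- sample.int(n)
    mean(sqrt((mov$x[p] - fix$x)^2 + (mov$y[p] - fix$y)^2))
  }, 0)
  m <- mean(dist_shuf)
  (m - dist_real) / m
}

#' Count view-label frames
#'
#' @param view factor of view labels as produced by [classify_view()].
#' @return Named counts: \code{n_left}, \code{n_binocular}, \code{n_right},
#'   \code{n_blind}.
#' @export
eye_counts <- function(view) {
  tab <- table(factor(view, levels = c("LEFT", "BINOCULAR", "RIGHT", "BLIND")))
  c(n_left = unname(tab["LEFT"]), n_binocular = unname(tab["BINOCULAR"]),
    n_right = unname(tab["RIGHT"]), n_blind = unname(tab["BLIND"]))
}

#' Eye-use percentages (LEP, FBVP, REP)
#'
#' Percentages of left-eye, binocular and right-eye frames over the frames in
#' which the opponent is visible at all; blind frames are excluded from the
#' common denominator, so the three always sum to 100.
#'
#' @param counts named counts as returned by [eye_counts()].
#' @return Named vector \code{c(lep, fbvp, rep)}; all \code{NA} when no
#'   visible frames exist.
#' @export
eye_percentages <- function(counts) {
  den <- counts[["n_left"]] + counts[["n_right"]] + counts[["n_binocular"]]
  if (den == 0) return(c(lep = NA_real_, fbvp = NA_real_, rep = NA_real_))
  c(lep = 100 * counts[["n_left"]] / den,
    fbvp = 100 * counts[["n_binocular"]] / den,
    rep = 100 * counts[["n_right"]] / den)
}

#' Left eye index (LEI)
#'
#' \code{(n_left - n_right) / (n_left + n_right)} over monocular frames only;
#' binocular and blind frames never enter. +1 means exclusive left-eye use.
#'
#' @param counts named counts as returned by [eye_counts()].
#' @return Value in [-1, 1], or \code{NA} when no monocular frames exist.
#' @export
left_eye_index <- function(counts) {
  den <- counts[["n_left"]] + counts[["n_right"]]
  if (den == 0) return(NA_real_)
  (counts[["n_left"]] - counts[["n_right"]]) / den
}

#' Distance-binned eye-use profile
#'
#' Frames are grouped by mutual distance into \code{fbv_n_bins} bins of width
#' \code{fbv_bin_width} (defaults: 20 bins covering 0-200) and the eye
#' percentages are computed per bin from the pooled frames.
#'
#' @param distance numeric vector of per-frame mutual distances.
#' @param view factor of per-frame view labels (same length).
#' @param config an [arena_config()].
#' @return Data frame: \code{bin_lo}, \code{bin_hi}, \code{lep}, \code{fbvp},
#'   \code{rep}, \code{n_frames}; percentage columns are \code{NA} for empty
#'   or all-blind bins.
#' @export
fbvp_by_distance <- function(distance, view, config = arena_config()) {
  stopifnot(length(distance) == length(view))
  w <- config$fbv_bin_width; nb <- config$fbv_n_bins
  bin <- floor(distance / w)
  out <- lapply(seq_len(nb) - 1L, function(b) {
    sel <- which(bin == b)
    pc <- if (length(sel)) eye_percentages(eye_counts(view[sel]))
          else c(lep = NA_real_, fbvp = NA_real_, rep = NA_real_)
    data.frame(bin_lo = b * w, bin_hi = (b + 1) * w,
               lep = pc[["lep"]], fbvp = pc[["fbvp"]], rep = pc[["rep"]],
               n_frames = length(sel))
  })
  do.call(rbind, out)
}

#' Split approach episodes by terminal proximity
#'
#' Episodes ending at a remaining distance at or below
#' \code{high_proximity_threshold} (default 20, just under one avatar length)
#' form the high-proximity subset; those ending beyond
#' \code{low_proximity_threshold} (default 100, the arena radius) the
#' low-proximity subset; the rest belong to neither.
#'
#' @param episodes result of [detect_approaches()].
#' @param config an [arena_config()].
#' @return \code{episodes} with an added factor column \code{proximity}
#'   (levels \code{high}, \code{low}, \code{neither}).
#' @export
proximity_split <- function(episodes, config = arena_config()) {
  rd <- episodes$remaining_distance
  prox <- ifelse(rd <= config$high_proximity_threshold, "high",
                 ifelse(rd > config$low_proximity_threshold, "low", "neither"))
  episodes$proximity <- factor(prox, levels = c("high", "low", "neither"))
  episodes
}

#' Full per-trial metric bundle
#'
#' Computes every trial-level statistic the analysis defines: mean mutual
#' distance, attraction, near rate, per-fish center occupancy and attack
#' posture rates, per-fish eye percentages and left eye index (over all
#' frames or approach frames only), approach and bite counts, and the
#' transfer-entropy bundle.
#'
#' @param trial a \code{dyad_trial}.
#' @param config an [arena_config()].
#' @param seed seed for the attraction shuffles.
#' @param eye_frames \code{"all"}: eye statistics over every frame;
#'   \code{"approach"}: over each fish's own approach-episode frames only.
#' @return An object of class \code{"trial_metrics"}: a list with pair-level
#'   fields and per-fish sublists.
#' @export
trial_metrics <- function(trial, config = arena_config(), seed = 1,
                          eye_frames = c("all", "approach")) {
  eye_frames <- match.arg(eye_frames)
  d <- mutual_distance_series(trial)
  bites <- detect_bites(trial, config)
  episodes <- detect_approaches(trial, config, bites = bites)
  te <- te_bundle(trial)
  per_fish <- lapply(c(a = "a", b = "b"), function(f) {
    vt <- view_track(trial, f, config)
    if (eye_frames == "approach") {
      eps <- episodes[episodes$approacher == f, , drop = FALSE]
      sel <- rep(FALSE, nrow(vt))
      for (i in seq_len(nrow(eps)))
        sel <- sel | (vt$t >= eps$start_t[i] & vt$t <= eps$end_t[i])
      view <- vt$view[sel]
    } else view <- vt$view
    counts <- eye_counts(view)
    pc <- eye_percentages(counts)
    list(center_occupancy = center_occupancy_rate(trial, f, config),
         attack_posture_rate = attack_posture_rate(trial, f, config),
         lep = pc[["lep"]], fbvp = pc[["fbvp"]], rep = pc[["rep"]],
         lei = left_eye_index(counts),
         n_approaches = sum(episodes$approacher == f),
         n_bites = sum(bites$biter == f))
  })
  structure(list(
    pair_id = trial$pair_id, condition = trial$condition,
    genotype_pair = trial$genotype_pair,
    mean_mutual_distance = mean(d),
    attraction = attraction(trial, seed = seed),
    near_rate = near_rate(trial, config),
    fish = per_fish, te = te,
    n_approaches = nrow(episodes), n_bites = nrow(bites)
  ), class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("Trial metrics for '%s' (%s)\n", x$pair_id, x$condition))
  cat(sprintf("  mean mutual distance %.2f, attraction %.4f, near rate %.1f%%\n",
              x$mean_mutual_distance, x$attraction, x$near_rate))
  cat(sprintf("  approaches %d, bites %d\n", x$n_approaches, x$n_bites))
  for (f in c("a", "b")) {
    p <- x$fish[[f]]
    cat(sprintf(
      "  fish %s: center %.1f%%, attack posture %.1f%%, LEP/FBVP/REP %.1f/%.1f/%.1f, LEI %.3f\n",
      f, p$center_occupancy, p$attack_posture_rate, p$lep, p$fbvp, p$rep, p$lei))
  }
  cat(sprintf("  TE (merged ethogram) a->b %.4f, b->a %.4f bits\n",
              x$te$merged$te_ab, x$te$merged$te_ba))
  invisible(x)
}

#' Flatten trial metrics to a data frame
#'
#' @param x a \code{"trial_metrics"} object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return One row per fish with all scalar metrics as columns.
#' @export
as.data.frame.trial_metrics <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rows <- lapply(c("a", "b"), function(f) {
    p <- x$fish[[f]]
    data.frame(pair_id = x$pair_id, condition = x$condition,
               genotype_pair = x$genotype_pair, fish = f,
               mean_mutual_distance = x$mean_mutual_distance,
               attraction = x$attraction, near_rate = x$near_rate,
               center_occupancy = p$center_occupancy,
               attack_posture_rate = p$attack_posture_rate,
               lep = p$lep, fbvp = p$fbvp, rep = p$rep, lei = p$lei,
               n_approaches = p$n_approaches, n_bites = p$n_bites,
               te_merged_out = if (f == "a") x$te$merged$te_ab else x$te$merged$te_ba,
               te_speed_out = if (f == "a") x$te$speed$te_ab else x$te$speed$te_ba,
               te_turn_out = if (f == "a") x$te$turn$te_ab else x$te$turn$te_ba,
               delta_te_merged = if (f == "a") x$te$merged$delta_te else -x$te$merged$delta_te,
               delta_te_speed = if (f == "a") x$te$speed$delta_te else -x$te$speed$delta_te,
               delta_te_turn = if (f == "a") x$te$turn$delta_te else -x$te$turn$delta_te)
  })
  do.call(rbind, rows)
}
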