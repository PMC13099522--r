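#' Per-frame inter-fish distance
#'
#' @param trial a \code{dyad_trial}.
#' @return Numeric vector, one Euclidean distance per frame.
#' @export
mutual_distance_series <- function(trial) {
  sqrt((trial$fish_a$x - trial$fish_b$x)^2 +
       (trial$fish_a$y - trial$fish_b$y)^2)
}

#' Alternating peaks and valleys of a distance series
#'
#' Plateaus are collapsed to their first frame; a monotone run reaching either
#' end of the series makes the endpoint an extremum, so the output always
#' starts and ends with an extremum and strictly alternates peak/valley.
#' With \code{min_prominence > 0}, adjacent peak/valley pairs whose height
#' difference is below the threshold are merged away, smallest first.
#'
#' @param series numeric vector, length >= 3.
#' @param min_prominence minimal height difference between neighbouring
#'   extrema (default 0: keep all).
#' @return Data frame with columns \code{index} (1-based position in
#'   \code{series}) and \code{type} ("peak" or "valley"); zero rows for a
#'   constant series.
#' @export
find_distance_extrema <- function(series, min_prominence = 0) {
  n <- length(series)
  if (n < 3L) stop("find_distance_extrema: series must have length >= 3")
  keep <- c(TRUE, diff(series) != 0)          # first frame of each plateau
  idx <- which(keep)
  vals <- series[idx]
  m <- length(vals)
  if (m < 2L) return(data.frame(index = integer(), type = character()))
  d <- sign(diff(vals))                        # all nonzero
  ext_i <- integer(); ext_t <- character()
  add <- function(i, ty) { ext_i <<- c(ext_i, i); ext_t <<- c(ext_t, ty) }
  add(idx[1], if (d[1] < 0) "peak" else "valley")
  if (m > 2L) for (k in 2:(m - 1L)) {
    if (d[k - 1L] > 0 && d[k] < 0) add(idx[k], "peak")
    if (d[k - 1L] < 0 && d[k] > 0) add(idx[k], "valley")
  }
  add(idx[m], if (d[m - 1L] > 0) "peak" else "valley")
  out <- data.frame(index = ext_i, type = ext_t)
  if (min_prominence > 0) {
    repeat {
      if (nrow(out) < 2L) break
      h <- abs(diff(series[out$index]))
      k <- which.min(h)
      if (h[k] >= min_prominence) break
      out <- out[-c(k, k + 1L), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

# maximal runs of TRUE in a logical vector -> list of (from, to) 1-based
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Map(c, starts[keep], ends[keep])
}

#' Detect approach episodes
#'
#' Within every peak-to-valley window of the mutual-distance series, the
#' maximal frame spans in which (1) the distance is non-increasing with a
#' strict net decrease, (2) the approacher's episode-mean speed exceeds the
#' target's, and (3) the target stays within \code{toward_range_halfwidth}
#' degrees of the approacher's heading at every frame, are emitted as that
#' fish's approach episodes. Mean-speed ties are assigned to neither fish,
#' and no frame belongs to episodes of both fish: overlapping candidates are
#' accepted in start order and a later candidate is trimmed to begin after
#' the accepted one, then re-checked against all three conditions.
#'
#' @param trial a \code{dyad_trial}.
#' @param config an [arena_config()].
#' @param min_frames minimal episode length in frames (default 3).
#' @param bites optional result of [detect_bites()], used to flag
#'   \code{terminal_bite} (a bite by the approacher within the episode);
#'   computed from the trial when NULL.
#' @return Data frame of episodes: \code{approacher}, \code{start_t},
#'   \code{end_t}, \code{remaining_distance}, \code{terminal_bite}, plus a
#'   list column \code{view} of per-frame view labels of the approacher
#'   toward the target.
#' @export
detect_approaches <- function(trial, config = arena_config(), min_frames = 3,
                              bites = NULL) {
  d <- mutual_distance_series(trial)
  t_idx <- trial$fish_a$t
  n <- length(d)
  empty <- data.frame(approacher = character(), start_t = numeric(),
                      end_t = numeric(), remaining_distance = numeric(),
                      terminal_bite = logical())
  empty$view <- list()
  if (n < 3L) return(empty)
  ext <- find_distance_extrema(d)
  if (nrow(ext) < 2L) return(empty)
  if (is.null(bites)) bites <- detect_bites(trial, config)

  va <- view_track(trial, "a", config)
  vb <- view_track(trial, "b", config)
  facing <- list(a = abs(va$bearing) <= config$toward_range_halfwidth,
                 b = abs(vb$bearing) <= config$toward_range_halfwidth)
  speed <- list(a = trial$fish_a$speed, b = trial$fish_b$speed)
  views <- list(a = va$view, b = vb$view)

  check_span <- function(fish, from, to) {
    if (to - from + 1L < min_frames) return(NULL)
    dd <- d[from:to]
    if (any(diff(dd) > 0) || dd[length(dd)] >= dd[1]) return(NULL)
    other <- if (fish == "a") "b" else "a"
    ms <- mean(speed[[fish]][from:to])
    mo <- mean(speed[[other]][from:to])
    if (!(ms > mo)) return(NULL)
    list(fish = fish, from = from, to = to)
  }

  candidates <- list()
  for (w in seq_len(nrow(ext) - 1L)) {
    if (ext$type[w] != "peak") next
    p <- ext$index[w]; v <- ext$index[w + 1L]
    for (fish in c("a", "b")) {
      for (run in true_runs(facing[[fish]][p:v])) {
        sp <- check_span(fish, p + run[1] - 1L, p + run[2] - 1L)
        if (!is.null(sp)) candidates[[length(candidates) + 1L]] <- sp
      }
    }
  }
  if (!length(candidates)) return(empty)
  ord <- order(vapply(candidates, `[[`, 0, "from"),
               vapply(candidates, `[[`, 0, "to"))
  candidates <- candidates[ord]

  accepted <- list()
  last_end <- 0L
  for (cand in candidates) {
    if (cand$from <= last_end) {
      cand <- check_span(cand$fish, last_end + 1L, cand$to)
      if (is.null(cand)) next
    }
    accepted[[length(accepted) + 1L]] <- cand
    last_end <- cand$to
  }
  if (!length(accepted)) return(empty)

  rows <- lapply(accepted, function(ep) {
    vlab <- views[[ep$fish]][ep$from:ep$to]
    tb <- any(bites$biter == ep$fish &
              bites$t >= t_idx[ep$from] & bites$t <= t_idx[ep$to])
    r <- data.frame(approacher = ep$fish, start_t = t_idx[ep$from],
                    end_t = t_idx[ep$to],
                    remaining_distance = d[ep$to], terminal_bite = tb)
    r$view <- list(vlab)
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bites per approach
#'
#' Ratio of bite events to approach episodes, per fish, read as the
#' probability of scoring a bite from an approach.
#'
#' @param episodes result of [detect_approaches()].
#' @param bites result of [detect_bites()].
#' @return Named numeric vector for fish \code{a} and \code{b}; \code{NA} for
#'   a fish with zero approaches.
#' @export
bites_per_approach <- function(episodes, bites) {
  vapply(c(a = "a", b = "b"), function(f) {
    napp <- sum(episodes$approacher == f)
    if (napp == 0L) return(NA_real_)
    sum(bites$biter == f) / napp
  }, 0)
}
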