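# interval helpers: intervals are 2-column matrices [start, end) in ms,
# assumed start < end.

interval_subtract <- function(iv, cut) {
  if (!nrow(iv) || !nrow(cut)) return(iv)
  out <- list()
  for (i in seq_len(nrow(iv))) {
    pieces <- matrix(iv[i, ], ncol = 2)
    for (j in seq_len(nrow(cut))) {
      nxt <- list()
      for (k in seq_len(nrow(pieces))) {
        s <- pieces[k, 1]; e <- pieces[k, 2]
        cs <- cut[j, 1]; ce <- cut[j, 2]
        if (ce <= s || cs >= e) { nxt[[length(nxt) + 1L]] <- c(s, e); next }
        if (cs > s) nxt[[length(nxt) + 1L]] <- c(s, cs)
        if (ce < e) nxt[[length(nxt) + 1L]] <- c(ce, e)
      }
      pieces <- if (length(nxt)) do.call(rbind, nxt) else matrix(0, 0, 2)
      if (!nrow(pieces)) break
    }
    if (nrow(pieces)) out[[length(out) + 1L]] <- pieces
  }
  if (!length(out)) matrix(0, 0, 2) else do.call(rbind, out)
}

#' Simulate the closed-loop shock schedule of a trial
#'
#' Both fish receive the periodic mild stimulus (\code{mild_voltage} for
#' \code{mild_on_ms} at the start of every \code{mild_period_ms} cycle,
#' phase-locked to trial start). A bite modifies the schedule: the bitten
#' fish receives \code{transient_voltage} for \code{transient_ms} starting at
#' the bite time (overriding any concurrent mild pulse), and the biter's
#' periodic stimulus is suppressed for \code{relief_s} seconds from the bite.
#' A repeat bite inside an open relief window restarts the window (relief
#' windows union rather than queue), and pulses resume on the global cycle
#' phase after relief. If both fish bite in the same frame, each receives the
#' transient shock and each earns relief.
#'
#' @param bites data frame as from [detect_bites()] (columns \code{t},
#'   \code{biter}, \code{bitten}); bite times are frames, converted via
#'   \code{frame_interval_ms}.
#' @param trial_length_ms trial duration in milliseconds.
#' @param config an [arena_config()].
#' @return Object of class \code{"stimulus_trace"}: a list with one data
#'   frame per fish (\code{a}, \code{b}) of non-overlapping, time-ordered
#'   segments \code{start_ms}, \code{end_ms}, \code{voltage}.
#' @export
simulate_stimulation <- function(bites, trial_length_ms,
                                 config = arena_config()) {
  if (trial_length_ms <= 0) stop("simulate_stimulation: trial_length_ms must be positive")
  bite_ms <- bites$t * config$frame_interval_ms
  if (any(bite_ms < 0 | bite_ms >= trial_length_ms))
    stop("simulate_stimulation: bite outside the trial")
  n_cycles <- floor(trial_length_ms / config$mild_period_ms)
  starts <- (seq_len(n_cycles) - 1) * config$mild_period_ms
  mild <- cbind(starts, pmin(starts + config$mild_on_ms, trial_length_ms))
  one_fish <- function(f) {
    relief <- bite_ms[bites$biter == f]
    transient <- bite_ms[bites$bitten == f]
    relief_iv <- if (length(relief))
      cbind(relief, pmin(relief + config$relief_s * 1000, trial_length_ms))
    else matrix(0, 0, 2)
    trans_iv <- if (length(transient))
      cbind(transient, pmin(transient + config$transient_ms, trial_length_ms))
    else matrix(0, 0, 2)
    m <- interval_subtract(mild, relief_iv)
    m <- interval_subtract(m, trans_iv)       # transient overrides mild
    seg <- rbind(
      if (nrow(m)) data.frame(start_ms = m[, 1], end_ms = m[, 2],
                              voltage = config$mild_voltage),
      if (nrow(trans_iv)) data.frame(start_ms = trans_iv[, 1],
                                     end_ms = trans_iv[, 2],
                                     voltage = config$transient_voltage)
    )
    if (is.null(seg))
      seg <- data.frame(start_ms = numeric(), end_ms = numeric(),
                        voltage = numeric())
    seg <- seg[order(seg$start_ms), , drop = FALSE]
    rownames(seg) <- NULL
    seg
  }
  structure(list(a = one_fish("a"), b = one_fish("b"),
                 trial_length_ms = trial_length_ms),
            class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("Stimulus trace over %g ms\n", x$trial_length_ms))
  for (f in c("a", "b")) {
    s <- stimulus_summary(x)[[f]]
    cat(sprintf("  fish %s: %d segments, on-time by voltage: %s\n",
                f, nrow(x[[f]]),
                paste(sprintf("%gV = %g ms", s$voltage, s$on_ms),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Summarize a stimulus trace
#'
#' @param trace a \code{"stimulus_trace"}.
#' @return List with one data frame per fish giving, per voltage level, the
#'   accumulated on-time (\code{on_ms}) and the duty fraction over the trial.
#' @export
stimulus_summary <- function(trace) {
  out <- lapply(trace[c("a", "b")], function(seg) {
    if (!nrow(seg))
      return(data.frame(voltage = numeric(), on_ms = numeric(),
                        duty = numeric()))
    agg <- stats::aggregate(end_ms - start_ms ~ voltage, data = seg, FUN = sum)
    names(agg)[2] <- "on_ms"
    agg$duty <- agg$on_ms / trace$trial_length_ms
    agg
  })
  names(out) <- c("a", "b")
  out
}

#' Step plot of a stimulus trace
#'
#' @param x a \code{"stimulus_trace"}.
#' @param ... passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.stimulus_trace <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, x$trial_length_ms / 1000),
                 ylim = c(0, 10), xlab = "time (s)", ylab = "voltage (V)",
                 yaxt = "n", ...)
  graphics::axis(2, at = c(0, 0.5, 4, 5, 5.5, 9),
                 labels = c(0, 0.5, 4, 0, 0.5, 4))
  offs <- c(a = 5, b = 0)
  for (f in c("a", "b")) {
    seg <- x[[f]]
    for (i in seq_len(nrow(seg)))
      graphics::rect(seg$start_ms[i] / 1000, offs[[f]],
                     seg$end_ms[i] / 1000, offs[[f]] + seg$voltage[i],
                     col = "grey30", border = NA)
    graphics::abline(h = offs[[f]], col = "grey70")
  }
  graphics::text(0, offs + 4.5, c("fish a", "fish b"), adj = 0)
  invisible(x)
}
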