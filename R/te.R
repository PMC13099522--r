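#' Merged-ethogram symbolization (4 symbols)
#'
#' For every consecutive frame pair, the signs of the change in forward speed
#' and in heading-direction value are combined into one of four symbols:
#' 0 = (+,+), 1 = (+,-), 2 = (-,+), 3 = (-,-), where the first sign is the
#' speed change and the second the heading change. Heading differences are
#' wrap-corrected to (-180, 180]. A zero change counts as '+' (nonnegative);
#' the output is one symbol shorter than the input.
#'
#' @param traj trajectory data frame with columns \code{speed} and
#'   \code{heading} (e.g. \code{trial$fish_a}).
#' @return Integer vector of symbols in 0..3 with attribute \code{K = 4}.
#' @export
merged_ethogram <- function(traj) {
  if (nrow(traj) < 2L) stop("merged_ethogram: need at least 2 frames")
  ds <- diff(traj$speed)
  dh <- wrap_angle(diff(traj$heading))
  s_neg <- ds < 0
  h_neg <- dh < 0
  sym <- as.integer(2L * s_neg + h_neg)
  attr(sym, "K") <- 4L
  sym
}

#' Five-level percentile binning of a value series
#'
#' Each value is mapped to one of five levels split at the series' own 5th,
#' 35th, 65th and 95th percentiles (linear-interpolation quantiles); values
#' at a boundary go to the lower bin, so level 0 is "at or below the lowest
#' 5%" and level 4 "above the 95%".
#'
#' @param x numeric series (length >= 20 recommended; shorter series give
#'   degenerate quantiles).
#' @return Integer vector of levels in 0..4 with attribute \code{K = 5}.
#' @export
percentile_bins <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.35, 0.65, 0.95), names = FALSE, type = 7)
  sym <- as.integer(findInterval(x, q, left.open = TRUE))
  attr(sym, "K") <- 5L
  sym
}

symbol_K <- function(s) {
  K <- attr(s, "K")
  if (is.null(K)) K <- max(s) + 1L
  as.integer(K)
}

# encode L-length histories of a symbol series as integers base K;
# hist[t] codes s[t], s[t-1], ..., s[t-L+1]
encode_history <- function(s, L, K) {
  n <- length(s)
  out <- numeric(n - L + 1L)
  for (j in seq_len(L)) out <- out * K + s[(L - j + 1L):(n - j + 1L)]
  out
}

entropy_bits <- function(codes) {
  p <- tabulate(match(codes, unique(codes)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Plug-in transfer entropy between symbol series
#'
#' Estimates \eqn{T_{P \to Q} = H(Q_t | Q_{t-1:t-L}) - H(Q_t | Q_{t-1:t-L},
#' P_{t-1:t-L})} from empirical joint frequencies, in bits, with the
#' convention 0 log 0 = 0. The estimate is clamped at 0 against floating
#' error; the plug-in estimator itself is never negative in exact
#' arithmetic.
#'
#' @param src source symbol series P (integers in 0..K-1).
#' @param dst destination symbol series Q (same length).
#' @param L history length in frames (default 1, one frame = one delay step).
#' @return Transfer entropy in bits.
#' @export
transfer_entropy <- function(src, dst, L = 1) {
  if (length(src) != length(dst))
    stop("transfer_entropy: src and dst must have equal length")
  n <- length(dst)
  if (n < L + 1L) stop("transfer_entropy: series too short for history L")
  Ks <- symbol_K(src); Kd <- symbol_K(dst)
  K <- max(Ks, Kd)
  # align: rows t = L+1 .. n
  q_now <- dst[(L + 1L):n]
  q_hist <- encode_history(dst, L, K)[1:(n - L)]
  p_hist <- encode_history(src, L, K)[1:(n - L)]
  KL <- K^L
  h_qh <- entropy_bits(q_hist)
  h_q_qh <- entropy_bits(q_hist * K + q_now)
  h_qh_ph <- entropy_bits(q_hist * KL + p_hist)
  h_q_qh_ph <- entropy_bits((q_hist * KL + p_hist) * K + q_now)
  te <- (h_q_qh - h_qh) - (h_q_qh_ph - h_qh_ph)
  max(te, 0)
}

#' Bidirectional transfer entropy and net flow
#'
#' @param a,b symbol series for the two agents.
#' @param L history length.
#' @return Object of class \code{"te_result"}: \code{te_ab} (a to b),
#'   \code{te_ba}, \code{delta_te = te_ab - te_ba}, \code{L},
#'   \code{n_samples}.
#' @export
delta_te <- function(a, b, L = 1) {
  te_ab <- transfer_entropy(a, b, L)
  te_ba <- transfer_entropy(b, a, L)
  structure(list(te_ab = te_ab, te_ba = te_ba, delta_te = te_ab - te_ba,
                 L = L, n_samples = length(a) - L),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("TE a->b %.4f bits, b->a %.4f bits, dTE %.4f (L = %d, n = %d)\n",
              x$te_ab, x$te_ba, x$delta_te, x$L, x$n_samples))
  invisible(x)
}

#' Transfer-entropy bundle of a trial
#'
#' Computes both directions of TE and the net flow for the three
#' symbolizations used throughout the analysis: the 4-symbol merged ethogram
#' (signs of speed and heading change), the 5-level percentile-binned forward
#' speed, and the 5-level percentile-binned turning speed.
#'
#' @param trial a \code{dyad_trial}.
#' @param L history length (default 1 frame, i.e. one 100-ms delay step at
#'   the default frame interval).
#' @return List of three \code{"te_result"} objects: \code{merged},
#'   \code{speed}, \code{turn}.
#' @export
te_bundle <- function(trial, L = 1) {
  if (n_frames(trial) < L + 2L) stop("te_bundle: trial too short")
  list(
    merged = delta_te(merged_ethogram(trial$fish_a),
                      merged_ethogram(trial$fish_b), L),
    speed = delta_te(percentile_bins(trial$fish_a$speed),
                     percentile_bins(trial$fish_b$speed), L),
    turn = delta_te(percentile_bins(trial$fish_a$turn),
                    percentile_bins(trial$fish_b$turn), L)
  )
}
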