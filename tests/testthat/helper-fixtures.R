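# shared fixture builders and independent oracles

# minimal hand-built trajectory
make_traj <- function(t, x, y, heading = 0, speed = 1, turn = 0) {
  data.frame(t = t, x = x, y = y, heading = heading, speed = speed,
             turn = turn)
}

# trial with prescribed per-frame inter-fish distances: fish a fixed at the
# origin, fish b on the +x axis at the given distance
distance_trial <- function(dists, speed_a = 1, speed_b = 0) {
  n <- length(dists)
  dyad_trial(make_traj(0:(n - 1), 0, 0, speed = speed_a),
             make_traj(0:(n - 1), dists, 0, speed = speed_b))
}

# independent bearing oracle: rotate the target into the observer frame and
# negate the CCW angle (left must come out negative)
bearing_oracle <- function(x, y, heading, tx, ty) {
  th <- -heading * pi / 180
  vx <- cos(th) * (tx - x) - sin(th) * (ty - y)
  vy <- sin(th) * (tx - x) + cos(th) * (ty - y)
  a <- -atan2(vy, vx) * 180 / pi
  if (a <= -180) a + 360 else a
}

# independent brute-force transfer entropy: direct evaluation of
# sum p(q, qh, ph) log2( p(q | qh, ph) / p(q | qh) ) over observed triples
te_oracle <- function(src, dst, L = 1) {
  n <- length(dst)
  key_hist <- function(s, t) paste(s[(t - 1):(t - L)], collapse = ",")
  rows <- t(vapply((L + 1):n, function(t)
    c(q = as.character(dst[t]), qh = key_hist(dst, t), ph = key_hist(src, t)),
    c(q = "", qh = "", ph = "")))
  N <- nrow(rows)
  joint3 <- table(apply(rows, 1, paste, collapse = "|"))
  cnt <- function(keys) table(keys)
  c_qh <- cnt(rows[, "qh"])
  c_qh_ph <- cnt(paste(rows[, "qh"], rows[, "ph"], sep = "|"))
  c_q_qh <- cnt(paste(rows[, "q"], rows[, "qh"], sep = "|"))
  te <- 0
  for (k in names(joint3)) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    q <- parts[1]; qh <- parts[2]; ph <- parts[3]
    p_joint <- joint3[[k]] / N
    p_q_given_qh_ph <- joint3[[k]] / c_qh_ph[[paste(qh, ph, sep = "|")]]
    p_q_given_qh <- c_q_qh[[paste(q, qh, sep = "|")]] / c_qh[[qh]]
    te <- te + p_joint * log2(p_q_given_qh_ph / p_q_given_qh)
  }
  te
}

# brute-force local-extremum scan (plateau-free series only)
extrema_oracle <- function(s) {
  n <- length(s)
  idx <- integer(); type <- character()
  add <- function(i, ty) { idx <<- c(idx, i); type <<- c(type, ty) }
  add(1L, if (s[2] < s[1]) "peak" else "valley")
  for (i in 2:(n - 1)) {
    if (s[i] > s[i - 1] && s[i] > s[i + 1]) add(i, "peak")
    if (s[i] < s[i - 1] && s[i] < s[i + 1]) add(i, "valley")
  }
  add(n, if (s[n] > s[n - 1]) "peak" else "valley")
  data.frame(index = idx, type = type)
}

# all symbol sequences of length n over 0..(K-1), as rows
all_sequences <- function(K, n) {
  as.matrix(rev(expand.grid(rep(list(0:(K - 1)), n))))
}

# exact two-sided rank-sum p-value by exhaustive enumeration of which ranks
# go to group 1 (no ties assumed)
ranksum_exact_oracle <- function(g1, g2) {
  n1 <- length(g1); n <- n1 + length(g2)
  r <- rank(c(g1, g2))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(seq_len(n)[combos], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# mirror a trial about the x axis (y -> -y, headings negated)
mirror_trial <- function(trial) {
  flip <- function(tr) {
    tr$y <- -tr$y
    tr$heading <- wrap_angle(-tr$heading)
    tr$turn <- -tr$turn
    tr
  }
  dyad_trial(flip(trial$fish_a), flip(trial$fish_b),
             frame_interval_ms = trial$frame_interval_ms)
}
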