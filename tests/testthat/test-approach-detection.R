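cfg <- arena_config()

test_that("mutual distance matches an independent hypot computation", {
  expect_equal(mutual_distance_series(
    dyad_trial(make_traj(0, 50, 0), make_traj(0, -50, 0))), 100)
  expect_equal(mutual_distance_series(
    dyad_trial(make_traj(0, 3, 4), make_traj(0, 3, 4))), 0)
  set.seed(21)
  tr <- generate_dyad(sim_params(n_frames = 200, seed = 21))
  a <- tr$fish_a; b <- tr$fish_b
  oracle <- vapply(seq_len(200), function(i)
    sqrt(sum((c(a$x[i], a$y[i]) - c(b$x[i], b$y[i]))^2)), 0)
  expect_equal(mutual_distance_series(tr), oracle)
})

test_that("extremum detection alternates and matches a brute-force scan", {
  # monotone series: endpoints are the only extrema
  mono <- find_distance_extrema(seq(100, 10, length.out = 20))
  expect_equal(mono$type, c("peak", "valley"))
  expect_equal(mono$index, c(1L, 20L))
  # triangle wave
  tri <- find_distance_extrema(c(0, 1, 2, 1, 0, 1, 2, 1, 0))
  expect_equal(tri$type, c("valley", "peak", "valley", "peak", "valley"))
  expect_equal(tri$index, c(1L, 3L, 5L, 7L, 9L))
  # plateau: first frame of the plateau is the extremum
  plat <- find_distance_extrema(c(0, 2, 2, 2, 0))
  expect_equal(plat$index[plat$type == "peak"], 2L)
  # noisy sinusoid vs oracle (strictly distinct values)
  set.seed(22)
  s <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, 0, 0.2)
  got <- find_distance_extrema(s)
  want <- extrema_oracle(s)
  expect_equal(got$index, want$index)
  expect_equal(got$type, want$type)
  # alternation always holds
  expect_true(all(got$type[-1] != got$type[-nrow(got)]))
  expect_equal(nrow(find_distance_extrema(rep(5, 10))), 0L)
  expect_error(find_distance_extrema(c(1, 2)), "length >= 3")
})

test_that("a scripted homing run yields exactly one episode for the mover", {
  tr <- generate_scripted_approach(90, 25, "binocular_homing", n_frames = 50)
  eps <- detect_approaches(tr, cfg)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$approacher, "a")
  expect_equal(eps$start_t, 0)
  expect_equal(eps$end_t, 49)
  expect_equal(eps$remaining_distance, 25)
  expect_lte(eps$remaining_distance, 25)  # terminal distance <= scripted stop
})

test_that("mutual approach goes to the faster fish; exact ties to neither", {
  n <- 20
  xs_a <- seq(-50, -10, length.out = n)      # a moves right at 20 units/s
  xs_b <- seq(50, 30, length.out = n)        # b moves left at 10 units/s
  a <- make_traj(0:(n - 1), xs_a, 0, heading = 0, speed = 20)
  b <- make_traj(0:(n - 1), xs_b, 0, heading = 180, speed = 10)
  eps <- detect_approaches(dyad_trial(a, b), cfg)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$approacher, "a")
  # equal speeds: no approach at all
  b_eq <- make_traj(0:(n - 1), seq(50, 10, length.out = n), 0,
                    heading = 180, speed = 20)
  expect_equal(nrow(detect_approaches(dyad_trial(a, b_eq), cfg)), 0L)
})

test_that("the toward-cone condition gates assignment frame-by-frame", {
  n <- 20
  xs_a <- seq(-50, -10, length.out = n)
  # a closes distance but faces away from b for the whole span
  a <- make_traj(0:(n - 1), xs_a, 0, heading = 180, speed = 20)
  b <- make_traj(0:(n - 1), 50, 0, heading = 90, speed = 0)
  expect_equal(nrow(detect_approaches(dyad_trial(a, b), cfg)), 0L)
})

test_that("episode frames are exclusive and distances non-increasing on random dyads", {
  for (s in 1:100) {
    tr <- generate_dyad(sim_params(n_frames = 400, seed = 3000 + s,
                                   attraction_gain = 0.15))
    eps <- detect_approaches(tr, cfg)
    if (!nrow(eps)) next
    d <- mutual_distance_series(tr)
    claimed <- integer(0)
    for (i in seq_len(nrow(eps))) {
      span <- (eps$start_t[i] + 1):(eps$end_t[i] + 1)   # 1-based
      expect_true(all(diff(d[span]) <= 0))
      expect_lt(d[span[length(span)]], d[span[1]])
      expect_length(intersect(claimed, span), 0)
      claimed <- c(claimed, span)
      expect_length(eps$view[[i]], length(span))
    }
  }
})

test_that("bites per approach is the per-fish ratio, missing when undefined", {
  eps <- data.frame(approacher = c("a", "a", "a", "a", "b"))
  bites <- data.frame(t = c(5, 9), biter = c("a", "a"), bitten = c("b", "b"))
  r <- bites_per_approach(eps, bites)
  expect_equal(r[["a"]], 0.5)
  expect_equal(r[["b"]], 0)
  none <- bites_per_approach(data.frame(approacher = character()), bites)
  expect_true(all(is.na(none)))
  eps3 <- data.frame(approacher = c("a", "a", "a"))
  one <- data.frame(t = 2, biter = "a", bitten = "b")
  expect_equal(bites_per_approach(eps3, one)[["a"]], 1 / 3)
})
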