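cfg <- arena_config()

test_that("attraction is exactly zero for a shuffle-invariant partner", {
  n <- 50
  a <- make_traj(0:(n - 1), seq(-50, 40, length.out = n),
                 seq(0, 20, length.out = n))
  b <- make_traj(0:(n - 1), 30, -10)          # fish b never moves
  expect_identical(attraction(dyad_trial(a, b)), 0)
})

test_that("attraction is positive for tracking dyads and seeded-deterministic", {
  # moderate gain: the pair tracks while still roaming the arena (very strong
  # gain collapses the dyad into a mutual orbit where the statistic saturates)
  tr <- generate_dyad(sim_params(n_frames = 3000, seed = 31,
                                 attraction_gain = 0.05))
  a1 <- attraction(tr, seed = 5)
  expect_gt(a1, 0)
  expect_lte(a1, 1)
  expect_identical(a1, attraction(tr, seed = 5))
  expect_false(identical(a1, attraction(tr, seed = 6)))
  # averaging over both shuffle choices is the mean of the two
  both <- attraction(tr, seed = 5, shuffle_fish = "both")
  expect_equal(both, mean(c(attraction(tr, seed = 5, shuffle_fish = "a"),
                            attraction(tr, seed = 5, shuffle_fish = "b"))))
})

test_that("eye percentages share one denominator and sum to 100", {
  expect_equal(eye_percentages(c(n_left = 10, n_binocular = 0, n_right = 0,
                                 n_blind = 5)),
               c(lep = 100, fbvp = 0, rep = 0))
  expect_equal(eye_percentages(c(n_left = 1, n_binocular = 2, n_right = 1,
                                 n_blind = 0)),
               c(lep = 25, fbvp = 50, rep = 25))
  expect_true(all(is.na(eye_percentages(c(n_left = 0, n_binocular = 0,
                                          n_right = 0, n_blind = 7)))))
  set.seed(32)
  for (i in 1:50) {
    counts <- c(n_left = rpois(1, 5), n_binocular = rpois(1, 5),
                n_right = rpois(1, 5), n_blind = rpois(1, 5))
    if (sum(counts[1:3]) == 0) next
    expect_equal(sum(eye_percentages(counts)), 100)
  }
})

test_that("LEI uses monocular frames only", {
  expect_equal(left_eye_index(c(n_left = 7, n_binocular = 0, n_right = 0,
                                n_blind = 0)), 1)
  expect_equal(left_eye_index(c(n_left = 4, n_binocular = 9, n_right = 4,
                                n_blind = 0)), 0)
  # binocular count cannot move the index
  expect_equal(left_eye_index(c(n_left = 3, n_binocular = 99, n_right = 1,
                                n_blind = 0)), 0.5)
  expect_equal(left_eye_index(c(n_left = 3, n_binocular = 0, n_right = 1,
                                n_blind = 0)), 0.5)
  expect_true(is.na(left_eye_index(c(n_left = 0, n_binocular = 5,
                                     n_right = 0, n_blind = 0))))
})

test_that("mirroring the arena negates LEI, swaps LEP/REP, preserves FBVP", {
  tr <- generate_dyad(sim_params(n_frames = 1000, seed = 33,
                                 attraction_gain = 0.1, lateral_bias = 40))
  mt <- mirror_trial(tr)
  for (f in c("a", "b")) {
    c1 <- eye_counts(view_track(tr, f, cfg)$view)
    c2 <- eye_counts(view_track(mt, f, cfg)$view)
    expect_equal(c2[["n_left"]], c1[["n_right"]])
    expect_equal(c2[["n_right"]], c1[["n_left"]])
    expect_equal(c2[["n_binocular"]], c1[["n_binocular"]])
    p1 <- eye_percentages(c1); p2 <- eye_percentages(c2)
    expect_equal(p2[["fbvp"]], p1[["fbvp"]])
    expect_equal(p2[["lep"]], p1[["rep"]])
    expect_equal(left_eye_index(c2), -left_eye_index(c1))
  }
})

test_that("distance bins follow floor(distance/width) and conserve frames", {
  # all frames at distance 5, binocular: bin 0 full, others missing
  prof <- fbvp_by_distance(rep(5, 8),
                           factor(rep("BINOCULAR", 8),
                                  levels = levels(classify_view(0))), cfg)
  expect_equal(prof$fbvp[1], 100)
  expect_equal(prof$n_frames[1], 8)
  expect_true(all(is.na(prof$fbvp[-1])))
  expect_equal(nrow(prof), 20)
  expect_equal(prof$bin_lo, seq(0, 190, by = 10))
  set.seed(34)
  d <- runif(500, 0, 220)
  v <- classify_view(runif(500, -180, 180), cfg)
  prof2 <- fbvp_by_distance(d, v, cfg)
  expect_equal(prof2$n_frames,
               vapply(0:19, function(b) sum(floor(d / 10) == b), 0L))
  expect_equal(sum(prof2$n_frames), sum(d < 200))
})

test_that("a homing approacher shows FBVP rising as distance falls", {
  tr <- generate_scripted_approach(190, 5, "binocular_homing", n_frames = 120)
  vt <- view_track(tr, "a", cfg)
  d <- mutual_distance_series(tr)
  prof <- fbvp_by_distance(d, vt$view, cfg)
  occ <- prof[!is.na(prof$fbvp), ]
  # FBVP in the nearest occupied bin exceeds the farthest
  expect_gt(occ$fbvp[1], occ$fbvp[nrow(occ)])
  expect_true(all(diff(occ$fbvp) <= 0))      # monotone over occupied bins
})

test_that("proximity split partitions by remaining distance with a gap", {
  eps <- data.frame(approacher = "a", start_t = 0, end_t = 9,
                    remaining_distance = c(15, 20, 60, 100, 101, 150),
                    terminal_bite = FALSE)
  out <- proximity_split(eps, cfg)
  expect_equal(as.character(out$proximity),
               c("high", "high", "neither", "neither", "low", "low"))
})

test_that("the trial metric bundle is coherent and exports one row per fish", {
  tr <- generate_dyad(sim_params(n_frames = 600, seed = 35,
                                 attraction_gain = 0.2, coupling_gain = 0.5))
  tm <- trial_metrics(tr, cfg, seed = 2)
  expect_s3_class(tm, "trial_metrics")
  expect_equal(tm$near_rate, near_rate(tr, cfg))
  expect_lte(tm$attraction, 1)
  for (f in c("a", "b")) {
    p <- tm$fish[[f]]
    expect_equal(sum(p$lep, p$fbvp, p$rep), 100)
    expect_gte(p$lei, -1); expect_lte(p$lei, 1)
  }
  df <- as.data.frame(tm)
  expect_equal(nrow(df), 2L)
  expect_equal(df$delta_te_merged[1], -df$delta_te_merged[2])
  # approach-frames-only variant runs and stays in range
  tm2 <- trial_metrics(tr, cfg, seed = 2, eye_frames = "approach")
  for (f in c("a", "b")) {
    p <- tm2$fish[[f]]
    if (!is.na(p$lep)) expect_equal(sum(p$lep, p$fbvp, p$rep), 100)
  }
})
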