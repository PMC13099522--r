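cfg <- arena_config()

test_that("relative bearing matches the rotation-matrix oracle and the sign convention", {
  # dead ahead and perpendicular anchors
  expect_equal(relative_bearing(0, 0, 0, 10, 0), 0)
  expect_equal(relative_bearing(0, 0, 0, 0, 10), -90)  # left = negative
  expect_equal(relative_bearing(0, 0, 0, 0, -10), 90)
  expect_error(relative_bearing(1, 1, 0, 1, 1), "coincide")
  set.seed(11)
  for (i in 1:200) {
    x <- runif(1, -90, 90); y <- runif(1, -90, 90)
    h <- runif(1, -179, 180)
    tx <- runif(1, -90, 90); ty <- runif(1, -90, 90)
    if (tx == x && ty == y) next
    expect_equal(relative_bearing(x, y, h, tx, ty),
                 bearing_oracle(x, y, h, tx, ty), tolerance = 1e-9)
  }
})

test_that("classify_view partitions (-180, 180] with unique boundary labels", {
  expect_equal(as.character(classify_view(0, cfg)), "BINOCULAR")
  expect_equal(as.character(classify_view(-90, cfg)), "LEFT")
  expect_equal(as.character(classify_view(90, cfg)), "RIGHT")
  expect_equal(as.character(classify_view(180, cfg)), "BLIND")
  # boundary ownership: -135 left, -30 binocular, 30 binocular, 135 right
  expect_equal(as.character(classify_view(c(-135, -30, 30, 135, -135.0001,
                                            135.0001), cfg)),
               c("LEFT", "BINOCULAR", "BINOCULAR", "RIGHT", "BLIND", "BLIND"))
  # totality: a fine grid gets exactly one non-NA label each
  grid <- seq(-179.99, 180, by = 0.01)
  expect_false(anyNA(classify_view(grid, cfg)))
})

test_that("attack posture matches a dense ray-sampling oracle", {
  # heading straight at the target centre: always true
  expect_true(is_attack_posture(0, 0, 0, 80, 0, cfg))
  # heading directly away: false
  expect_false(is_attack_posture(0, 0, 180, 80, 0, cfg))
  sample_oracle <- function(x, y, h, tx, ty) {
    hr <- h * pi / 180
    mx <- x + cfg$avatar_length / 2 * cos(hr)
    my <- y + cfg$avatar_length / 2 * sin(hr)
    dmax <- sqrt((tx - mx)^2 + (ty - my)^2) + cfg$attack_circle_radius + 5
    s <- seq(0, dmax, by = 0.02)
    any((mx + s * cos(hr) - tx)^2 + (my + s * sin(hr) - ty)^2 <=
          cfg$attack_circle_radius^2)
  }
  set.seed(12)
  for (i in 1:1000) {
    x <- runif(1, -90, 90); y <- runif(1, -90, 90); h <- runif(1, -179, 180)
    tx <- runif(1, -90, 90); ty <- runif(1, -90, 90)
    expect_equal(is_attack_posture(x, y, h, tx, ty, cfg),
                 sample_oracle(x, y, h, tx, ty))
  }
})

test_that("attack posture is invariant under global rotation and translation", {
  set.seed(13)
  for (i in 1:100) {
    x <- runif(1, -50, 50); y <- runif(1, -50, 50); h <- runif(1, -179, 180)
    tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
    phi <- runif(1, 0, 2 * pi); dx <- runif(1, -20, 20); dy <- runif(1, -20, 20)
    rot <- function(px, py) c(cos(phi) * px - sin(phi) * py + dx,
                              sin(phi) * px + cos(phi) * py + dy)
    p1 <- rot(x, y); p2 <- rot(tx, ty)
    expect_equal(
      is_attack_posture(x, y, h, tx, ty, cfg),
      is_attack_posture(p1[1], p1[2], wrap_angle(h + phi * 180 / pi),
                        p2[1], p2[2], cfg))
  }
})

test_that("attack posture rate counts posture frames as a percentage", {
  n <- 10
  # fish a at origin aiming at fish b for 4 of 10 frames
  headings <- c(rep(0, 4), rep(180, 6))
  tr <- dyad_trial(make_traj(0:(n - 1), 0, 0, heading = headings),
                   make_traj(0:(n - 1), 80, 0, heading = 90))
  expect_equal(attack_posture_rate(tr, "a", cfg), 40)
  always <- dyad_trial(make_traj(0:4, 0, 0, heading = 0),
                       make_traj(0:4, 80, 0))
  expect_equal(attack_posture_rate(always, "a", cfg), 100)
  expect_equal(attack_posture_rate(mirror_trial(always), "a", cfg), 100)
})

test_that("bite detection is rising-edge: one event per contiguous collision block", {
  bb <- dyadvr:::bite_block_trial(cfg)
  bites <- detect_bites(bb, cfg)
  expect_equal(nrow(bites), 1L)
  expect_equal(bites$t, 4)
  expect_equal(bites$biter, "a")
  expect_equal(bites$bitten, "b")
  # two separated collision blocks -> two events
  half <- cfg$avatar_length / 2
  xs <- c(40, half + 1, half + 1, 40, 40, half + 1, half + 1, 40)
  tr2 <- dyad_trial(make_traj(0:7, xs, 0, heading = 180),
                    make_traj(0:7, 0, 0, heading = 90))
  b2 <- detect_bites(tr2, cfg)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$t, c(1, 5))
})

test_that("approach parallel to the opponent's body axis is not a bite", {
  half <- cfg$avatar_length / 2
  # victim at the origin, body along +y; place the biter so its mouth point
  # (half a body length ahead along the heading) sits exactly on the victim's
  # body centre, and vary only the approach inclination
  biter_at <- function(heading) {
    hr <- heading * pi / 180
    make_traj(0:2, -half * cos(hr), -half * sin(hr), heading = heading)
  }
  victim <- make_traj(0:2, 0, 0, heading = 90)
  bites_for <- function(heading)
    nrow(detect_bites(dyad_trial(biter_at(heading), victim), cfg))
  expect_equal(bites_for(90), 0L)        # parallel to the axis: 90 deg off the perpendicular
  expect_equal(bites_for(180), 1L)       # dead-on perpendicular strike
  expect_equal(bites_for(180 - 74), 1L)  # just inside +/-75
  expect_equal(bites_for(180 - 76), 0L)  # just outside
})

test_that("near rate and center occupancy count frames against their thresholds", {
  expect_equal(near_rate(distance_trial(rep(100, 5)), cfg), 0)
  expect_equal(near_rate(distance_trial(rep(10, 5)), cfg), 100)
  expect_equal(near_rate(distance_trial(c(40, 40, 40, 60, 60, 60, 60, 60,
                                          60, 60)), cfg), 30)
  expect_equal(near_rate(distance_trial(rep(50, 4)), cfg), 100)  # <= 50 is near
  at_origin <- dyad_trial(make_traj(0:4, 0, 0), make_traj(0:4, 90, 0))
  expect_equal(center_occupancy_rate(at_origin, "a", cfg), 100)
  expect_equal(center_occupancy_rate(at_origin, "b", cfg), 0)
  half_in <- dyad_trial(make_traj(0:3, c(0, 0, 90, 90), 0),
                        make_traj(0:3, 10, 10))
  expect_equal(center_occupancy_rate(half_in, "a", cfg), 50)
  expect_true(near_rate(generate_dyad(sim_params(n_frames = 100, seed = 2)),
                        cfg) >= 0)
})
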