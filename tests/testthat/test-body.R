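test_that("zero posture stretches each arm 3 units out from its shoulder", {
  cfg <- body_config()
  geom <- forward_kinematics(numeric(6), cfg)
  expect_equal(geom$hands["left", ],
               cfg$shoulder_anchors["left", ] + c(-3, 0), tolerance = 1e-12)
  expect_equal(geom$hands["right", ],
               cfg$shoulder_anchors["right", ] + c(3, 0), tolerance = 1e-12)
})

test_that("hand end-points agree with a rotation-chain oracle on random postures", {
  cfg <- body_config()
  set.seed(11)
  for (i in 1:200) {
    p <- stats::runif(6, -pi, pi)
    geom <- forward_kinematics(p, cfg)
    left <- fk_oracle_hand(p[1:3], cfg$shoulder_anchors["left", ], pi,
                           cfg$link_lengths)
    right <- fk_oracle_hand(p[4:6], cfg$shoulder_anchors["right", ], 0,
                            cfg$link_lengths)
    expect_equal(unname(geom$hands["left", ]), left, tolerance = 1e-9)
    expect_equal(unname(geom$hands["right", ]), right, tolerance = 1e-9)
  }
})

test_that("consecutive joint points are separated by exactly the link lengths", {
  cfg <- body_config(link_lengths = c(0.7, 1.3, 2.1))
  set.seed(12)
  for (i in 1:50) {
    geom <- forward_kinematics(stats::runif(6, -pi, pi), cfg)
    for (arm in list(geom$left, geom$right)) {
      d <- sqrt(rowSums((arm[-1, ] - arm[-4, ])^2))
      expect_equal(d, cfg$link_lengths, tolerance = 1e-9)
    }
  }
})

test_that("negating and swapping arm angles mirrors the geometry about the torso axis", {
  cfg <- body_config()
  set.seed(13)
  for (i in 1:50) {
    p <- stats::runif(6, -pi, pi)
    mirrored <- c(-p[4:6], -p[1:3])
    g1 <- forward_kinematics(p, cfg)
    g2 <- forward_kinematics(mirrored, cfg)
    expect_equal(g2$left[, 1], -g1$right[, 1], tolerance = 1e-9)
    expect_equal(g2$left[, 2], g1$right[, 2], tolerance = 1e-9)
  }
})

test_that("non-finite joint angles are rejected", {
  cfg <- body_config()
  expect_error(forward_kinematics(c(0, NA, 0, 0, 0, 0), cfg), "finite")
  expect_error(forward_kinematics(rep(Inf, 6), cfg), "finite")
})

test_that("sensor arclength interpolation hits the hands and the joints", {
  # place sensors exactly at the polyline knots
  arm <- 3
  cfg0 <- body_config()
  total <- cfg0$total_length
  knots <- c(0, 1, 2, arm, arm + cfg0$torso_width, total - 2, total - 1,
             total) / total
  cfg <- body_config(n_sensors = 8, sensor_arc_positions = knots)
  set.seed(14)
  for (i in 1:20) {
    geom <- forward_kinematics(stats::runif(6, -pi, pi), cfg)
    pts <- sensor_world_positions(geom, cfg)
    expect_equal(pts[1, ], unname(geom$hands["left", ]), tolerance = 1e-9)
    expect_equal(pts[8, ], unname(geom$hands["right", ]), tolerance = 1e-9)
    expect_equal(pts[4, ], geom$left[1, ], tolerance = 1e-9)   # left shoulder
    expect_equal(pts[5, ], geom$right[1, ], tolerance = 1e-9)  # right shoulder
    expect_equal(pts[2, ], geom$left[3, ], tolerance = 1e-9)   # wrist joint
  }
})

test_that("uniform sensors are equally spaced along the straightened body", {
  cfg <- body_config(n_sensors = 30)
  geom <- forward_kinematics(numeric(6), cfg)  # body lies on a straight line
  pts <- sensor_world_positions(geom, cfg)
  gaps <- sqrt(rowSums((pts[-1, ] - pts[-30, ])^2))
  expect_equal(gaps, rep(cfg$total_length / 29, 29), tolerance = 1e-9)
})

test_that("a hand resting exactly on a permitted sensor drives it to 1", {
  cfg0 <- body_config()
  # right arm folded back: hand lands on the torso at x = w/2 - 3
  posture <- c(0, 0, 0, pi, 0, 0)
  x_hand <- cfg0$torso_width / 2 - 3
  arc <- (3 + (x_hand + cfg0$torso_width / 2)) / cfg0$total_length
  cfg <- body_config(n_sensors = 3, sensor_arc_positions = c(0, arc, 1))
  geom <- forward_kinematics(posture, cfg)
  a <- touch_activation(geom, cfg)
  expect_equal(a[2], 1, tolerance = 1e-6)
})

test_that("a sensor at a hand's own end-point ignores that hand", {
  cfg <- body_config()
  set.seed(15)
  for (i in 1:20) {
    geom <- forward_kinematics(stats::runif(6, -pi, pi), cfg)
    a <- touch_activation(geom, cfg)
    # sensor 1 sits on the left hand (distance 0) yet only feels the right one
    d_right <- sqrt(sum((sensor_world_positions(geom, cfg)[1, ] -
                           geom$hands["right", ])^2))
    expect_equal(a[1], exp(-d_right^2 / (2 * cfg$touch_sigma^2)),
                 tolerance = 1e-12)
  }
})

test_that("hands far from every permitted sensor leave all activations silent", {
  cfg <- body_config()
  geom <- forward_kinematics(numeric(6), cfg)  # arms stretched fully outward
  expect_true(all(touch_activation(geom, cfg) < 1e-6))
})

test_that("touch activation is bounded by 2 and translation invariant", {
  cfg <- body_config()
  set.seed(16)
  for (i in 1:50) {
    geom <- forward_kinematics(stats::runif(6, -pi, pi), cfg)
    a <- touch_activation(geom, cfg)
    expect_true(all(a >= 0 & a <= 2))
    shift <- stats::runif(2, -5, 5)
    geom2 <- geom
    geom2$polyline <- sweep(geom$polyline, 2, shift, "+")
    geom2$hands <- sweep(geom$hands, 2, shift, "+")
    expect_equal(touch_activation(geom2, cfg), a, tolerance = 1e-12)
  }
})

test_that("configuration validation rejects malformed bodies", {
  expect_error(body_config(link_lengths = c(1, -1, 1)), "positive")
  expect_error(body_config(n_sensors = 4,
                           sensor_arc_positions = c(0, 0.5, 0.4, 1)),
               "increasing")
  expect_error(body_config(joint_limits = c(2, 1)), "lo < hi")
})

test_that("density-variant layout splits 10 sparse / 20 dense sensors", {
  pos <- density_variant_positions()
  expect_length(pos, 30)
  expect_true(all(diff(pos) > 0))
  expect_equal(sum(pos <= 2 / 3), 10)
  expect_equal(sum(pos > 2 / 3), 20)
  expect_equal(pos[30], 1)
})
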