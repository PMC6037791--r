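#' Configure the simulated two-arm body
#'
#' Builds the geometry and sensor layout of the planar agent: a horizontal
#' torso segment joining two shoulders, each carrying a three-link kinematic
#' arm.  The body surface is the one-dimensional polyline running from the
#' left hand, up the left arm, across the torso and down the right arm to the
#' right hand; `n_sensors` touch sensors sit at fixed arclength coordinates
#' on that surface and move with the posture.
#'
#' A sensor responds to each hand (arm end-point) with a Gaussian of the 2-D
#' Euclidean distance between sensor and hand.  Sensors whose *arclength*
#' distance to a hand's own end-point is at most `mask_radius` ignore that
#' hand, so a hand cannot permanently stimulate the sensors it is attached
#' to.
#'
#' @param link_lengths three positive link lengths shared by both arms.
#' @param torso_width positive distance between the two shoulders.  The
#'   default 33/7 places the shoulders at arclength 0.28 and 0.72 of the
#'   whole body surface, so the exposed "chest" spans the central body
#'   region while the "shoulders" are hidden in the arm/torso angle.
#' @param n_sensors number of touch sensors (default 30).
#' @param sensor_arc_positions strictly increasing arclength coordinates in
#'   `[0, 1]` (0 = left hand tip, 1 = right hand tip).  `NULL` gives a
#'   uniform layout; see [density_variant_positions()] for a non-uniform one.
#' @param touch_sigma Gaussian width of the sensors in 2-D distance units.
#'   `NULL` defaults to 2% of the total body arclength, which gives
#'   localized, partially overlapping receptive fields.
#' @param mask_radius arclength radius within which a sensor is insensitive
#'   to the nearby hand.  `NULL` defaults to the arm length
#'   (`sum(link_lengths)`), so every sensor on an arm ignores that arm's
#'   own hand and arm sensors respond to the contralateral hand only.
#'   Without this, the sinusoidal babbling (whose joint angles dwell near
#'   the fold limits) parks each hand on its own forearm and permanently
#'   activates those sensors.
#' @param joint_limits either a length-2 `c(lo, hi)` applied to all six
#'   joints or a 6 x 2 matrix of per-joint limits, in radians.
#'
#' @return an object of class `body_config`.
#' @export
body_config <- function(link_lengths = c(1, 1, 1),
                        torso_width = 33 / 7,
                        n_sensors = 30,
                        sensor_arc_positions = NULL,
                        touch_sigma = NULL,
                        mask_radius = NULL,
                        joint_limits = c(-pi, pi)) {
  if (length(link_lengths) != 3L || any(!is.finite(link_lengths)) ||
      any(link_lengths <= 0)) {
    stop("`link_lengths` must be 3 positive finite lengths", call. = FALSE)
  }
  if (!is.finite(torso_width) || torso_width <= 0) {
    stop("`torso_width` must be positive", call. = FALSE)
  }
  n_sensors <- as.integer(n_sensors)
  if (n_sensors < 2L) stop("`n_sensors` must be at least 2", call. = FALSE)

  if (is.null(sensor_arc_positions)) {
    sensor_arc_positions <- seq(0, 1, length.out = n_sensors)
  }
  if (length(sensor_arc_positions) != n_sensors) {
    stop("`sensor_arc_positions` must have length `n_sensors`", call. = FALSE)
  }
  if (any(sensor_arc_positions < 0) || any(sensor_arc_positions > 1) ||
      any(diff(sensor_arc_positions) <= 0)) {
    stop("`sensor_arc_positions` must be strictly increasing within [0, 1]",
         call. = FALSE)
  }

  if (is.matrix(joint_limits)) {
    if (!all(dim(joint_limits) == c(6L, 2L))) {
      stop("matrix `joint_limits` must be 6 x 2", call. = FALSE)
    }
  } else {
    if (length(joint_limits) != 2L) {
      stop("`joint_limits` must be c(lo, hi) or a 6 x 2 matrix", call. = FALSE)
    }
    joint_limits <- matrix(rep(joint_limits, each = 6L), nrow = 6L)
  }
  if (any(joint_limits[, 1] >= joint_limits[, 2])) {
    stop("joint limits must satisfy lo < hi", call. = FALSE)
  }

  total_length <- 2 * sum(link_lengths) + torso_width
  if (is.null(touch_sigma)) touch_sigma <- 0.02 * total_length
  if (touch_sigma <= 0) stop("`touch_sigma` must be positive", call. = FALSE)
  if (is.null(mask_radius)) mask_radius <- sum(link_lengths)
  if (mask_radius < 0) stop("`mask_radius` must be non-negative", call. = FALSE)

  sensor_arc <- sensor_arc_positions * total_length
  cfg <- list(
    link_lengths = as.numeric(link_lengths),
    torso_width = torso_width,
    shoulder_anchors = rbind(left = c(-torso_width / 2, 0),
                             right = c(torso_width / 2, 0)),
    n_sensors = n_sensors,
    sensor_arc_positions = as.numeric(sensor_arc_positions),
    sensor_arclength = sensor_arc,
    total_length = total_length,
    touch_sigma = touch_sigma,
    mask_radius = mask_radius,
    joint_limits = joint_limits,
    # posture-independent: which hand each sensor is allowed to feel
    left_hand_permitted = sensor_arc > mask_radius,
    right_hand_permitted = (total_length - sensor_arc) > mask_radius
  )
  class(cfg) <- "body_config"
  cfg
}

#' Sensor layout with a denser right third of the body
#'
#' Places one third of the sensors uniformly on the first two thirds of the
#' body surface and the remaining two thirds of the sensors uniformly on the
#' last third, so that tactile resolution is three to four times higher on
#' the right part of the body.
#'
#' @param n_sparse sensors on `[0, 2/3]` (default 10).
#' @param n_dense sensors on `(2/3, 1]` (default 20).
#' @return strictly increasing arclength coordinates in `[0, 1]`.
#' @export
density_variant_positions <- function(n_sparse = 10, n_dense = 20) {
  sparse <- seq(0, 2 / 3, length.out = n_sparse)
  dense <- 2 / 3 + seq_len(n_dense) * (1 / 3) / n_dense
  c(sparse, dense)
}

#' Forward kinematics of the two arms
#'
#' Computes every joint point and both hand end-points from the six joint
#' angles by cumulative rotation of successive links starting at each
#' shoulder anchor.  At the zero posture both arms lie stretched outward
#' along the torso axis.  Angles are clipped to the configured joint limits;
#' movement is purely kinematic (no dynamics).
#'
#' @param posture numeric length 6: left joints 1-3 (shoulder to wrist),
#'   then right joints 1-3, in radians.
#' @param cfg a [body_config()].
#' @return an object of class `body_geometry` with the left/right joint
#'   chains (4 x 2 matrices, shoulder first), the hand positions, the body
#'   polyline and its cumulative arclength.
#' @export
forward_kinematics <- function(posture, cfg) {
  if (length(posture) != 6L || any(!is.finite(posture))) {
    stop("`posture` must be 6 finite joint angles", call. = FALSE)
  }
  posture <- pmin(pmax(posture, cfg$joint_limits[, 1]), cfg$joint_limits[, 2])
  L <- cfg$link_lengths
  # left arm unfolds along -x (direction pi + cumsum), right along +x;
  # with left angles = -right angles the two arms mirror about x = 0
  phi_l <- pi + cumsum(posture[1:3])
  phi_r <- cumsum(posture[4:6])
  ls <- cfg$shoulder_anchors["left", ]
  rs <- cfg$shoulder_anchors["right", ]
  left <- rbind(ls, cbind(ls[1] + cumsum(L * cos(phi_l)),
                          ls[2] + cumsum(L * sin(phi_l))))
  right <- rbind(rs, cbind(rs[1] + cumsum(L * cos(phi_r)),
                           rs[2] + cumsum(L * sin(phi_r))))
  dimnames(left) <- dimnames(right) <- NULL

  # body surface: left hand -> left arm -> torso -> right arm -> right hand
  polyline <- rbind(left[4, ], left[3, ], left[2, ], left[1, ],
                    right[1, ], right[2, ], right[3, ], right[4, ])
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                         polyline[-nrow(polyline), , drop = FALSE])^2))
  geom <- list(
    posture = posture,
    left = left,
    right = right,
    hands = rbind(left = left[4, ], right = right[4, ]),
    polyline = polyline,
    cum_arclength = c(0, cumsum(seg)),
    total_length = cfg$total_length
  )
  class(geom) <- "body_geometry"
  geom
}

#' World coordinates of the touch sensors
#'
#' Linearly interpolates each sensor's arclength coordinate along the
#' current body polyline, so sensors on the arms move with the posture.
#'
#' @param geom a [forward_kinematics()] result.
#' @param cfg the matching [body_config()].
#' @return `n_sensors` x 2 matrix of sensor positions.
#' @export
sensor_world_positions <- function(geom, cfg) {
  if (any(cfg$sensor_arc_positions < 0) || any(cfg$sensor_arc_positions > 1)) {
    stop("sensor arc positions outside [0, 1]", call. = FALSE)
  }
  s <- cfg$sensor_arclength
  cum <- geom$cum_arclength
  # rule = 2 clamps the endpoints against floating-point arclength rounding
  cbind(stats::approx(cum, geom$polyline[, 1], xout = s, rule = 2)$y,
        stats::approx(cum, geom$polyline[, 2], xout = s, rule = 2)$y)
}

#' Touch sensor activation
#'
#' Each sensor's activation is the sum, over the hands it is permitted to
#' feel, of `exp(-d^2 / (2 sigma^2))` where `d` is the 2-D Euclidean
#' distance between the sensor and that hand.  Sensors within
#' `mask_radius` (arclength) of a hand's end-point ignore that hand, so a
#' hand only activates sensors via the *other* arm or the torso.
#'
#' @inheritParams sensor_world_positions
#' @return numeric vector of `n_sensors` non-negative activations (at most 2).
#' @export
touch_activation <- function(geom, cfg) {
  pts <- sensor_world_positions(geom, cfg)
  dl2 <- (pts[, 1] - geom$hands["left", 1])^2 +
    (pts[, 2] - geom$hands["left", 2])^2
  dr2 <- (pts[, 1] - geom$hands["right", 1])^2 +
    (pts[, 2] - geom$hands["right", 2])^2
  s2 <- 2 * cfg$touch_sigma^2
  cfg$left_hand_permitted * exp(-dl2 / s2) +
    cfg$right_hand_permitted * exp(-dr2 / s2)
}

#' @export
print.body_config <- function(x, ...) {
  cat("<body_config> ", x$n_sensors, " sensors on arclength ",
      format(x$total_length), "; sigma = ", format(x$touch_sigma),
      ", mask = ", format(x$mask_radius), "\n", sep = "")
  invisible(x)
}
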