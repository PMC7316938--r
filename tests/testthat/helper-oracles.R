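# Independent brute-force oracles. These deliberately avoid the package's
# code paths: angles via clamped acos instead of atan2, point C via an
# explicit parametric line-plane solve, ICC via stats::aov mean squares.

norm3 <- function(v) sqrt(sum(v^2))

oracle_deviate <- function(planned, placed) {
  a <- planned$shoulder
  b <- placed$shoulder
  u <- (planned$apex - a) / norm3(planned$apex - a)
  v <- (placed$apex - b) / norm3(placed$apex - b)
  ang <- acos(min(max(sum(u * v), -1), 1)) * 180 / pi
  # point C: walk the placed axis b + t v until it satisfies (x - a).u = 0
  denom <- sum(v * u)
  lateral <- if (abs(denom) <= 1e-6) NA_real_ else {
    t <- (sum(a * u) - sum(b * u)) / denom
    norm3(a - (b + t * v))
  }
  signed <- sum((b - a) * u)
  list(angular_deg = ang, global_mm = norm3(b - a), lateral_mm = lateral,
       depth_mm = abs(signed), depth_signed_mm = signed,
       point_d = a + signed * u)
}

# ICC(A,1) from a two-way ANOVA fitted by stats::aov.
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), times = k)),
                  observer = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + observer, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

random_rotation <- function() {
  axis <- rnorm(3)
  rotation_about_axis(axis / norm3(axis), runif(1, 0, 2 * pi))
}

random_rigid <- function(trans_scale = 10) {
  rigid_transform(random_rotation(), rnorm(3, 0, trans_scale))
}

# A valid planned/placed pair with realistic magnitudes: shoulder offset up
# to ~3 mm, axis tilt up to ~20 degrees, lengths 10-16 mm.
random_pair <- function(id = "S1", site = "13") {
  shoulder <- rnorm(3, 0, 10)
  axis_p <- rnorm(3); axis_p <- axis_p / norm3(axis_p)
  len <- runif(1, 10, 16)
  planned <- implant_pose(id, site, "planned", shoulder, shoulder + len * axis_p)
  tilt <- rotation_about_axis(rnorm(3), runif(1, 0, 20 * pi / 180))
  axis_q <- as.numeric(tilt %*% axis_p)
  shoulder_q <- shoulder + rnorm(3, 0, 1)
  placed <- implant_pose(id, site, "placed", shoulder_q, shoulder_q + len * axis_q)
  list(planned = planned, placed = placed)
}
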