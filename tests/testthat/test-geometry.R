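test_that("implant axis is the normalised shoulder-to-apex direction", {
  p <- implant_pose("P1", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  expect_equal(implant_axis(p), c(0, 0, 1))
  # translation invariance
  p2 <- implant_pose("P1", "13", "planned", c(1, 1, 1), c(1, 1, 14))
  expect_equal(implant_axis(p2), c(0, 0, 1))
  # 3-4-5 triple normalises by hand to (0.6, 0, 0.8)
  p3 <- implant_pose("P1", "13", "planned", c(0, 0, 0), c(3, 0, 4))
  expect_equal(implant_axis(p3), c(0.6, 0, 0.8), tolerance = 1e-12)
  expect_equal(norm3(implant_axis(p3)), 1, tolerance = 1e-12)
})

test_that("pose construction rejects invalid geometry", {
  expect_error(implant_pose("P", "13", "planned", c(1, 2, 3), c(1, 2, 3)),
               "coincide")
  expect_error(implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13),
                            length_mm = 10), "5%")
  expect_error(implant_pose("P", "13", "nailed", c(0, 0, 0), c(0, 0, 13)))
  expect_error(implant_pose("P", "13", "planned", c(0, 0, NA), c(0, 0, 13)),
               "finite")
})

test_that("angular deviation matches analytic constructions and is symmetric", {
  mk <- function(axis, role = "planned") {
    implant_pose("P", "13", role, c(0, 0, 0), 13 * axis)
  }
  expect_equal(angular_deviation(mk(c(0, 0, 1)), mk(c(0, 0, 1))), 0)
  expect_equal(angular_deviation(mk(c(0, 0, 1)), mk(c(1, 0, 0))), 90)
  a5 <- c(sin(5 * pi / 180), 0, cos(5 * pi / 180))
  expect_equal(angular_deviation(mk(c(0, 0, 1)), mk(a5)), 5, tolerance = 1e-9)
  for (i in 1:20) {
    pr <- random_pair()
    expect_equal(angular_deviation(pr$planned, pr$placed),
                 angular_deviation(pr$placed, pr$planned), tolerance = 1e-12)
  }
})

test_that("a near-flipped implant reads near 180 degrees with a warning", {
  p <- implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  flipped <- implant_pose("P", "13", "placed", c(0, 0, 13), c(0.1, 0, 0.1))
  expect_warning(ang <- angular_deviation(p, flipped), "flipped")
  expect_gt(ang, 170)
  expect_lt(ang, 180)
})

test_that("global, lateral and depth deviations match hand computations", {
  planned <- implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  # parallel axes, shoulder offset (0.8, 0, 0.6): the 3-4-5 decomposition
  placed <- implant_pose("P", "13", "placed", c(0.8, 0, 0.6), c(0.8, 0, 13.6))
  expect_equal(global_deviation(planned, placed), 1.0, tolerance = 1e-12)
  lat <- lateral_deviation(planned, placed)
  expect_equal(lat$lateral_mm, 0.8, tolerance = 1e-12)
  expect_equal(lat$point_c, c(0.8, 0, 0), tolerance = 1e-12)
  dep <- depth_deviation(planned, placed)
  expect_equal(dep$depth_mm, 0.6, tolerance = 1e-12)
  expect_equal(dep$depth_signed_mm, 0.6, tolerance = 1e-12)
  expect_equal(dep$point_d, c(0, 0, 0.6), tolerance = 1e-12)
  # single-axis 2.6 mm offset
  placed26 <- implant_pose("P", "13", "placed", c(2.6, 0, 0), c(2.6, 0, 13))
  expect_equal(global_deviation(planned, placed26), 2.6, tolerance = 1e-12)
  # purely perpendicular displacement has zero depth
  expect_equal(depth_deviation(planned, placed26)$depth_mm, 0, tolerance = 1e-12)
  # coronal displacement carries a negative sign
  placed_cor <- implant_pose("P", "13", "placed", c(0, 0, -0.5), c(0, 0, 12.5))
  expect_equal(depth_deviation(planned, placed_cor)$depth_signed_mm, -0.5,
               tolerance = 1e-12)
})

test_that("point C follows the tilted placed axis, not the projection shortcut", {
  planned <- implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  v <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  b <- c(0.5, 0, 1.0)
  placed <- implant_pose("P", "13", "placed", b, b + 13 * v)
  lat <- lateral_deviation(planned, placed)
  c_expected <- b - (1.0 / cos(10 * pi / 180)) * v
  expect_equal(lat$point_c, c_expected, tolerance = 1e-12)
  expect_equal(lat$lateral_mm, norm3(c_expected), tolerance = 1e-12)
  # differs from projecting B onto the shoulder plane (the shortcut)
  expect_false(isTRUE(all.equal(lat$lateral_mm, norm3(c(b[1], b[2], 0)))))
})

test_that("lateral deviation is undefined when the placed axis lies in the shoulder plane", {
  planned <- implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  placed <- implant_pose("P", "13", "placed", c(1, 0, 1), c(14, 0, 1))
  expect_error(lateral_deviation(planned, placed), "undefined lateral")
  rec <- deviate(planned, placed)
  expect_true(is.na(rec$lateral_mm))
  expect_false(is.na(rec$global_mm))
  expect_false(is.na(rec$depth_mm))
})

test_that("deviate enforces pairing and composes the individual metrics bit-for-bit", {
  planned <- implant_pose("P1", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  placed_wrong <- implant_pose("P2", "13", "placed", c(0, 0, 0), c(0, 0, 13))
  expect_error(deviate(planned, placed_wrong), "pairing error")
  expect_error(deviate(placed_wrong, placed_wrong), "planned pose")
  placed <- implant_pose("P1", "13", "placed", c(0.8, 0, 0.6), c(0.8, 0, 13.6))
  rec <- deviate(planned, placed)
  expect_identical(rec$global_mm, global_deviation(planned, placed))
  expect_identical(rec$angular_deg, angular_deviation(planned, placed))
  expect_identical(rec$lateral_mm, lateral_deviation(planned, placed)$lateral_mm)
  expect_identical(rec$depth_mm, depth_deviation(planned, placed)$depth_mm)
  expect_equal(rec$angular_deg, 0)
  expect_equal(c(rec$global_mm, rec$lateral_mm, rec$depth_mm), c(1.0, 0.8, 0.6),
               tolerance = 1e-12)
})

test_that("deviate of a pose against itself is the zero record", {
  set.seed(11)
  for (i in 1:10) {
    pr <- random_pair()
    self <- pr$planned
    self$role <- "placed"
    rec <- deviate(pr$planned, self)
    expect_equal(rec$angular_deg, 0, tolerance = 1e-12)
    expect_equal(rec$global_mm, 0, tolerance = 1e-12)
    expect_equal(rec$lateral_mm, 0, tolerance = 1e-12)
    expect_equal(rec$depth_mm, 0, tolerance = 1e-12)
  }
})

test_that("deviate agrees with the brute-force point-construction oracle", {
  set.seed(42)
  for (i in 1:200) {
    pr <- random_pair()
    rec <- deviate(pr$planned, pr$placed)
    orc <- oracle_deviate(pr$planned, pr$placed)
    expect_equal(rec$angular_deg, orc$angular_deg, tolerance = 1e-9)
    expect_equal(rec$global_mm, orc$global_mm, tolerance = 1e-9)
    expect_equal(rec$lateral_mm, orc$lateral_mm, tolerance = 1e-9)
    expect_equal(rec$depth_mm, orc$depth_mm, tolerance = 1e-9)
    expect_equal(rec$depth_signed_mm, orc$depth_signed_mm, tolerance = 1e-9)
    expect_equal(rec$point_d, orc$point_d, tolerance = 1e-9)
  }
})

test_that("deviation metrics are invariant under a common rigid motion", {
  set.seed(7)
  for (i in 1:50) {
    pr <- random_pair()
    tf <- random_rigid()
    rec0 <- deviate(pr$planned, pr$placed)
    rec1 <- deviate(transform_pose(pr$planned, tf), transform_pose(pr$placed, tf))
    expect_equal(rec1$angular_deg, rec0$angular_deg, tolerance = 1e-9)
    expect_equal(rec1$global_mm, rec0$global_mm, tolerance = 1e-9)
    expect_equal(rec1$lateral_mm, rec0$lateral_mm, tolerance = 1e-9)
    expect_equal(rec1$depth_mm, rec0$depth_mm, tolerance = 1e-9)
  }
})

test_that("parallel axes give the exact Pythagorean decomposition and depth <= global", {
  set.seed(13)
  for (i in 1:50) {
    shoulder <- rnorm(3, 0, 5)
    axis <- rnorm(3); axis <- axis / norm3(axis)
    planned <- implant_pose("P", "13", "planned", shoulder, shoulder + 13 * axis)
    off <- rnorm(3, 0, 1)
    placed <- implant_pose("P", "13", "placed", shoulder + off,
                           shoulder + off + 13 * axis)
    rec <- deviate(planned, placed)
    expect_equal(rec$angular_deg, 0, tolerance = 1e-9)
    expect_equal(rec$global_mm^2, rec$lateral_mm^2 + rec$depth_mm^2,
                 tolerance = 1e-9)
    # and for arbitrary pairs depth never exceeds global
    pr <- random_pair()
    r2 <- deviate(pr$planned, pr$placed)
    expect_lte(r2$depth_mm, r2$global_mm + 1e-12)
  }
})

test_that("rigid transforms validate and compose correctly", {
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
  refl <- diag(c(1, 1, -1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "proper")
  p <- implant_pose("P", "13", "planned", c(0, 0, 0), c(13, 0, 0))
  # identity leaves the pose unchanged
  expect_equal(transform_pose(p, rigid_transform())$apex, p$apex)
  # pure translation shifts both landmarks; deviations against the original
  tf <- rigid_transform(diag(3), c(1, 2, 3))
  q <- transform_pose(p, tf)
  q$role <- "placed"
  expect_equal(q$shoulder, c(1, 2, 3))
  rec <- deviate(p, q)
  expect_equal(rec$global_mm, norm3(c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(rec$angular_deg, 0, tolerance = 1e-12)
  # 90-degree rotation about z maps the x axis onto y
  rz <- rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 2))
  expect_equal(implant_axis(transform_pose(p, rz)), c(0, 1, 0), tolerance = 1e-12)
  # axis length preserved under arbitrary rigid motion
  set.seed(3)
  tfr <- random_rigid()
  pq <- transform_pose(p, tfr)
  expect_equal(norm3(pq$apex - pq$shoulder), 13, tolerance = 1e-9)
})
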