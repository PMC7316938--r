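test_that("closed-form alignment is exact on noiseless correspondences", {
  set.seed(21)
  cloud <- matrix(rnorm(300, 0, 10), ncol = 3)
  # identity on identical clouds
  res0 <- closed_form_align(cloud, cloud)
  expect_equal(res0$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(res0$rmsd_mm, 0, tolerance = 1e-12)
  expect_identical(res0$iterations, 0L)
  # recovery of random transforms to machine precision
  for (i in 1:20) {
    tf <- random_rigid()
    res <- closed_form_align(cloud, transform_points(cloud, tf))
    expect_equal(res$transform$rotation, tf$rotation, tolerance = 1e-9)
    expect_equal(res$transform$translation, tf$translation, tolerance = 1e-9)
    expect_lt(res$rmsd_mm, 1e-9)
  }
})

test_that("closed-form rmsd is self-consistent under noisy correspondence", {
  set.seed(22)
  src <- matrix(rnorm(300, 0, 10), ncol = 3)
  tf <- random_rigid()
  tgt <- transform_points(src, tf) + matrix(rnorm(300, 0, 0.1), ncol = 3)
  res <- closed_form_align(src, tgt)
  brute <- sqrt(mean(rowSums((transform_points(src, res$transform) - tgt)^2)))
  expect_equal(res$rmsd_mm, brute, tolerance = 1e-9)
  # the returned transform is a least-squares optimum: small perturbations
  # of the rotation cannot do better
  for (i in 1:5) {
    wob <- rotation_about_axis(rnorm(3), 0.01)
    tf2 <- rigid_transform(wob %*% res$transform$rotation, res$transform$translation)
    expect_gte(sqrt(mean(rowSums((transform_points(src, tf2) - tgt)^2))), res$rmsd_mm)
  }
})

test_that("closed-form alignment rejects degenerate configurations", {
  expect_error(closed_form_align(matrix(rnorm(6), ncol = 3),
                                 matrix(rnorm(6), ncol = 3)), "fewer than 3")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(closed_form_align(line, line), "collinear")
  expect_error(closed_form_align(matrix(rnorm(30), ncol = 3),
                                 matrix(rnorm(33), ncol = 3)), "equal point counts")
})

test_that("trimmed ICP recovers a 5 degree / 1 mm perturbation with monotone rmsd", {
  pose <- implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  target <- simulate_implant_cloud(pose, n_points = 1500, seed = 31)
  tf <- rigid_transform(rotation_about_axis(c(0, 1, 0), 5 * pi / 180),
                        c(0.6, -0.5, 0.6))
  source <- transform_points(target, tf)
  # identity start on identical clouds converges immediately
  res0 <- iterative_surface_align(target, target, max_iter = 5)
  expect_true(res0$converged)
  expect_lte(res0$iterations, 2L)
  expect_lt(res0$rmsd_mm, 1e-12)
  res <- iterative_surface_align(source, target, trim_fraction = 0)
  expect_true(res$converged)
  expect_lt(res$rmsd_mm, 0.01)
  moved <- transform_points(source, res$transform)
  expect_lt(max(abs(moved - target)), 0.01)
  expect_true(all(diff(res$rmsd_history) <= 1e-12))
})

test_that("trimming rescues alignment under 20% scatter outliers", {
  pose <- implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  clean <- simulate_implant_cloud(pose, n_points = 1500, seed = 32)
  noisy <- simulate_implant_cloud(pose, n_points = 1500, scatter_fraction = 0.2,
                                  seed = 33)
  tf <- rigid_transform(rotation_about_axis(c(1, 0, 0), 5 * pi / 180),
                        c(0.5, 0.5, -0.7))
  res <- iterative_surface_align(transform_points(noisy, tf), clean,
                                 trim_fraction = 0.25)
  # measure recovery on the inlier geometry: the known-true inverse motion
  back <- transform_points(transform_points(clean, tf), res$transform)
  inlier_rmsd <- sqrt(mean(rowSums((back - clean)^2)))
  expect_lt(inlier_rmsd, 0.1)
  expect_true(all(diff(res$rmsd_history) <= 1e-12))
})

test_that("ICP reports non-convergence without error and validates inputs", {
  pose <- implant_pose("P", "13", "planned", c(0, 0, 0), c(0, 0, 13))
  a <- simulate_implant_cloud(pose, n_points = 300, seed = 34)
  tf <- rigid_transform(rotation_about_axis(c(0, 1, 0), 0.4), c(3, 1, 1))
  res <- iterative_surface_align(transform_points(a, tf), a, max_iter = 2)
  expect_false(res$converged)
  expect_identical(res$iterations, 2L)
  expect_error(iterative_surface_align(a, a, max_iter = 0), "max_iter")
  expect_error(iterative_surface_align(a, a, trim_fraction = 1), "trim_fraction")
  expect_error(iterative_surface_align(matrix(numeric(0), ncol = 3), a),
               "fewer than 3")
})

test_that("analogue pose fitting recovers noiseless and noisy cylinder poses", {
  pose <- implant_pose("P", "13", "placed", c(4, -2, 1),
                       c(4, -2, 1) + 13 * c(sin(0.2), 0, cos(0.2)))
  clean <- simulate_implant_cloud(pose, radius_mm = 1.75, n_points = 2000, seed = 41)
  fit <- fit_analogue_pose(clean, 13, apex_hint = pose$apex)
  expect_lt(angular_deviation(pose, fit), 0.1)
  expect_lt(norm3(fit$shoulder - pose$shoulder), 0.05)
  expect_false(attr(fit, "orientation_ambiguous"))
  noisy <- simulate_implant_cloud(pose, radius_mm = 1.75, n_points = 2000,
                                  surface_sigma_mm = 0.2, seed = 42)
  fitn <- fit_analogue_pose(noisy, 13, apex_hint = pose$apex)
  expect_lt(angular_deviation(pose, fitn), 1)
  expect_lt(norm3(fitn$shoulder - pose$shoulder), 0.3)
})

test_that("pose fitting flags ambiguity and rejects isotropic clouds", {
  pose <- implant_pose("P", "13", "placed", c(0, 0, 0), c(0, 0, 13))
  cloud <- simulate_implant_cloud(pose, seed = 43)
  fit <- fit_analogue_pose(cloud, 13)
  expect_true(attr(fit, "orientation_ambiguous"))
  set.seed(44)
  sphere <- matrix(rnorm(3000), ncol = 3)
  sphere <- sphere / sqrt(rowSums(sphere^2)) * 5
  expect_error(fit_analogue_pose(sphere, 13), "unfittable")
})

test_that("pose fitting is equivariant under rigid motion of the cloud", {
  set.seed(45)
  pose <- implant_pose("P", "13", "placed", c(1, 1, 0), c(1, 1, 13))
  cloud <- simulate_implant_cloud(pose, seed = 46)
  tf <- random_rigid(trans_scale = 5)
  fit0 <- fit_analogue_pose(cloud, 13, apex_hint = pose$apex)
  moved_pose <- transform_pose(pose, tf)
  fit1 <- fit_analogue_pose(transform_points(cloud, tf), 13,
                            apex_hint = moved_pose$apex)
  expect_equal(fit1$shoulder, transform_pose(fit0, tf)$shoulder, tolerance = 1e-3)
  expect_lt(angular_deviation(transform_pose(fit0, tf), fit1), 0.05)
})
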