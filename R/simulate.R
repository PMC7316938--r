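# Synthetic cohort generator. Emulates the error structure of
# template-guided implant surgery in a severely resorbed maxilla: one
# rigid-body seating error per patient (rotation about a horizontal axis
# through the nasal-aperture fulcrum, plus a small translation), a
# per-implant drill-sleeve tilt, an unguided insertion-depth slide along
# the drilled axis, and optional per-observer measurement noise. The arch
# model is a schematic circular arc; only the error geometry matters for
# exercising the deviation metrics.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation parameters for a synthetic implant cohort
#'
#' Defaults reflect a cohort of edentulous patients receiving 2-4 implants
#' in the anterior maxilla through a bone-supported template braced on the
#' nasal aperture. Error magnitudes are calibration choices (the source
#' study publishes no quantitative decomposition of its error budget),
#' picked so that default cohorts land in the clinically reported range:
#' mean angular deviation of a few degrees, mean global deviation around
#' 1 mm.
#'
#' @param n_patients Number of patients (default 11).
#' @param implants_per_patient Implants per patient, an integer in 2..4
#'   (default 2).
#' @param arch_radius_mm Radius of the schematic anterior arch (default 25).
#' @param fulcrum_offset_mm Position of the nasal-aperture fulcrum relative
#'   to the arch centre (default `c(0, 8, 18)`: anterior-superior).
#' @param sigma_seat_deg SD of the template seating rotation angle about a
#'   horizontal axis through the fulcrum, degrees (default 2).
#' @param sigma_seat_trans_mm SD per component of the seating translation,
#'   mm (default 0.3).
#' @param sigma_sleeve_deg SD of the per-implant drill tilt angle (sleeve
#'   wobble), degrees, uniform azimuth (default 6).
#' @param sigma_depth_mm SD of the unguided insertion-depth slide along the
#'   drilled axis, mm (default 0.5).
#' @param sigma_observer_mm SD per component of observer shoulder-placement
#'   noise, mm (default 0.1).
#' @param sigma_observer_deg SD of observer axis-reading tilt, degrees
#'   (default 0.5).
#' @param seating_axis `"horizontal"` (default, bracket mechanics of a
#'   nasal-aperture template) or `"random"` (fully random rotation axis).
#' @param seed Integer seed; every draw in the simulator derives from it.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 11L, implants_per_patient = 2L,
                          arch_radius_mm = 25, fulcrum_offset_mm = c(0, 8, 18),
                          sigma_seat_deg = 2, sigma_seat_trans_mm = 0.3,
                          sigma_sleeve_deg = 6, sigma_depth_mm = 0.5,
                          sigma_observer_mm = 0.1, sigma_observer_deg = 0.5,
                          seating_axis = c("horizontal", "random"),
                          seed = 1L) {
  seating_axis <- match.arg(seating_axis)
  n_patients <- as.integer(n_patients)
  implants_per_patient <- as.integer(implants_per_patient)
  if (is.na(n_patients) || n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (is.na(implants_per_patient) || implants_per_patient < 2L ||
      implants_per_patient > 4L) {
    stop("implants_per_patient must be in 2..4", call. = FALSE)
  }
  if (!is.finite(arch_radius_mm) || arch_radius_mm <= 0) {
    stop("arch_radius_mm must be positive", call. = FALSE)
  }
  sig <- c(sigma_seat_deg, sigma_seat_trans_mm, sigma_sleeve_deg,
           sigma_depth_mm, sigma_observer_mm, sigma_observer_deg)
  if (any(!is.finite(sig)) || any(sig < 0)) {
    stop("all sigma parameters must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, implants_per_patient = implants_per_patient,
         arch_radius_mm = arch_radius_mm,
         fulcrum_offset_mm = .vec3(fulcrum_offset_mm, "fulcrum_offset_mm"),
         sigma_seat_deg = sigma_seat_deg,
         sigma_seat_trans_mm = sigma_seat_trans_mm,
         sigma_sleeve_deg = sigma_sleeve_deg, sigma_depth_mm = sigma_depth_mm,
         sigma_observer_mm = sigma_observer_mm,
         sigma_observer_deg = sigma_observer_deg,
         seating_axis = seating_axis, seed = as.integer(seed)),
    class = "cohort_params")
}

# FDI site labels for m implants across the anterior maxilla, right to left.
.fdi_sites <- function(m) {
  switch(as.character(m),
         "2" = c("13", "23"),
         "3" = c("13", "12", "23"),
         "4" = c("15", "12", "22", "25"),
         stop("implants_per_patient must be in 2..4", call. = FALSE))
}

# Tilt a unit axis away from itself by angle_rad towards azimuth az_rad
# (azimuth measured in the plane perpendicular to the axis).
.tilt_axis <- function(axis, angle_rad, az_rad) {
  b <- .perp_basis(axis)
  w <- cos(az_rad) * b$e1 + sin(az_rad) * b$e2
  as.numeric(rotation_about_axis(w, angle_rad) %*% axis)
}

# Planned poses for one patient: shoulders on the anterior arch (z = 0
# plane), axes within 10 degrees of vertical (+z = apical), lengths drawn
# from the 13/15 mm implant sizes used clinically.
.planned_for_patient <- function(pid, params) {
  m <- params$implants_per_patient
  phi <- if (m == 1L) 0 else seq(-40, 40, length.out = m) * pi / 180
  sites <- .fdi_sites(m)
  lapply(seq_len(m), function(i) {
    tilt <- runif(1, 0, 10) * pi / 180
    az <- runif(1, 0, 2 * pi)
    len <- sample(c(13, 15), 1L)
    axis <- .tilt_axis(c(0, 0, 1), tilt, az)
    shoulder <- c(params$arch_radius_mm * sin(phi[i]),
                  params$arch_radius_mm * cos(phi[i]), 0)
    implant_pose(pid, sites[i], "planned", shoulder,
                 shoulder + len * axis, length_mm = len)
  })
}

# One seating transform: rotation of |N(0, sigma_seat)| about a random
# (horizontal or fully random) axis through the fulcrum, then a N(0,
# sigma_trans) translation per component.
.draw_seating <- function(params) {
  if (params$seating_axis == "horizontal") {
    psi <- runif(1, 0, 2 * pi)
    axis <- c(cos(psi), sin(psi), 0)
  } else {
    axis <- .unit3(rnorm(3))
  }
  theta <- abs(rnorm(1, 0, params$sigma_seat_deg)) * pi / 180
  trans <- rnorm(3, 0, params$sigma_seat_trans_mm)
  f <- params$fulcrum_offset_mm
  rot <- rotation_about_axis(axis, theta)
  # x -> f + R (x - f) + trans, expressed as a plain rigid transform
  rigid_transform(rot, f - as.numeric(rot %*% f) + trans)
}

#' Simulate a cohort of planned/placed implant pairs
#'
#' Generates planned poses on a schematic anterior arch and perturbs them
#' through the simulator's three error stages: per-patient template seating
#' (shared by all of that patient's implants), per-implant drill-sleeve
#' tilt about the shoulder, and an insertion-depth slide along the placed
#' axis. The true deviation record of every pair is computed (not sampled)
#' with [deviate()]. Draws are consumed in a fixed documented order
#' (per patient: planned tilts/azimuths/lengths, then the seating rotation
#' and translation, then per implant: sleeve tilt, azimuth, depth), so
#' cohorts are bit-reproducible from `params$seed`.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `simulated_cohort`; each element is a
#'   `simulated_pair` with fields `planned`, `placed` and `truth`.
#' @examples
#' pairs <- simulate_cohort(cohort_params(n_patients = 2, seed = 7))
#' summarise_cohort(cohort_truth(pairs))
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("params must be a cohort_params object", call. = FALSE)
  }
  .with_seed(params$seed, {
    out <- list()
    for (p in seq_len(params$n_patients)) {
      pid <- sprintf("S%02d", p)
      planned <- .planned_for_patient(pid, params)
      seat <- .draw_seating(params)
      for (pl in planned) {
        placed <- transform_pose(pl, seat)
        placed$role <- "placed"
        # sleeve wobble: tilt about the (post-seating) shoulder
        ang <- abs(rnorm(1, 0, params$sigma_sleeve_deg)) * pi / 180
        az <- runif(1, 0, 2 * pi)
        axis_now <- implant_axis(placed)
        new_axis <- .tilt_axis(axis_now, ang, az)
        len <- .norm3(placed$apex - placed$shoulder)
        placed$apex <- placed$shoulder + len * new_axis
        # unguided depth: slide along the drilled (placed) axis
        slide <- rnorm(1, 0, params$sigma_depth_mm)
        placed$shoulder <- placed$shoulder + slide * new_axis
        placed$apex <- placed$apex + slide * new_axis
        out[[length(out) + 1L]] <- structure(
          list(planned = pl, placed = placed, truth = deviate(pl, placed)),
          class = "simulated_pair")
      }
    }
    structure(out, class = c("simulated_cohort", "list"))
  })
}

#' True deviation table of a simulated cohort
#'
#' @param pairs A `simulated_cohort` from [simulate_cohort()].
#' @return Data frame of the per-pair true deviation records.
#' @export
cohort_truth <- function(pairs) {
  deviations_table(lapply(pairs, `[[`, "truth"))
}

#' Lateral error versus distance from the seating fulcrum
#'
#' Quantifies the lever-arm effect of template seating error: with a pure
#' seating rotation (all other error sources zero), an implant at distance d
#' from the fulcrum sees a mean lateral deviation of approximately
#' d * E|theta|, so bracing the template close to the implants shortens the
#' lever arm. Implants are placed directly inferior to the fulcrum at each
#' requested distance, axis vertical, and `n_rep` seating rotations are
#' sampled per distance.
#'
#' @param params A [cohort_params()] with `sigma_seat_deg > 0` and all other
#'   sigmas zero (otherwise an error is raised).
#' @param distances_mm Numeric vector of fulcrum-to-implant distances, mm.
#' @param n_rep Seating draws per distance (default 2000).
#' @return Data frame with columns `distance_mm` and `mean_lateral_mm`.
#' @export
lever_arm_check <- function(params, distances_mm, n_rep = 2000L) {
  if (!inherits(params, "cohort_params")) {
    stop("params must be a cohort_params object", call. = FALSE)
  }
  if (params$sigma_seat_trans_mm != 0 || params$sigma_sleeve_deg != 0 ||
      params$sigma_depth_mm != 0) {
    stop("lever_arm_check requires a pure seating rotation (all other sigmas zero)",
         call. = FALSE)
  }
  distances_mm <- as.numeric(distances_mm)
  if (any(!is.finite(distances_mm)) || any(distances_mm < 0)) {
    stop("distances_mm must be finite and >= 0", call. = FALSE)
  }
  f <- params$fulcrum_offset_mm
  .with_seed(params$seed, {
    res <- vapply(distances_mm, function(d) {
      shoulder <- f + c(0, 0, -d)
      planned <- implant_pose("L", "13", "planned", shoulder, shoulder + c(0, 0, 13))
      lat <- vapply(seq_len(n_rep), function(i) {
        seat <- .draw_seating(params)
        placed <- transform_pose(planned, seat)
        placed$role <- "placed"
        lateral_deviation(planned, placed)$lateral_mm
      }, numeric(1))
      mean(lat)
    }, numeric(1))
    data.frame(distance_mm = distances_mm, mean_lateral_mm = res)
  })
}

#' Simulate a segmented-implant point cloud
#'
#' Samples points uniformly by area on a capped cylinder along the pose
#' axis (radius `radius_mm`, length = the pose's shoulder-apex distance),
#' adds isotropic Gaussian surface noise, and replaces a fixed fraction of
#' points by uniform scatter outliers, emulating the speckled segmentation
#' that metal artefacts produce around titanium implants. The outlier box is
#' centred on the cylinder with lateral half-width five radii and axial
#' half-extent half-length plus five radii.
#'
#' @param pose An [implant_pose()]; points run shoulder to apex.
#' @param radius_mm Cylinder radius, mm (default 1.75, a 3.5 mm implant).
#' @param n_points Number of points (>= 100; default 2000).
#' @param surface_sigma_mm SD of isotropic Gaussian surface noise (default 0).
#' @param scatter_fraction Fraction of points replaced by outliers, in
#'   \[0, 1) (default 0). Exactly `round(scatter_fraction * n_points)` points
#'   are replaced.
#' @param seed Integer seed.
#' @return An n x 3 point matrix, mm.
#' @export
simulate_implant_cloud <- function(pose, radius_mm = 1.75, n_points = 2000L,
                                   surface_sigma_mm = 0, scatter_fraction = 0,
                                   seed = 1L) {
  .assert_pose(pose)
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("radius_mm must be positive", call. = FALSE)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 100L) stop("n_points must be >= 100", call. = FALSE)
  if (scatter_fraction < 0 || scatter_fraction >= 1) {
    stop("scatter_fraction must be in [0, 1)", call. = FALSE)
  }
  if (surface_sigma_mm < 0) stop("surface_sigma_mm must be >= 0", call. = FALSE)
  axis <- implant_axis(pose)
  len <- .norm3(pose$apex - pose$shoulder)
  b <- .perp_basis(axis)
  a_side <- 2 * pi * radius_mm * len
  a_cap <- pi * radius_mm^2
  .with_seed(seed, {
    region <- sample(c("side", "cap0", "cap1"), n_points, replace = TRUE,
                     prob = c(a_side, a_cap, a_cap))
    t_ax <- numeric(n_points)
    r_pt <- numeric(n_points)
    t_ax[region == "side"] <- runif(sum(region == "side"), 0, len)
    t_ax[region == "cap1"] <- len
    r_pt[region == "side"] <- radius_mm
    ncap <- sum(region != "side")
    r_pt[region != "side"] <- radius_mm * sqrt(runif(ncap))
    theta <- runif(n_points, 0, 2 * pi)
    pts <- t(vapply(seq_len(n_points), function(i) {
      pose$shoulder + t_ax[i] * axis +
        r_pt[i] * (cos(theta[i]) * b$e1 + sin(theta[i]) * b$e2)
    }, numeric(3)))
    if (surface_sigma_mm > 0) {
      pts <- pts + matrix(rnorm(3 * n_points, 0, surface_sigma_mm), ncol = 3)
    }
    n_out <- round(scatter_fraction * n_points)
    if (n_out > 0) {
      centre <- pose$shoulder + (len / 2) * axis
      idx <- sample(n_points, n_out)
      u <- matrix(runif(3 * n_out, -1, 1), ncol = 3)
      lateral <- 5 * radius_mm
      axial <- len / 2 + 5 * radius_mm
      offsets <- t(apply(u, 1L, function(ui) {
        ui[1] * lateral * b$e1 + ui[2] * lateral * b$e2 + ui[3] * axial * axis
      }))
      pts[idx, ] <- sweep(offsets, 2L, centre, "+")
    }
    pts
  })
}

#' Simulate per-observer deviation measurements
#'
#' Emulates independent observers re-seating the virtual analogue on the
#' same cohort: each observer reads each placed pose with independent
#' shoulder noise (`sigma_observer_mm` per component) and axis tilt
#' (`sigma_observer_deg`, uniform azimuth), and the chosen deviation metric
#' is recomputed from the perturbed pose. The result is the n x k ratings
#' matrix consumed by [icc_absolute_single()].
#'
#' @param pairs A `simulated_cohort`.
#' @param params The [cohort_params()] providing observer noise and the seed.
#' @param n_observers Number of observers k (default 2).
#' @param metric Which deviation to rate: `"global_mm"` (default),
#'   `"angular_deg"`, `"lateral_mm"` or `"depth_mm"`.
#' @return n x k numeric matrix with subject row names and observer column
#'   names.
#' @export
simulate_observer_ratings <- function(pairs, params, n_observers = 2L,
                                      metric = c("global_mm", "angular_deg",
                                                 "lateral_mm", "depth_mm")) {
  metric <- match.arg(metric)
  if (!inherits(params, "cohort_params")) {
    stop("params must be a cohort_params object", call. = FALSE)
  }
  n_observers <- as.integer(n_observers)
  if (is.na(n_observers) || n_observers < 2L) stop("need at least 2 observers", call. = FALSE)
  .with_seed(params$seed + 1L, {
    vals <- sapply(seq_len(n_observers), function(o) {
      vapply(pairs, function(pr) {
        placed <- pr$placed
        placed$shoulder <- placed$shoulder + rnorm(3, 0, params$sigma_observer_mm)
        ang <- abs(rnorm(1, 0, params$sigma_observer_deg)) * pi / 180
        az <- runif(1, 0, 2 * pi)
        axis <- .tilt_axis(implant_axis(placed), ang, az)
        len <- .norm3(placed$apex - placed$shoulder)
        placed$apex <- placed$shoulder + len * axis
        deviate(pr$planned, placed)[[metric]]
      }, numeric(1))
    })
    rownames(vals) <- vapply(pairs, function(pr) {
      paste0(pr$planned$patient_id, "-", pr$planned$location)
    }, character(1))
    colnames(vals) <- paste0("observer_", seq_len(n_observers))
    vals
  })
}
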