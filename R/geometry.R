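# Tolerances used across the geometry layer. Double precision geometry at
# millimetre scale: identities hold to ~1e-12, so 1e-9 is a safe assertion
# tolerance; 1e-6 guards near-parallel/near-perpendicular configurations.
.TOL_IDENT <- 1e-9
.TOL_PARALLEL <- 1e-6

.vec3 <- function(v, what = "vector") {
  v <- as.numeric(v)
  if (length(v) != 3L || !all(is.finite(v))) {
    stop(sprintf("%s must be a finite numeric vector of length 3", what),
         call. = FALSE)
  }
  v
}

.norm3 <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit3 <- function(v, what = "axis") {
  n <- .norm3(v)
  if (n <= 0) stop(sprintf("degenerate %s (zero length)", what), call. = FALSE)
  v / n
}

#' Construct an implant pose
#'
#' An implant pose is the position and orientation of one implant, given by
#' the 3D coordinates of its shoulder (the coronal platform centre) and its
#' apex, in millimetres. The shoulder of the planned implant is point A of
#' the deviation construction; the shoulder of the placed implant is point B.
#' The longitudinal axis runs shoulder to apex.
#'
#' @param patient_id Patient identifier (coerced to character).
#' @param location FDI two-digit tooth code for the implant site, e.g. "13".
#' @param role Either `"planned"` or `"placed"`.
#' @param shoulder Numeric length-3: shoulder (coronal centre) coordinates, mm.
#' @param apex Numeric length-3: apex coordinates, mm.
#' @param implant_id Optional implant identifier; defaults to
#'   `"<patient_id>-<location>"`.
#' @param length_mm Optional nominal implant length in mm. When supplied it
#'   must agree with the shoulder-apex distance to within 5%.
#' @param diameter_mm Optional implant diameter in mm.
#'
#' @return An object of class `implant_pose`.
#' @examples
#' p <- implant_pose("P1", "13", "planned", shoulder = c(0, 0, 0),
#'                   apex = c(0, 0, 13), length_mm = 13)
#' implant_axis(p)
#' @export
implant_pose <- function(patient_id, location, role, shoulder, apex,
                         implant_id = NULL, length_mm = NULL,
                         diameter_mm = NULL) {
  role <- match.arg(role, c("planned", "placed"))
  shoulder <- .vec3(shoulder, "shoulder")
  apex <- .vec3(apex, "apex")
  len <- .norm3(apex - shoulder)
  if (len <= 0) {
    stop("invalid geometry: shoulder and apex coincide", call. = FALSE)
  }
  if (!is.null(length_mm)) {
    length_mm <- as.numeric(length_mm)
    if (!is.finite(length_mm) || length_mm <= 0) {
      stop("length_mm must be a positive number", call. = FALSE)
    }
    if (abs(len - length_mm) > 0.05 * length_mm) {
      stop(sprintf(
        "shoulder-apex distance %.3f mm disagrees with length_mm = %g by more than 5%%",
        len, length_mm), call. = FALSE)
    }
  }
  if (!is.null(diameter_mm)) {
    diameter_mm <- as.numeric(diameter_mm)
    if (!is.finite(diameter_mm) || diameter_mm <= 0) {
      stop("diameter_mm must be a positive number", call. = FALSE)
    }
  }
  patient_id <- as.character(patient_id)
  location <- as.character(location)
  if (is.null(implant_id)) implant_id <- paste0(patient_id, "-", location)
  structure(
    list(patient_id = patient_id, implant_id = as.character(implant_id),
         location = location, role = role, shoulder = shoulder, apex = apex,
         length_mm = length_mm, diameter_mm = diameter_mm),
    class = "implant_pose")
}

#' @export
print.implant_pose <- function(x, ...) {
  cat(sprintf("<implant_pose %s patient %s site %s>\n",
              x$role, x$patient_id, x$location))
  cat(sprintf("  shoulder: (%.3f, %.3f, %.3f) mm\n",
              x$shoulder[1], x$shoulder[2], x$shoulder[3]))
  cat(sprintf("  apex:     (%.3f, %.3f, %.3f) mm\n",
              x$apex[1], x$apex[2], x$apex[3]))
  invisible(x)
}

.assert_pose <- function(pose, what = "pose") {
  if (!inherits(pose, "implant_pose")) {
    stop(sprintf("%s must be an implant_pose object", what), call. = FALSE)
  }
  pose
}

#' Longitudinal axis of an implant pose
#'
#' The unit direction from shoulder to apex (apical direction).
#'
#' @param pose An [implant_pose()].
#' @return Unit numeric vector of length 3.
#' @export
implant_axis <- function(pose) {
  .assert_pose(pose)
  .unit3(pose$apex - pose$shoulder, "implant axis")
}

#' Angular deviation between planned and placed implants
#'
#' The angle alpha between the longitudinal (shoulder-to-apex) axes of the
#' planned and placed implants, in degrees, computed with the numerically
#' stable two-argument arctangent of the cross-product norm and dot product.
#' Axes are oriented shoulder to apex and the angle is not folded to
#' \[0, 90\]: a flipped implant reads near 180 degrees and a warning is
#' issued above 90 degrees, since folding would mask gross orientation
#' errors.
#'
#' @param planned,placed [implant_pose()] objects.
#' @return Angle in degrees, in \[0, 180).
#' @export
angular_deviation <- function(planned, placed) {
  u <- implant_axis(planned)
  v <- implant_axis(placed)
  ang <- atan2(.norm3(.cross3(u, v)), sum(u * v)) * 180 / pi
  if (ang >= 180) ang <- 0  # atan2 returns pi only for exactly opposite axes
  if (ang > 90) {
    warning(sprintf(
      "angular deviation %.1f deg exceeds 90 deg: possible flipped axis", ang),
      call. = FALSE)
  }
  ang
}

#' Global deviation (point A to point B)
#'
#' The 3D Euclidean distance between the coronal centres of the planned
#' implant (point A) and the placed implant (point B), in millimetres.
#'
#' @inheritParams angular_deviation
#' @return Distance in mm.
#' @export
global_deviation <- function(planned, placed) {
  .assert_pose(planned, "planned"); .assert_pose(placed, "placed")
  .norm3(placed$shoulder - planned$shoulder)
}

#' Lateral deviation (point A to point C)
#'
#' Point C is where the longitudinal axis of the placed implant pierces the
#' shoulder plane of the planned implant (the plane through point A
#' perpendicular to the planned axis). Lateral deviation is |A - C| in mm.
#' When the placed axis lies within the shoulder plane (direction cosine
#' against the planned axis below 1e-6) there is no unique intersection and
#' an error is raised.
#'
#' @inheritParams angular_deviation
#' @return A list with `lateral_mm` and `point_c`.
#' @export
lateral_deviation <- function(planned, placed) {
  u <- implant_axis(planned)   # normal of the shoulder plane through A
  v <- implant_axis(placed)
  a <- planned$shoulder
  b <- placed$shoulder
  denom <- sum(v * u)
  if (abs(denom) <= .TOL_PARALLEL) {
    stop("undefined lateral deviation: placed axis lies in the planned shoulder plane",
         call. = FALSE)
  }
  t <- sum((a - b) * u) / denom
  point_c <- b + t * v
  list(lateral_mm = .norm3(a - point_c), point_c = point_c)
}

#' Depth deviation (point A to point D)
#'
#' Point D is the foot of point B on the planned axis through A: the centre
#' of the plane parallel to the planned shoulder plane that passes through
#' the placed shoulder. The signed depth is the component of B - A along the
#' planned (shoulder-to-apex) axis, positive when the placed shoulder sits
#' apical of the planned one; tables report the magnitude.
#'
#' @inheritParams angular_deviation
#' @return A list with `depth_mm`, `depth_signed_mm` and `point_d`.
#' @export
depth_deviation <- function(planned, placed) {
  u <- implant_axis(planned)
  .assert_pose(placed, "placed")
  signed <- sum((placed$shoulder - planned$shoulder) * u)
  list(depth_mm = abs(signed), depth_signed_mm = signed,
       point_d = planned$shoulder + signed * u)
}

#' All four deviation metrics for one planned/placed pair
#'
#' Assembles angular, global, lateral and depth deviation into a single
#' `deviation_record`. The pair must refer to the same patient and implant
#' site. If the lateral deviation is geometrically undefined (placed axis in
#' the planned shoulder plane) the record carries `NA` for the lateral metric
#' only.
#'
#' @inheritParams angular_deviation
#' @return An object of class `deviation_record`: a list with fields
#'   `angular_deg`, `global_mm`, `lateral_mm`, `depth_mm`, `depth_signed_mm`,
#'   `point_c`, `point_d`, plus the pair identifiers.
#' @examples
#' pl <- implant_pose("P1", "13", "planned", c(0, 0, 0), c(0, 0, 13))
#' pz <- implant_pose("P1", "13", "placed", c(0.8, 0, 0.6), c(0.8, 0, 13.6))
#' deviate(pl, pz)
#' @export
deviate <- function(planned, placed) {
  .assert_pose(planned, "planned"); .assert_pose(placed, "placed")
  if (planned$role != "planned" || placed$role != "placed") {
    stop("deviate() expects a planned pose and a placed pose, in that order",
         call. = FALSE)
  }
  if (planned$patient_id != placed$patient_id ||
      planned$location != placed$location) {
    stop(sprintf(
      "pairing error: planned (%s, site %s) does not match placed (%s, site %s)",
      planned$patient_id, planned$location,
      placed$patient_id, placed$location), call. = FALSE)
  }
  lat <- tryCatch(lateral_deviation(planned, placed), error = function(e) NULL)
  dep <- depth_deviation(planned, placed)
  structure(
    list(patient_id = planned$patient_id, location = planned$location,
         angular_deg = angular_deviation(planned, placed),
         global_mm = global_deviation(planned, placed),
         lateral_mm = if (is.null(lat)) NA_real_ else lat$lateral_mm,
         depth_mm = dep$depth_mm,
         depth_signed_mm = dep$depth_signed_mm,
         point_c = if (is.null(lat)) rep(NA_real_, 3) else lat$point_c,
         point_d = dep$point_d),
    class = "deviation_record")
}

#' @export
print.deviation_record <- function(x, ...) {
  cat(sprintf("<deviation_record patient %s site %s>\n", x$patient_id, x$location))
  cat(sprintf("  angular %.2f deg | global %.2f mm | lateral %s mm | depth %.2f mm (signed %+.2f)\n",
              x$angular_deg, x$global_mm,
              if (is.na(x$lateral_mm)) "NA" else sprintf("%.2f", x$lateral_mm),
              x$depth_mm, x$depth_signed_mm))
  invisible(x)
}

#' Convert deviation records to a data frame
#'
#' @param records A single `deviation_record` or a list of them.
#' @return A data frame with one row per record and columns `patient_id`,
#'   `location`, `angular_deg`, `global_mm`, `lateral_mm`, `depth_mm`,
#'   `depth_signed_mm`.
#' @export
deviations_table <- function(records) {
  if (inherits(records, "deviation_record")) records <- list(records)
  stopifnot(length(records) >= 1L)
  do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, location = r$location,
               angular_deg = r$angular_deg, global_mm = r$global_mm,
               lateral_mm = r$lateral_mm, depth_mm = r$depth_mm,
               depth_signed_mm = r$depth_signed_mm,
               stringsAsFactors = FALSE)
  }))
}

#' Construct a rigid transform
#'
#' A proper rigid-body transform `x -> R x + t`. The rotation must be
#' orthonormal with determinant +1 to within 1e-9.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length-3 translation, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > .TOL_IDENT) {
    stop("rotation is not orthonormal (R'R != I within 1e-9)", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > .TOL_IDENT) {
    stop("rotation is not proper (det != +1 within 1e-9)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = .vec3(translation, "translation")),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation: (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points or a pose
#'
#' @param x An [implant_pose()] or an n x 3 matrix of points.
#' @param transform A [rigid_transform()].
#' @return The transformed pose or point matrix.
#' @export
transform_points <- function(x, transform) {
  if (!inherits(transform, "rigid_transform")) {
    stop("transform must be a rigid_transform", call. = FALSE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
  sweep(x %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' @rdname transform_points
#' @param pose An [implant_pose()].
#' @export
transform_pose <- function(pose, transform) {
  .assert_pose(pose)
  pts <- transform_points(rbind(pose$shoulder, pose$apex), transform)
  out <- pose
  out$shoulder <- pts[1, ]
  out$apex <- pts[2, ]
  out
}

#' Rotation matrix about an axis
#'
#' Proper rotation by `angle_rad` radians about the (not necessarily unit)
#' direction `axis`, in Rodrigues form. Convenience for building
#' [rigid_transform()] objects and synthetic perturbations.
#'
#' @param axis Numeric length-3 rotation axis.
#' @param angle_rad Rotation angle, radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_rad) {
  u <- .unit3(.vec3(axis, "rotation axis"), "rotation axis")
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# Orthonormal pair spanning the plane perpendicular to unit vector u.
.perp_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit3(.cross3(u, ref))
  e2 <- .cross3(u, e1)
  list(e1 = e1, e2 = e2)
}
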