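# Rigid point-set registration: closed-form (Kabsch) alignment of
# corresponding point sets, trimmed iterative closest point for surfaces
# without known correspondence, and principal-axis pose fitting of
# segmented implant clouds.

.as_cloud <- function(x, what = "point cloud") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(sprintf("%s must be an n x 3 matrix", what), call. = FALSE)
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite points", what), call. = FALSE)
  x
}

# A configuration is degenerate for rigid fitting when it has fewer than 3
# points or all points are collinear (second principal extent ~ 0).
.check_nondegenerate <- function(x, what = "point cloud") {
  if (nrow(x) < 3L) {
    stop(sprintf("degenerate configuration: %s has fewer than 3 points", what),
         call. = FALSE)
  }
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1)) {
    stop(sprintf("degenerate configuration: %s is collinear", what), call. = FALSE)
  }
  invisible(x)
}

.registration_result <- function(transform, rmsd, iterations, converged,
                                 rmsd_history = numeric()) {
  structure(list(transform = transform, rmsd_mm = rmsd,
                 iterations = as.integer(iterations), converged = converged,
                 rmsd_history = rmsd_history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result rmsd %.6f mm, %d iteration(s), %s>\n",
              x$rmsd_mm, x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

#' Closed-form rigid alignment of corresponding point sets
#'
#' Least-squares proper rigid transform mapping `source` onto `target`,
#' where point i of the source corresponds to point i of the target
#' (Kabsch/Umeyama solution via singular value decomposition of the weighted
#' cross-covariance, with reflection correction so the rotation is proper).
#' Globally optimal for the given correspondence.
#'
#' @param source,target n x 3 matrices of corresponding points, mm.
#' @param weights Optional non-negative per-pair weights.
#' @return A `registration_result`: `transform` ([rigid_transform()]),
#'   `rmsd_mm` (root-mean-square pair distance after alignment, unweighted),
#'   `iterations = 0`, `converged = TRUE`.
#' @export
closed_form_align <- function(source, target, weights = NULL) {
  s <- .as_cloud(source, "source")
  t_ <- .as_cloud(target, "target")
  if (nrow(s) != nrow(t_)) {
    stop("source and target must have equal point counts (point i corresponds to point i)",
         call. = FALSE)
  }
  .check_nondegenerate(s, "source")
  if (is.null(weights)) {
    w <- rep(1, nrow(s))
  } else {
    w <- as.numeric(weights)
    if (length(w) != nrow(s) || any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
      stop("weights must be non-negative, finite, with positive sum", call. = FALSE)
    }
  }
  w <- w / sum(w)
  cs <- colSums(s * w)
  ct <- colSums(t_ * w)
  sc <- sweep(s, 2L, cs)
  tc <- sweep(t_, 2L, ct)
  h <- crossprod(sc * w, tc)  # 3x3 cross-covariance
  dec <- svd(h)
  d <- sign(det(dec$v %*% t(dec$u)))
  rot <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  trans <- ct - as.numeric(rot %*% cs)
  tf <- rigid_transform(rot, trans)
  resid <- transform_points(s, tf) - t_
  .registration_result(tf, sqrt(mean(rowSums(resid^2))), 0L, TRUE)
}

# Exact nearest neighbour of each row of `query` among rows of `ref`,
# brute force via the |q|^2 + |r|^2 - 2 q.r expansion, chunked to bound
# memory. Returns list(index, dist2).
.nearest_neighbours <- function(query, ref, chunk = 2048L) {
  nq <- nrow(query)
  ref2 <- rowSums(ref^2)
  idx <- integer(nq)
  d2 <- numeric(nq)
  for (start in seq(1L, nq, by = chunk)) {
    end <- min(start + chunk - 1L, nq)
    q <- query[start:end, , drop = FALSE]
    dd <- outer(rowSums(q^2), ref2, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-dd, ties.method = "first")
    idx[start:end] <- j
    d2[start:end] <- pmax(dd[cbind(seq_len(nrow(q)), j)], 0)
  }
  list(index = idx, dist2 = d2)
}

#' Trimmed iterative closest point surface alignment
#'
#' Aligns a source cloud onto a target surface with unknown correspondence
#' by alternating exact nearest-neighbour matching and closed-form rigid
#' updates, keeping only the `(1 - trim_fraction)` closest pairs at each
#' iteration (trimmed ICP). Trimming makes the alignment robust to scatter
#' outliers such as metal-artifact speckle around titanium implants. The
#' trimmed RMSD sequence is non-increasing; iteration stops when the
#' improvement falls below `tol_mm` or `max_iter` is reached.
#'
#' @param source,target n x 3 point matrices, mm (counts may differ).
#' @param init Optional [rigid_transform()] starting estimate (default
#'   identity).
#' @param max_iter Maximum number of iterations (default 100).
#' @param tol_mm Convergence threshold on the RMSD improvement (default 1e-6).
#' @param trim_fraction Fraction of worst pairs discarded each iteration, in
#'   \[0, 1); default 0.2. Zero disables trimming.
#' @param pre_align `"none"` (default) or `"principal"`: centroid plus
#'   principal-axes pre-alignment used to seed the iteration when no `init`
#'   is given.
#' @return A `registration_result`; `converged = FALSE` (not an error) if
#'   `max_iter` was exhausted. `rmsd_mm` is the final trimmed RMSD and
#'   `rmsd_history` the per-iteration sequence.
#' @export
iterative_surface_align <- function(source, target, init = NULL,
                                    max_iter = 100L, tol_mm = 1e-6,
                                    trim_fraction = 0.2,
                                    pre_align = c("none", "principal")) {
  s <- .as_cloud(source, "source")
  t_ <- .as_cloud(target, "target")
  .check_nondegenerate(s, "source")
  .check_nondegenerate(t_, "target")
  pre_align <- match.arg(pre_align)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (trim_fraction < 0 || trim_fraction >= 1) {
    stop("trim_fraction must be in [0, 1)", call. = FALSE)
  }
  if (is.null(init)) {
    tf <- if (pre_align == "principal") .principal_prealign(s, t_)
          else rigid_transform()
  } else {
    if (!inherits(init, "rigid_transform")) {
      stop("init must be a rigid_transform", call. = FALSE)
    }
    tf <- init
  }
  keep_n <- max(3L, ceiling((1 - trim_fraction) * nrow(s)))
  history <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- transform_points(s, tf)
    nn <- .nearest_neighbours(cur, t_)
    keep <- order(nn$dist2)[seq_len(keep_n)]
    fit <- closed_form_align(s[keep, , drop = FALSE],
                             t_[nn$index[keep], , drop = FALSE])
    tf <- fit$transform
    resid <- transform_points(s[keep, , drop = FALSE], tf) -
      t_[nn$index[keep], , drop = FALSE]
    rmsd <- sqrt(mean(rowSums(resid^2)))
    history <- c(history, rmsd)
    if (prev - rmsd < tol_mm) {
      converged <- TRUE
      break
    }
    prev <- rmsd
  }
  .registration_result(tf, history[length(history)], iter, converged, history)
}

# Centroid + principal-axes seeding: rotate the source principal frame onto
# the target principal frame (signs chosen to keep the rotation proper).
.principal_prealign <- function(s, t_) {
  vs <- svd(sweep(s, 2L, colMeans(s)), nu = 0)$v
  vt <- svd(sweep(t_, 2L, colMeans(t_)), nu = 0)$v
  if (det(vs) < 0) vs[, 3] <- -vs[, 3]
  if (det(vt) < 0) vt[, 3] <- -vt[, 3]
  rot <- vt %*% t(vs)
  rigid_transform(rot, colMeans(t_) - as.numeric(rot %*% colMeans(s)))
}

# Refine an initial cylinder axis (and its lateral position) by minimising
# the variance of radial point distances over the mid-shaft (end caps and
# their rims excluded via a mask fixed from the initial axis). Exact on a
# noiseless cylinder: the true axis gives zero radial variance. PCA alone
# leaves a finite-sample tilt of a few tenths of a degree on random surface
# samplings; this step removes it.
.refine_cylinder_axis <- function(xc, axis0) {
  b <- .perp_basis(axis0)
  t0 <- as.numeric(xc %*% axis0)
  lo <- quantile(t0, 0.15)
  hi <- quantile(t0, 0.85)
  mid <- which(t0 > lo & t0 < hi)
  # Sparse clouds (e.g. bare mesh vertices concentrated at the end rims)
  # leave nothing in the mid-shaft; the PCA axis is then the best estimate.
  if (length(mid) < 30L) {
    return(list(axis = axis0, point = c(0, 0, 0)))
  }
  obj <- function(par) {
    ax <- .unit3(axis0 + par[1] * b$e1 + par[2] * b$e2)
    p0 <- par[3] * b$e1 + par[4] * b$e2
    d <- sweep(xc[mid, , drop = FALSE], 2L, p0)
    t_ax <- as.numeric(d %*% ax)
    r2 <- pmax(rowSums(d^2) - t_ax^2, 0)
    stats::var(sqrt(r2))
  }
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 4000))
  list(axis = .unit3(axis0 + fit$par[1] * b$e1 + fit$par[2] * b$e2),
       point = fit$par[3] * b$e1 + fit$par[4] * b$e2)
}

#' Fit an implant pose to a segmented implant point cloud
#'
#' Estimates the pose of an approximately cylindrical implant from its
#' segmented surface cloud, the way a virtual analogue is seated on a
#' post-operative scan. The axis starts from the dominant principal
#' direction of the centred cloud and is refined by a cylinder fit that
#' minimises the spread of radial point distances over the mid-shaft; its
#' apical orientation is disambiguated by `apex_hint` (a point on the
#' apical side), otherwise the returned pose is flagged
#' orientation-ambiguous. The shoulder is located on the fitted axis at the
#' coronal cap: within the coronal 10% slab, cap points are separated from
#' side-wall points by radial distance (below 0.8 of the estimated implant
#' radius) and the shoulder is their mean axial position; if too few cap
#' points are found the slab centroid is used. The apex is placed
#' `nominal_length_mm` apical of the shoulder.
#'
#' @param cloud n x 3 point matrix of the segmented implant surface, mm.
#' @param nominal_length_mm Implant length used to place the apex, mm.
#' @param apex_hint Optional length-3 point on the apical side of the cloud.
#' @param patient_id,location Identifiers stamped on the returned pose.
#' @return An [implant_pose()] (role `"placed"`) with an extra attribute
#'   `orientation_ambiguous` (TRUE when no `apex_hint` was given).
#' @export
fit_analogue_pose <- function(cloud, nominal_length_mm, apex_hint = NULL,
                              patient_id = "unknown", location = "00") {
  x <- .as_cloud(cloud, "implant cloud")
  if (nrow(x) < 10L) stop("unfittable: implant cloud has too few points", call. = FALSE)
  if (!is.finite(nominal_length_mm) || nominal_length_mm <= 0) {
    stop("nominal_length_mm must be positive", call. = FALSE)
  }
  centroid <- colMeans(x)
  xc <- sweep(x, 2L, centroid)
  dec <- svd(xc, nu = 0)
  if (dec$d[1] < 1.5 * dec$d[2]) {
    stop("unfittable: cloud has no dominant axis (anisotropy ratio < 1.5)",
         call. = FALSE)
  }
  axis <- dec$v[, 1]
  ambiguous <- is.null(apex_hint)
  if (!ambiguous) {
    hint <- .vec3(apex_hint, "apex_hint")
    if (sum((hint - centroid) * axis) < 0) axis <- -axis
  }
  ref <- .refine_cylinder_axis(xc, axis)
  axis <- ref$axis
  xc <- sweep(xc, 2L, ref$point)             # axis line through centroid + point
  centroid <- centroid + ref$point
  t_ax <- as.numeric(xc %*% axis)            # axial coordinate, apical positive
  radial <- sqrt(pmax(rowSums(xc^2) - t_ax^2, 0))
  t_lo <- min(t_ax)
  span <- max(t_ax) - t_lo
  slab <- t_ax <= t_lo + 0.1 * span          # coronal 10% slab
  # Radius from mid-shaft points so end caps do not bias it.
  mid <- t_ax > t_lo + 0.25 * span & t_ax < t_lo + 0.75 * span
  r_est <- if (any(mid)) median(radial[mid]) else median(radial)
  cap <- slab & radial < 0.8 * r_est
  t_shoulder <- if (sum(cap) >= 10L) mean(t_ax[cap]) else mean(t_ax[slab])
  shoulder <- centroid + t_shoulder * axis
  pose <- implant_pose(patient_id, location, "placed",
                       shoulder = shoulder,
                       apex = shoulder + nominal_length_mm * axis)
  attr(pose, "orientation_ambiguous") <- ambiguous
  pose
}
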