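#' Pinhole viewer camera
#'
#' The viewer's head: eye position, gaze direction and pinhole intrinsics.
#' Image coordinates are pixels with the origin at the top-left corner,
#' x to the right, y down, and the principal point at the image centre.
#' The focal length in pixels is `(height_px / 2) / tan(vfov / 2)`.
#'
#' @param eye numeric(3), eye position in scene millimetres.
#' @param gaze numeric(3), viewing direction (normalised internally).
#' @param up numeric(3), approximate up direction; must not be parallel to
#'   `gaze`. The camera basis is re-orthogonalised internally.
#' @param vfov_deg vertical field of view in degrees, in (0, 180).
#' @param width_px,height_px viewport size in pixels (positive integers).
#' @return an object of class `viewer_camera`.
#' @export
viewer_camera <- function(eye, gaze, up = c(0, 1, 0), vfov_deg = 60,
                          width_px = 1000, height_px = 1000) {
  stopifnot(length(eye) == 3, length(gaze) == 3, length(up) == 3,
            all(is.finite(c(eye, gaze, up))))
  if (!(vfov_deg > 0 && vfov_deg < 180)) stop("vfov_deg must be in (0, 180)")
  if (width_px < 1 || height_px < 1) stop("viewport dimensions must be positive")
  fwd <- vunit(gaze)
  if (vnorm(vcross(fwd, up)) < 1e-9) stop("gaze and up must not be parallel")
  structure(list(eye = as.numeric(eye), gaze = fwd, up = vunit(up),
                 vfov_deg = vfov_deg,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px)),
            class = "viewer_camera")
}

# Orthonormal camera frame plus intrinsics.
camera_frame <- function(cam) {
  fwd <- cam$gaze
  right <- vunit(vcross(fwd, cam$up))
  upv <- vcross(right, fwd)
  f <- (cam$height_px / 2) / tan(cam$vfov_deg * pi / 360)
  list(fwd = fwd, right = right, up = upv, f = f,
       cx = cam$width_px / 2, cy = cam$height_px / 2)
}

#' Project scene points through a viewer camera
#'
#' @param pts numeric matrix (n x 3) of scene points (mm), or a single
#'   length-3 vector.
#' @param cam a [viewer_camera()].
#' @return n x 2 matrix of pixel coordinates (x right, y down).
#' @details Errors if any point lies at or behind the camera plane: the
#'   analytic projection layer does no clipping.
#' @export
project_points <- function(pts, cam) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  fr <- camera_frame(cam)
  q <- sweep(pts, 2, cam$eye)
  z <- as.vector(q %*% fr$fwd)
  if (any(z <= 1e-9)) stop("point at or behind the camera; no clipping support")
  x <- as.vector(q %*% fr$right)
  y <- as.vector(q %*% fr$up)
  cbind(fr$cx + fr$f * x / z, fr$cy - fr$f * y / z)
}

#' Image-space ellipse
#'
#' An ellipse in screenshot pixel coordinates. `phi_deg` is the major-axis
#' orientation in degrees measured from the +x image axis toward +y (image
#' y points down), normalised to `[0, 180)`; this matches the convention of
#' common image-analysis tools. If `a < b` on input the axes are swapped and
#' the orientation rotated by 90 degrees.
#'
#' @param cx_px,cy_px centre (pixels).
#' @param a_px,b_px semi-major and semi-minor axes (pixels), `a_px >= b_px > 0`.
#' @param phi_deg major-axis orientation (degrees).
#' @return object of class `image_ellipse`.
#' @export
image_ellipse <- function(cx_px, cy_px, a_px, b_px, phi_deg = 0) {
  stopifnot(is.finite(cx_px), is.finite(cy_px),
            is.finite(a_px), is.finite(b_px), is.finite(phi_deg))
  if (a_px < b_px) {
    tmp <- a_px; a_px <- b_px; b_px <- tmp
    phi_deg <- phi_deg + 90
  }
  if (b_px <= 0) stop("ellipse semi-axes must be positive")
  phi_deg <- phi_deg %% 180
  structure(list(cx_px = cx_px, cy_px = cy_px, a_px = a_px, b_px = b_px,
                 phi_deg = phi_deg),
            class = "image_ellipse")
}

#' @export
print.image_ellipse <- function(x, ...) {
  cat(sprintf("<image_ellipse> centre (%.2f, %.2f) px, a %.2f px, b %.2f px, phi %.1f deg\n",
              x$cx_px, x$cy_px, x$a_px, x$b_px, x$phi_deg))
  invisible(x)
}

# Quadratic form of a point relative to an ellipse: <= 1 means inside.
ellipse_quadform <- function(e, x, y) {
  phi <- e$phi_deg * pi / 180
  dx <- x - e$cx_px; dy <- y - e$cy_px
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  (xr / e$a_px)^2 + (yr / e$b_px)^2
}

# Parametric boundary points of an image ellipse (k x 2 matrix).
ellipse_boundary_points <- function(e, k = 64) {
  t <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  phi <- e$phi_deg * pi / 180
  x0 <- e$a_px * cos(t); y0 <- e$b_px * sin(t)
  cbind(e$cx_px + x0 * cos(phi) - y0 * sin(phi),
        e$cy_px + x0 * sin(phi) + y0 * cos(phi))
}

#' Mirror plane
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal (normalised internally).
#' @return object of class `mirror_plane`.
#' @export
mirror_plane <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = vunit(normal)),
            class = "mirror_plane")
}

#' Reflect points through a planar mirror
#'
#' `p - 2 ((p - q) . n) n` with `q` a point on the plane and `n` its unit
#' normal: the planar-mirror virtual-image map. An involution and an isometry.
#'
#' @param p point (length-3) or n x 3 matrix of points.
#' @param plane a [mirror_plane()].
#' @return reflected point(s), same shape as `p`.
#' @export
reflect_point <- function(p, plane) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, ncol = 3)
  d <- sweep(p, 2, plane$point) %*% plane$normal
  out <- p - 2 * as.vector(d) %o% plane$normal
  if (vec) as.vector(out) else out
}

#' Reflect a direction through a mirror plane (no translation)
#' @param d direction vector (length 3).
#' @param plane a [mirror_plane()].
#' @return reflected direction.
#' @export
reflect_direction <- function(d, plane) {
  d - 2 * vdot(d, plane$normal) * plane$normal
}

#' Virtual image of a circular disc behind a planar mirror
#'
#' The mirror-image camera construction is symmetric: the virtual image of a
#' disc is the disc reflected through the mirror plane (centre by
#' [reflect_point()], normal as a direction, diameter preserved).
#'
#' @param disc a disc (e.g. [lesion_disc()] or [mirror_disc()]).
#' @param plane a [mirror_plane()].
#' @return a disc of the same class with reflected pose.
#' @export
virtual_image_of_disc <- function(disc, plane) {
  disc$center <- reflect_point(disc$center, plane)
  disc$normal <- reflect_direction(disc$normal, plane)
  disc
}

# Exact ellipse through >= 6 boundary points of a true conic: algebraic conic
# fit (smallest singular vector of the design matrix) in normalised
# coordinates, then conversion to centre/axes/orientation.
fit_ellipse_points <- function(xy) {
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  s <- mean(sqrt((xy[, 1] - mx)^2 + (xy[, 2] - my)^2))
  if (s < 1e-12) stop("degenerate point set for conic fit")
  x <- (xy[, 1] - mx) / s; y <- (xy[, 2] - my) / s
  D <- cbind(x^2, x * y, y^2, x, y, 1)
  v <- svd(D, nu = 0)$v[, 6]
  A <- v[1]; B <- v[2]; C <- v[3]; Dd <- v[4]; E <- v[5]; Ff <- v[6]
  det0 <- 4 * A * C - B^2
  if (det0 <= 0) stop("projected boundary is not an ellipse")
  cx <- (B * E - 2 * C * Dd) / det0
  cy <- (B * Dd - 2 * A * E) / det0
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + Dd * cx + E * cy + Ff
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(M, symmetric = TRUE)
  ax <- sqrt(-F0 / eg$values)          # increasing with decreasing eigenvalue
  if (any(!is.finite(ax))) stop("projected boundary is not an ellipse")
  i_major <- which.max(ax)
  vec <- eg$vectors[, i_major]
  phi <- atan2(vec[2], vec[1]) * 180 / pi
  image_ellipse(cx * s + mx, cy * s + my,
                max(ax) * s, min(ax) * s, phi)
}

# Boundary samples of a 3-D disc (k x 3 matrix).
disc_boundary <- function(disc, k = 256) {
  b <- plane_basis(vunit(disc$normal))
  t <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  r <- disc$diameter_mm / 2
  outer(cos(t) * r, b$u) + outer(sin(t) * r, b$v) +
    matrix(disc$center, k, 3, byrow = TRUE)
}

#' Perspective image of a circular disc
#'
#' Pinhole-projects `k` boundary samples of the disc and fits the exact
#' conic through them. For a disc fully in front of the camera the image of
#' a circle is an ellipse; the fit residual is at numerical-noise level.
#'
#' @param disc a disc with fields `center`, `normal`, `diameter_mm`.
#' @param cam a [viewer_camera()].
#' @param k number of boundary samples (default 256).
#' @return an [image_ellipse()].
#' @export
project_disc <- function(disc, cam, k = 256) {
  fit_ellipse_points(project_points(disc_boundary(disc, k), cam))
}

#' Analytic mirror view: mirror and lesion image ellipses
#'
#' Projects the mirror disc and the lesion's virtual image into the viewer
#' camera, reproducing the symmetric mirror-image-camera configuration.
#' Geometry lying between the mirror surface and the virtual image is
#' deliberately ignored (no occlusion test), matching the rendering rule the
#' simulator emulates. `bc_clipped` reports whether any part of the lesion
#' image falls outside the mirror ellipse; the analytic ellipses are *not*
#' clipped (rasterisation clips).
#'
#' @param viewer a [viewer_camera()].
#' @param mirror a [mirror_disc()]; its normal must face the viewer.
#' @param lesion a [lesion_disc()].
#' @param scene optional scene (unused at the analytic level; visibility is a
#'   scene-module criterion, see [check_criteria()]).
#' @param k boundary samples per disc.
#' @return list with `dm`, `bc` ([image_ellipse()]s) and `bc_clipped` (flag).
#' @export
mirror_view <- function(viewer, mirror, lesion, scene = NULL, k = 256) {
  if (vdot(mirror$normal, viewer$eye - mirror$center) <= 0)
    stop("mirror faces away from the viewer")
  plane <- mirror_plane(mirror$center, mirror$normal)
  dm <- project_disc(mirror, viewer, k)
  bc <- project_disc(virtual_image_of_disc(lesion, plane), viewer, k)
  pts <- ellipse_boundary_points(bc, 64)
  bc_clipped <- any(ellipse_quadform(dm, pts[, 1], pts[, 2]) > 1 + 1e-9)
  list(dm = dm, bc = bc, bc_clipped = bc_clipped)
}
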