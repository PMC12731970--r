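#' Scene primitives and the intraoral task model
#'
#' The dentition is modelled with parameterised primitives rather than
#' scanned meshes: capsules for the anterior teeth of both arches placed on
#' a parabolic arch curve, an ellipsoid tongue, and an axis-aligned frame
#' box standing in for the lips/cheek mucosa that bound the working space.
#' The occlusal plane is the plane z = 0, which is perpendicular to the
#' ground plane y = 0 (its normal is horizontal), and the viewer works from
#' the 12 o'clock position: behind the head, looking along -z into the open
#' mouth. The maxillary crowns end near z = +1.5 mm and the mandibular
#' crowns near z = -13.5 mm, leaving the inter-arch working space the
#' mirror head occupies.
#'
#' @name scene
NULL

TASK_TEETH <- c(12L, 21L, 31L, 42L)

# FDI label, arch ('U'pper/'L'ower), x position on the arch (mm), crown radius.
.tooth_table <- function() {
  data.frame(
    fdi  = c(12L, 11L, 21L, 22L, 42L, 41L, 31L, 32L),
    arch = c("U", "U", "U", "U", "L", "L", "L", "L"),
    x    = c(12.5, 4.3, -4.3, -12.5, 9.5, 3.2, -3.2, -9.5),
    r    = c(3.2, 4.2, 4.2, 3.2, 2.8, 2.6, 2.6, 2.8),
    stringsAsFactors = FALSE
  )
}

#' Circular mirror disc (the dental mirror head)
#'
#' @param center centre in scene mm.
#' @param normal unit normal of the reflective face.
#' @param diameter_mm mirror diameter, default 20 mm.
#' @return object of class `mirror_disc`.
#' @export
mirror_disc <- function(center, normal, diameter_mm = 20) {
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  structure(list(center = as.numeric(center), normal = vunit(normal),
                 diameter_mm = diameter_mm),
            class = "mirror_disc")
}

#' Circular caries lesion disc
#'
#' @param center centre in scene mm.
#' @param normal unit surface normal.
#' @param diameter_mm lesion diameter, default 3 mm.
#' @param tooth FDI label of the carrying tooth, one of 12, 21, 31, 42 (or
#'   NA for free-standing discs).
#' @return object of class `lesion_disc`.
#' @export
lesion_disc <- function(center, normal, diameter_mm = 3, tooth = NA_integer_) {
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  if (!is.na(tooth) && !(tooth %in% TASK_TEETH))
    stop("tooth must be one of 12, 21, 31, 42")
  structure(list(center = as.numeric(center), normal = vunit(normal),
                 diameter_mm = diameter_mm, tooth = as.integer(tooth)),
            class = "lesion_disc")
}

#' Handpiece tip
#' @param tip tip position (mm).
#' @param axis unit direction of the instrument shaft.
#' @return object of class `handpiece_tip`.
#' @export
handpiece_tip <- function(tip, axis = c(0, 0, 1)) {
  structure(list(tip = as.numeric(tip), axis = vunit(axis)),
            class = "handpiece_tip")
}

#' Build the default intraoral scene
#'
#' @param config optional list overriding `arch_width_mm` (default 50),
#'   `arch_depth_mm` (default 25), `tongue_axes_mm` (default c(16, 9, 7))
#'   and `frame_box_mm` (list with `min`, `max`). All dimensions positive.
#' @return object of class `scene_model` with tooth capsules (one per FDI
#'   label), a tongue ellipsoid, the frame box, per-tooth mirror-facing
#'   surface anchors, and the occlusal plane normal (horizontal, so the
#'   occlusal plane is perpendicular to the ground).
#' @export
build_default_scene <- function(config = list()) {
  arch_width <- config$arch_width_mm %||% 50
  arch_depth <- config$arch_depth_mm %||% 25
  tongue_axes <- config$tongue_axes_mm %||% c(16, 9, 7)
  if (arch_width <= 0 || arch_depth <= 0 || any(tongue_axes <= 0))
    stop("scene configuration error: dimensions must be positive")

  k <- arch_depth / (arch_width / 2)^2    # parabola drop per mm^2
  y_front_u <- 25
  y_front_l <- 24
  tt <- .tooth_table()

  teeth <- lapply(seq_len(nrow(tt)), function(i) {
    row <- tt[i, ]
    upper <- row$arch == "U"
    yc <- (if (upper) y_front_u else y_front_l) - k * row$x^2
    seg <- if (upper) c(3, 11) else c(-23, -15)
    crown_z <- if (upper) 1.5 else -13.5
    # Surface the mirror faces in the 12 o'clock posture: lingual for
    # maxillary, labial for mandibular anteriors (configurable via the
    # anchor fields of the returned scene).
    if (upper) {
      nrm <- vunit(c(0, -0.93, -0.37))
      anchor <- c(row$x, yc - row$r, crown_z)
    } else {
      nrm <- vunit(c(0, 1, 1))
      anchor <- c(row$x, yc + row$r, crown_z)
    }
    list(fdi = row$fdi,
         p0 = c(row$x, yc, seg[1]), p1 = c(row$x, yc, seg[2]),
         radius = row$r,
         anchor = anchor, anchor_normal = nrm)
  })
  names(teeth) <- as.character(tt$fdi)

  frame_box <- config$frame_box_mm %||%
    list(min = c(-30, -10, -30), max = c(30, 50, 20))
  if (any(unlist(frame_box$max) <= unlist(frame_box$min)))
    stop("scene configuration error: frame box must have positive extent")

  structure(list(
    teeth = teeth,
    tongue = list(center = c(0, 3, -22), axes = as.numeric(tongue_axes)),
    frame_box = frame_box,
    occlusal_plane_normal = c(0, 0, 1),
    arch_width_mm = arch_width, arch_depth_mm = arch_depth
  ), class = "scene_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Place the caries lesion on a task tooth
#'
#' Anchors a 3 mm lesion disc on the chosen tooth's mirror-facing surface,
#' with the disc normal along the surface normal.
#'
#' @param scene a [build_default_scene()] scene.
#' @param tooth FDI label, one of 12, 21, 31, 42.
#' @param diameter_mm lesion diameter (default 3).
#' @return a [lesion_disc()].
#' @export
place_lesion <- function(scene, tooth, diameter_mm = 3) {
  if (!(tooth %in% TASK_TEETH)) stop("tooth must be one of 12, 21, 31, 42")
  th <- scene$teeth[[as.character(tooth)]]
  lesion_disc(th$anchor, th$anchor_normal, diameter_mm, tooth)
}

# ---- distance / intersection helpers ---------------------------------------

# Closest distance between segment (p0,p1) and segment (q0,q1).
segment_segment_distance <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0; d2 <- q1 - q0; r <- p0 - q0
  a <- vdot(d1, d1); e <- vdot(d2, d2); f <- vdot(d2, r)
  if (a < 1e-14 && e < 1e-14) return(vnorm(r))
  if (a < 1e-14) {
    s <- 0; t <- min(1, max(0, f / e))
  } else {
    c1 <- vdot(d1, r)
    if (e < 1e-14) {
      t <- 0; s <- min(1, max(0, -c1 / a))
    } else {
      b <- vdot(d1, d2)
      denom <- a * e - b * b
      s <- if (denom > 1e-14) min(1, max(0, (b * f - c1 * e) / denom)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(1, max(0, -c1 / a)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c1) / a)) }
    }
  }
  vnorm((p0 + s * d1) - (q0 + t * d2))
}

# Closest point on a disc to point p.
closest_point_on_disc <- function(disc, p) {
  n <- vunit(disc$normal)
  q <- p - vdot(p - disc$center, n) * n       # project to disc plane
  v <- q - disc$center
  r <- disc$diameter_mm / 2
  if (vnorm(v) > r) q <- disc$center + vunit(v) * r
  q
}

# Minimum distance between a disc and a segment, by alternating projection
# (deterministic, converges quickly for convex sets).
disc_segment_distance <- function(disc, p0, p1, iters = 8) {
  d <- p1 - p0; a <- vdot(d, d)
  s <- if (a < 1e-14) 0 else min(1, max(0, vdot(disc$center - p0, d) / a))
  q <- p0 + s * d
  for (i in seq_len(iters)) {
    c_on_disc <- closest_point_on_disc(disc, q)
    s <- if (a < 1e-14) 0 else min(1, max(0, vdot(c_on_disc - p0, d) / a))
    q <- p0 + s * d
  }
  vnorm(q - closest_point_on_disc(disc, q))
}

# Does segment (p0,p1) pass within `radius` of capsule segment? (occlusion)
segment_hits_capsule <- function(p0, p1, cap) {
  segment_segment_distance(p0, p1, cap$p0, cap$p1) <= cap$radius
}

# Does segment (p0,p1) intersect the ellipsoid? Solved in the scaled space
# where the ellipsoid is the unit sphere.
segment_hits_ellipsoid <- function(p0, p1, ell) {
  a0 <- (p0 - ell$center) / ell$axes
  a1 <- (p1 - ell$center) / ell$axes
  d <- a1 - a0
  A <- vdot(d, d); B <- 2 * vdot(a0, d); C <- vdot(a0, a0) - 1
  if (A < 1e-14) return(C <= 0)
  disc <- B * B - 4 * A * C
  if (disc < 0) return(FALSE)
  sq <- sqrt(disc)
  t1 <- (-B - sq) / (2 * A); t2 <- (-B + sq) / (2 * A)
  (t1 <= 1 && t2 >= 0)
}

point_in_ellipsoid <- function(p, ell) {
  sum(((p - ell$center) / ell$axes)^2) <= 1
}

point_in_box <- function(p, box) {
  all(p >= box$min) && all(p <= box$max)
}

# ---- validity criteria ------------------------------------------------------

#' Task validity criteria
#'
#' Evaluates the stop criteria for a task: the entire mirror must be visible
#' (inside the viewport and unoccluded by teeth or tongue), and the mirror
#' must not penetrate the tongue, mucosa (frame box walls) or teeth. In
#' trial 2 the handpiece tip must additionally lie within the frame box and
#' must not overlap the lesion's mirror image.
#'
#' Visibility uses 32 eye-to-boundary rays; tangency counts as occluded
#' (conservative). Penetration uses the exact disc-to-capsule distance plus
#' 64 boundary samples against the tongue ellipsoid and the box walls.
#'
#' @param scene a [build_default_scene()] scene.
#' @param viewer a [viewer_camera()].
#' @param mirror a [mirror_disc()].
#' @param trial 1 or 2.
#' @param tip a [handpiece_tip()]; required iff `trial == 2`.
#' @param lesion a [lesion_disc()]; required for the trial-2 overlap test.
#' @return list of class `validity_flags` with `mirror_fully_visible`,
#'   `no_penetration`, and (trial 2) `tip_in_box`, `tip_clear_of_bc`
#'   (NA in trial 1).
#' @export
check_criteria <- function(scene, viewer, mirror, trial, tip = NULL,
                           lesion = NULL) {
  if (!trial %in% c(1, 2)) stop("trial must be 1 or 2")
  if (trial == 2 && is.null(tip)) stop("trial 2 requires a handpiece tip")

  caps <- scene$teeth
  tongue <- scene$tongue
  box <- scene$frame_box

  # full visibility: projected boundary inside viewport, rays unobstructed
  bnd32 <- disc_boundary(mirror, 32)
  visible <- TRUE
  xy <- tryCatch(project_points(rbind(bnd32, mirror$center), viewer),
                 error = function(e) NULL)
  if (is.null(xy) ||
      any(xy[, 1] < 0 | xy[, 1] >= viewer$width_px |
          xy[, 2] < 0 | xy[, 2] >= viewer$height_px)) {
    visible <- FALSE
  } else {
    for (i in seq_len(nrow(bnd32))) {
      p <- bnd32[i, ]
      # shorten the ray slightly so the mirror itself never "occludes"
      pe <- viewer$eye + 0.999 * (p - viewer$eye)
      if (any(vapply(caps, function(cp)
            segment_hits_capsule(viewer$eye, pe, cp), logical(1))) ||
          segment_hits_ellipsoid(viewer$eye, pe, tongue)) {
        visible <- FALSE
        break
      }
    }
  }

  # penetration: positive clearance to every tooth and the tongue, and the
  # whole mirror inside the frame box
  bnd64 <- disc_boundary(mirror, 64)
  no_pen <- TRUE
  for (cp in caps) {
    if (disc_segment_distance(mirror, cp$p0, cp$p1) <= cp$radius) {
      no_pen <- FALSE
      break
    }
  }
  if (no_pen) {
    inside_tongue <- point_in_ellipsoid(mirror$center, tongue) ||
      any(apply(bnd64, 1, point_in_ellipsoid, ell = tongue))
    outside_box <- !point_in_box(mirror$center, box) ||
      !all(apply(bnd64, 1, point_in_box, box = box))
    if (inside_tongue || outside_box) no_pen <- FALSE
  }

  tip_in <- NA
  tip_clear <- NA
  if (trial == 2) {
    tip_in <- point_in_box(tip$tip, box)
    if (is.null(lesion)) stop("trial 2 requires the lesion for the overlap test")
    mv <- mirror_view(viewer, mirror, lesion)
    tp <- tryCatch(project_points(tip$tip, viewer), error = function(e) NULL)
    tip_clear <- !is.null(tp) &&
      ellipse_quadform(mv$bc, tp[1, 1], tp[1, 2]) > 1
  }

  structure(list(mirror_fully_visible = visible,
                 no_penetration = no_pen,
                 tip_in_box = tip_in,
                 tip_clear_of_bc = tip_clear),
            class = "validity_flags")
}

#' Task list for one session
#'
#' Two trials of four tasks each; within a trial the four target teeth
#' (12, 21, 31, 42) appear exactly once each, in random order.
#'
#' @param seed integer seed for the task order.
#' @return data.frame with `task_index` (1..8), `trial` (1,1,1,1,2,2,2,2)
#'   and `tooth`.
#' @export
make_session <- function(seed = 1) {
  set.seed(as.integer(seed))
  data.frame(task_index = 1:8,
             trial = rep(c(1L, 2L), each = 4),
             tooth = c(sample(TASK_TEETH), sample(TASK_TEETH)))
}
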