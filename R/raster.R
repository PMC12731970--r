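#' Labelled screenshot rasterisation and moment-based re-measurement
#'
#' These functions emulate the screenshot-analysis stage: the analytic
#' mirror/lesion ellipses are rasterised into a labelled screenshot
#' (background = 0, mirror surface = 1, lesion image = 2), and the ellipses
#' are then re-measured from pixels alone via image moments, exactly as a
#' screenshot from the head-mounted display would be measured in an image
#' analysis tool.
#'
#' Rasterisation uses pixel-centre sampling: a pixel belongs to an ellipse
#' iff its centre does. The viewport is the half-open region
#' `[0, width) x [0, height)` with y down; pixel `(i, j)` (column, row,
#' 1-based) has its centre at `(i - 0.5, j - 0.5)`.
#'
#' @name raster_measure
NULL

LABEL_BACKGROUND <- 0L
LABEL_DM <- 1L
LABEL_BC <- 2L

#' Render a labelled screenshot of the mirror view
#'
#' Fills the mirror ellipse with the DM label, then overwrites with the BC
#' label inside the intersection of the lesion ellipse and the mirror
#' ellipse: the mirror clips its content. Deterministic for `noise_rate = 0`.
#'
#' @param dm mirror [image_ellipse()] (must be at least partly on-screen).
#' @param bc lesion [image_ellipse()].
#' @param width,height canvas size in pixels.
#' @param noise_rate optional label-flip rate in `[0, 1)` emulating
#'   segmentation noise (default 0, i.e. clean labels); flips are sampled
#'   from the current RNG stream.
#' @return object of class `screenshot`: list with `width_px`, `height_px`
#'   and integer `labels` matrix (height x width, row = image y).
#' @export
render_screenshot <- function(dm, bc, width = 1000, height = 1000,
                              noise_rate = 0) {
  if (width < 1 || height < 1) stop("canvas dimensions must be positive")
  labels <- matrix(LABEL_BACKGROUND, nrow = height, ncol = width)

  fill <- function(e, lab, mask = NULL) {
    # bounding box of the ellipse, clamped to the canvas
    ext <- sqrt((e$a_px * cos(e$phi_deg * pi / 180))^2 +
                (e$b_px * sin(e$phi_deg * pi / 180))^2)
    eyt <- sqrt((e$a_px * sin(e$phi_deg * pi / 180))^2 +
                (e$b_px * cos(e$phi_deg * pi / 180))^2)
    i0 <- max(1L, floor(e$cx_px - ext) + 1L); i1 <- min(width, ceiling(e$cx_px + ext))
    j0 <- max(1L, floor(e$cy_px - eyt) + 1L); j1 <- min(height, ceiling(e$cy_px + eyt))
    if (i0 > i1 || j0 > j1) return(invisible(NULL))
    xs <- (i0:i1) - 0.5
    ys <- (j0:j1) - 0.5
    g <- expand.grid(x = xs, y = ys)
    inside <- ellipse_quadform(e, g$x, g$y) <= 1
    if (!is.null(mask)) inside <- inside & (ellipse_quadform(mask, g$x, g$y) <= 1)
    sel <- matrix(inside, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    sub <- labels[j0:j1, i0:i1, drop = FALSE]
    sub[sel] <- lab
    labels[j0:j1, i0:i1] <<- sub
    invisible(NULL)
  }

  fill(dm, LABEL_DM)
  if (all(labels == LABEL_BACKGROUND))
    stop("mirror ellipse falls entirely outside the viewport")
  fill(bc, LABEL_BC, mask = dm)

  if (noise_rate > 0) {
    n_flip <- stats::rbinom(1, length(labels), noise_rate)
    if (n_flip > 0) {
      idx <- sample.int(length(labels), n_flip)
      labels[idx] <- sample(c(LABEL_BACKGROUND, LABEL_DM, LABEL_BC),
                            n_flip, replace = TRUE)
    }
  }

  structure(list(width_px = as.integer(width), height_px = as.integer(height),
                 labels = labels),
            class = "screenshot")
}

# Pixel-centre coordinates (x, y) of TRUE cells of a label mask.
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 0.5, y = idx[, 1] - 0.5)
}

#' Fit an ellipse to a pixel set by image moments
#'
#' Computes the centroid and second-order central moments of the pixel set
#' (each pixel contributes its own unit-square variance of 1/12, so a
#' filled region's moments match the continuous region), converts them to
#' axes and orientation, and rescales the axes so the ellipse area equals
#' the pixel count -- the same-area convention of standard image-analysis
#' ellipse fitting.
#'
#' @param pixels logical mask matrix (rows = image y), or a 2-column matrix
#'   of pixel-centre coordinates `(x, y)`.
#' @return an [image_ellipse()].
#' @details Errors for fewer than 16 pixels or a degenerate (collinear)
#'   pixel set.
#' @export
fit_ellipse_moments <- function(pixels) {
  xy <- if (is.logical(pixels)) mask_coords(pixels) else pixels
  n <- nrow(xy)
  if (is.null(n) || n < 16) stop("too few pixels for a stable ellipse fit (< 16)")
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  dx <- xy[, 1] - cx; dy <- xy[, 2] - cy
  m20 <- mean(dx * dx); m02 <- mean(dy * dy); m11 <- mean(dx * dy)
  # degeneracy on the raw point moments (before the pixel-extent term)
  tr <- m20 + m02
  det_raw <- m20 * m02 - m11 * m11
  if (det_raw < 1e-9 * max(tr, 1)^2)
    stop("degenerate pixel set: collinear pixels")
  m20 <- m20 + 1 / 12; m02 <- m02 + 1 / 12
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  s <- sqrt(n / (pi * a * b))            # same-area convention
  phi <- 0.5 * atan2(2 * m11, m20 - m02) * 180 / pi
  image_ellipse(cx, cy, a * s, b * s, phi)
}

#' Measure a labelled screenshot
#'
#' Fits the mirror ellipse on all mirror-surface pixels (the lesion image
#' lies on the mirror, so labels 1 and 2 together form the mirror disc) and
#' the lesion ellipse on lesion pixels; converts pixels to millimetres with
#' the mirror's known physical diameter as the per-image scale reference
#' (`mm_per_px = diameter / (2 a_dm)`, the major axis being preserved under
#' tilt); and infers the mirror-surface inclination
#' `theta = arccos(b_dm / a_dm)`.
#'
#' @param screenshot a [render_screenshot()] screenshot (or one read back
#'   from PNG).
#' @param dm_diameter_mm physical mirror diameter used for calibration
#'   (default 20 mm).
#' @return object of class `mirror_measurement`: list with `dm`, `bc`
#'   ([image_ellipse()]s), `theta_deg` and `mm_per_px`.
#' @export
measure <- function(screenshot, dm_diameter_mm = 20) {
  lab <- screenshot$labels
  if (!any(lab == LABEL_DM)) stop("missing label class: DM")
  if (!any(lab == LABEL_BC)) stop("missing label class: BC")
  dm <- fit_ellipse_moments(lab >= LABEL_DM)
  bc <- fit_ellipse_moments(lab == LABEL_BC)
  mm_per_px <- dm_diameter_mm / (2 * dm$a_px)
  theta_deg <- acos(min(1, dm$b_px / dm$a_px)) * 180 / pi
  structure(list(dm = dm, bc = bc, theta_deg = theta_deg,
                 mm_per_px = mm_per_px),
            class = "mirror_measurement")
}

#' Write / read a labelled screenshot as PNG
#'
#' The label raster is stored in an 8-bit grayscale PNG with raw values
#' 0 (background), 1 (mirror surface), 2 (lesion); an optional RGB preview
#' (dark background, grey mirror, black lesion on white) can be written
#' alongside for human inspection.
#'
#' @param screenshot a screenshot object.
#' @param path output PNG path for the label raster.
#' @param preview_path optional path for an RGB preview PNG.
#' @return `path`, invisibly.
#' @export
write_screenshot_png <- function(screenshot, path, preview_path = NULL) {
  png::writePNG(screenshot$labels / 255, target = path)
  if (!is.null(preview_path)) {
    lab <- screenshot$labels
    r <- ifelse(lab == LABEL_BC, 0, ifelse(lab == LABEL_DM, 0.75, 0.1))
    g <- ifelse(lab == LABEL_BC, 0, ifelse(lab == LABEL_DM, 0.8, 0.1))
    b <- ifelse(lab == LABEL_BC, 0, ifelse(lab == LABEL_DM, 0.85, 0.12))
    arr <- array(c(r, g, b), dim = c(nrow(lab), ncol(lab), 3))
    png::writePNG(arr, target = preview_path)
  }
  invisible(path)
}

#' @rdname write_screenshot_png
#' @export
read_screenshot_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  lab <- round(arr * 255)
  if (!all(lab %in% c(LABEL_BACKGROUND, LABEL_DM, LABEL_BC)))
    stop("not a label screenshot: pixel values outside {0, 1, 2}")
  structure(list(width_px = ncol(lab), height_px = nrow(lab),
                 labels = matrix(as.integer(lab), nrow(lab), ncol(lab))),
            class = "screenshot")
}
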