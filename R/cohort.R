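#' Synthetic operator-cohort generation
#'
#' The cohort generator emulates operator behaviour at the level of the
#' *apparent* (in-mirror-image) quantities the skill metrics measure, so
#' that group-level targets are exactly encodable: the radial offset of the
#' lesion image from the mirror centre is drawn from a Gamma distribution
#' whose mean is the group's target distance, the lesion-image ellipticity
#' target from a scaled Beta, the area-ratio target from a Gamma, and the
#' manipulation time from a log-normal. For each sampled record a full 3-D
#' pose (viewer, mirror disc, lesion disc) is constructed whose *analytic*
#' projected metrics equal the sampled targets, and the record then runs
#' through the complete render -> measure -> metrics pipeline.
#'
#' @name cohortsim
NULL

GROUP_LEVELS <- c("ID", "GS", "TD", "ST")
TOOTH_KEYS <- c("12", "21", "31", "42")

#' Per-group skill profile
#'
#' Target means may be a single number or a 4 x 2 matrix (rows = teeth
#' 12, 21, 31, 42; columns = trials 1, 2) for per-tooth/per-trial
#' calibration.
#'
#' @param group group label ("ID", "GS", "TD", "ST").
#' @param distance_mean_mm target mean radial offset of the lesion image
#'   from the mirror centre (mm); Gamma-distributed with `offset_shape`.
#' @param ellipticity_mean target mean lesion-image ellipticity in (0, 1];
#'   Beta-distributed with standard deviation `ellipticity_sd`.
#' @param ratio_mean_pct target mean lesion/mirror area ratio (%);
#'   Gamma-distributed with standard deviation `ratio_sd_pct`.
#' @param time_mean_s target mean manipulation time (s); log-normal with
#'   log-scale standard deviation `time_sdlog`.
#' @param offset_shape Gamma shape of the radial offset (default 4, i.e.
#'   coefficient of variation 0.5).
#' @param ellipticity_sd,ratio_sd_pct,time_sdlog dispersion parameters.
#' @param mirror_tilt_mean_deg,mirror_tilt_shape Gamma parameters of the
#'   mirror-surface inclination theta (defaults: mean 8 degrees, shape 4).
#' @param task1_time_factor multiplier applied to the very first task's
#'   time (warm-up effect; default 1 = none).
#' @return object of class `skill_profile`.
#' @export
skill_profile <- function(group, distance_mean_mm, ellipticity_mean,
                          ratio_mean_pct, time_mean_s,
                          offset_shape = 4, ellipticity_sd = 0.075,
                          ratio_sd_pct = 0.43, time_sdlog = 0.55,
                          mirror_tilt_mean_deg = 8, mirror_tilt_shape = 4,
                          task1_time_factor = 1) {
  group <- match.arg(group, GROUP_LEVELS)
  chk <- function(x, lo, hi, what) {
    if (any(!is.finite(unlist(x))) || any(unlist(x) <= lo) ||
        any(unlist(x) > hi))
      stop(sprintf("%s out of range", what))
  }
  chk(distance_mean_mm, -1e-12, Inf, "distance_mean_mm")
  chk(ellipticity_mean, 0, 1, "ellipticity_mean")
  chk(ratio_mean_pct, 0, 100, "ratio_mean_pct")
  chk(time_mean_s, 0, Inf, "time_mean_s")
  structure(list(group = group,
                 distance_mean_mm = distance_mean_mm,
                 ellipticity_mean = ellipticity_mean,
                 ratio_mean_pct = ratio_mean_pct,
                 time_mean_s = time_mean_s,
                 offset_shape = offset_shape,
                 ellipticity_sd = ellipticity_sd,
                 ratio_sd_pct = ratio_sd_pct,
                 time_sdlog = time_sdlog,
                 mirror_tilt_mean_deg = mirror_tilt_mean_deg,
                 mirror_tilt_shape = mirror_tilt_shape,
                 task1_time_factor = task1_time_factor),
            class = "skill_profile")
}

# Look up a (possibly per-tooth/per-trial) target.
resolve_target <- function(x, tooth, trial) {
  if (length(x) == 1) return(as.numeric(x))
  m <- as.matrix(x)
  if (!all(dim(m) == c(4, 2)))
    stop("per-cell targets must be a 4 x 2 (tooth x trial) matrix")
  rn <- rownames(m) %||% TOOTH_KEYS
  m[match(as.character(tooth), rn), trial]
}

#' Cohort specification
#'
#' @param profiles named list of [skill_profile()]s (names = group labels).
#' @param n_per_group named integer vector of participants per group;
#'   defaults to the study cohort sizes `c(ID = 25, GS = 24, TD = 17,
#'   ST = 21)` (87 participants).
#' @param seed integer master seed; every record draws from a stream keyed
#'   by (seed, group, participant, task) so results are reproducible under
#'   reordering.
#' @param trials which trials to simulate (default both; each trial is four
#'   tasks covering each target tooth exactly once).
#' @param camera list with capture settings `width_px`, `height_px`,
#'   `vfov_deg`, `view_distance_mm` (defaults 600, 600, 12, 250: a capture
#'   zoomed on the mirror region so both ellipses are well resolved).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(profiles, n_per_group = NULL, seed = 1,
                        trials = c(1L, 2L), camera = list()) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  if (is.null(n_per_group))
    n_per_group <- c(ID = 25L, GS = 24L, TD = 17L, ST = 21L)[names(profiles)]
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  if (any(n_per_group > 99)) stop("n_per_group must be <= 99")
  cam <- list(width_px = camera$width_px %||% 600L,
              height_px = camera$height_px %||% 600L,
              vfov_deg = camera$vfov_deg %||% 12,
              view_distance_mm = camera$view_distance_mm %||% 250)
  structure(list(profiles = profiles,
                 n_per_group = stats::setNames(as.integer(n_per_group),
                                               names(profiles)),
                 seed = as.integer(seed),
                 trials = as.integer(trials),
                 camera = cam),
            class = "cohort_spec")
}

# Deterministic per-record seed; injective for seed < 2000, gidx <= 9,
# participant <= 99, task <= 999.
task_seed <- function(seed, gidx, participant, task) {
  (seed %% 2000L) * 1000000L + gidx * 100000L + participant * 1000L + task
}

# Per-tooth mirror placement and viewing direction (12 o'clock posture).
# Upper teeth: mirror below/behind the crown, viewed nearly along -z;
# lower teeth: mirror above the crown, viewed from a steeper angle. The
# offsets keep the mirror clear of the crowns and visible from the eye for
# surface inclinations up to 35 degrees.
.pose_for_tooth <- function(scene, tooth) {
  th <- scene$teeth[[as.character(tooth)]]
  upper <- tooth %in% c(12L, 21L)
  if (upper) {
    dir <- vunit(c(0, -0.9, -0.436))
    dist <- 17
    u <- vunit(c(0, 0.10, 0.995))
  } else {
    dir <- vunit(c(0, 0.8, 0.6))
    dist <- 16
    u <- vunit(c(0, 0.4, 0.9165))
  }
  list(mirror_center = th$anchor + dist * dir, view_dir = u)
}

#' Sample the geometry and timing of one task
#'
#' Constructs a viewer/mirror/lesion pose whose analytic projected metrics
#' equal the profile's sampled targets: the lesion-image offset is drawn
#' from the Gamma offset distribution and laid along the mirror's tilt axis
#' (where projection preserves length exactly); the lesion tilt and radius
#' are then set by a short fixed-point iteration against the package's own
#' analytic projection so the analytic image ellipticity and area ratio
#' equal the sampled targets. The lesion disc is returned in its stop-state
#' apparent position (coplanar with the mirror surface).
#'
#' @param profile a [skill_profile()].
#' @param tooth FDI tooth label.
#' @param trial 1 or 2.
#' @param task_index task number (1..8), used for the warm-up time factor.
#' @param scene a scene model (default scene if NULL).
#' @param camera capture settings as in [cohort_spec()].
#' @param seed integer seed for this task's stream.
#' @return list with `viewer`, `mirror`, `lesion`, `tip`, `time_s` and
#'   `targets` (the sampled analytic targets).
#' @export
sample_task_geometry <- function(profile, tooth, trial, task_index = 1,
                                 scene = NULL, camera = list(), seed = 1) {
  scene <- scene %||% build_default_scene()
  cam_w <- camera$width_px %||% 600L
  cam_h <- camera$height_px %||% 600L
  vfov <- camera$vfov_deg %||% 12
  vdist <- camera$view_distance_mm %||% 250

  set.seed(as.integer(seed))
  tilt_deg <- if (profile$mirror_tilt_mean_deg <= 0) 0 else
    stats::rgamma(1, shape = profile$mirror_tilt_shape,
                  scale = profile$mirror_tilt_mean_deg / profile$mirror_tilt_shape)
  tilt_deg <- min(tilt_deg, 35)          # keep the mirror usable

  off_mean <- resolve_target(profile$distance_mean_mm, tooth, trial)
  r_off <- if (off_mean <= 0) 0 else
    stats::rgamma(1, shape = profile$offset_shape,
                  scale = off_mean / profile$offset_shape)
  sgn <- sample(c(-1, 1), 1)

  e_mean <- resolve_target(profile$ellipticity_mean, tooth, trial)
  e_t <- sample_beta_mean_sd(1, e_mean, profile$ellipticity_sd)

  ratio_mean <- resolve_target(profile$ratio_mean_pct, tooth, trial)
  ratio_t <- if (profile$ratio_sd_pct <= 0) ratio_mean else
    stats::rgamma(1, shape = (ratio_mean / profile$ratio_sd_pct)^2,
                  scale = profile$ratio_sd_pct^2 / ratio_mean)
  ratio_t <- min(ratio_t, 60)            # keep the lesion image on the mirror

  omega <- stats::runif(1, 0, 2 * pi)

  t_mean <- resolve_target(profile$time_mean_s, tooth, trial)
  if (task_index == 1) t_mean <- t_mean * profile$task1_time_factor
  time_s <- if (profile$time_sdlog <= 0) t_mean else
    stats::rlnorm(1, meanlog = log(t_mean) - profile$time_sdlog^2 / 2,
                  sdlog = profile$time_sdlog)

  pose <- .pose_for_tooth(scene, tooth)
  eye <- pose$mirror_center + vdist * pose$view_dir
  viewer <- viewer_camera(eye, gaze = -pose$view_dir, up = c(0, 1, 0),
                          vfov_deg = vfov, width_px = cam_w, height_px = cam_h)
  fr <- camera_frame(viewer)

  # mirror tilted about the camera-right axis (in the mirror plane), so the
  # projected major axis -- the calibration reference -- stays unforeshortened
  n_m <- rotate_about(pose$view_dir, fr$right, tilt_deg * pi / 180)
  mirror <- mirror_disc(pose$mirror_center, n_m, 20)

  # lesion image centre on the tilt axis: projection preserves its offset
  bc_center <- pose$mirror_center + sgn * r_off * fr$right

  # The lesion's *virtual image* is what the metrics see: place it coplanar
  # with the mirror surface (centre on the mirror plane), tilt it about a
  # random axis perpendicular to the view direction, and solve tilt and
  # radius so the analytic image ellipticity and area ratio equal the
  # sampled targets (secant on the tilt, square-root scaling on the
  # radius). The physical lesion disc returned is the reflection of this
  # virtual image through the mirror plane.
  w_axis <- cos(omega) * fr$right + sin(omega) * fr$up

  dm_e <- project_disc(mirror, viewer)
  eval_pose <- function(phi, r_bc) {
    vb <- lesion_disc(bc_center, rotate_about(pose$view_dir, w_axis, phi),
                      2 * r_bc, tooth)
    pe <- project_disc(vb, viewer)
    list(vb = vb, e = pe$b_px / pe$a_px,
         ratio = 100 * (pe$a_px * pe$b_px) / (dm_e$a_px * dm_e$b_px))
  }
  phi1 <- acos(min(1, e_t))
  r_bc <- 10 * sqrt(ratio_t / 100 / max(e_t, 1e-6))
  ev1 <- eval_pose(phi1, r_bc)
  r_bc <- r_bc * sqrt(ratio_t / ev1$ratio)
  phi2 <- acos(min(1, max(1e-9, cos(phi1) * e_t / ev1$e)))
  ev <- ev1
  for (it in 1:4) {
    if (abs(phi2 - phi1) < 1e-9) break
    ev2 <- eval_pose(phi2, r_bc)
    r_bc <- r_bc * sqrt(ratio_t / ev2$ratio)
    if (abs(ev2$e - e_t) < 1e-6) { ev <- ev2; phi1 <- phi2; break }
    phi_new <- phi2 - (ev2$e - e_t) * (phi2 - phi1) / (ev2$e - ev1$e)
    phi_new <- min(1.45, max(0, phi_new))
    phi1 <- phi2; ev1 <- ev2; phi2 <- phi_new; ev <- ev2
  }
  ev <- eval_pose(if (abs(phi2 - phi1) < 1e-9) phi1 else phi2, r_bc)
  plane <- mirror_plane(mirror$center, mirror$normal)
  lesion <- virtual_image_of_disc(ev$vb, plane)

  tip <- NULL
  if (trial == 2) {
    box <- scene$frame_box
    ctr <- (unlist(box$min) + unlist(box$max)) / 2
    half <- (unlist(box$max) - unlist(box$min)) / 2
    tip_pos <- ctr + pmin(pmax(stats::rnorm(3, 0, 4), -0.8 * half), 0.8 * half)
    tip <- handpiece_tip(tip_pos, c(0, 0, 1))
  }

  list(viewer = viewer, mirror = mirror, lesion = lesion, tip = tip,
       time_s = time_s,
       targets = list(offset_mm = r_off, ellipticity = e_t,
                      ratio_pct = ratio_t, tilt_deg = tilt_deg))
}

# Beta draw parameterised by mean and sd on (0, 1); degenerate sd -> mean.
sample_beta_mean_sd <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  v <- m * (1 - m) / s^2 - 1
  if (v <= 0) v <- 1e-2                  # sd too large for (0,1); near-flat
  stats::rbeta(n, m * v, (1 - m) * v)
}

#' Generate a full synthetic cohort
#'
#' Runs the complete per-record pipeline: sample geometry ->
#' [mirror_view()] -> [render_screenshot()] -> [measure()] -> metrics, with
#' validity criteria evaluated on the sampled pose. With the default group
#' sizes and both trials this yields 87 x 8 = 696 records.
#'
#' @param spec a [cohort_spec()].
#' @param scene a scene model (default scene if NULL).
#' @param compute_validity evaluate [check_criteria()] per record
#'   (default TRUE).
#' @param keep_screenshots if TRUE, attach the rendered screenshots as an
#'   attribute `"screenshots"` (memory-heavy; default FALSE).
#' @return data.frame of metric records, one row per participant x task.
#' @export
generate_cohort <- function(spec, scene = NULL, compute_validity = TRUE,
                            keep_screenshots = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  scene <- scene %||% build_default_scene()
  rows <- list()
  shots <- list()
  for (gidx in seq_along(spec$profiles)) {
    gname <- names(spec$profiles)[gidx]
    profile <- spec$profiles[[gidx]]
    n <- spec$n_per_group[[gname]]
    for (i in seq_len(n)) {
      session <- make_session(task_seed(spec$seed, gidx, i, 999L))
      session <- session[session$trial %in% spec$trials, ]
      for (row in seq_len(nrow(session))) {
        tk <- session[row, ]
        sd_i <- task_seed(spec$seed, gidx, i, tk$task_index)
        rec <- tryCatch(
          .run_task(profile, gname, i, tk$tooth, tk$trial, tk$task_index,
                    scene, spec$camera, sd_i, compute_validity,
                    keep_screenshots),
          error = function(e)
            stop(sprintf("task failed (group %s, participant %d, task %d): %s",
                         gname, i, tk$task_index, conditionMessage(e)))
        )
        rows[[length(rows) + 1]] <- rec$record
        if (keep_screenshots) shots[[length(shots) + 1]] <- rec$screenshot
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_screenshots) attr(out, "screenshots") <- shots
  out
}

.run_task <- function(profile, gname, i, tooth, trial, task_index, scene,
                      camera, seed, compute_validity, keep_screenshot = FALSE) {
  g <- sample_task_geometry(profile, tooth, trial, task_index, scene,
                            camera, seed)
  mv <- mirror_view(g$viewer, g$mirror, g$lesion)
  ss <- render_screenshot(mv$dm, mv$bc, camera$width_px %||% 600L,
                          camera$height_px %||% 600L)
  m <- measure(ss, dm_diameter_mm = g$mirror$diameter_mm)
  flags <- if (compute_validity)
    check_criteria(scene, g$viewer, g$mirror, trial, g$tip, g$lesion)
  else NULL
  rec <- make_record(gname, sprintf("%s_%02d", gname, i), trial, task_index,
                     tooth, m, g$time_s, flags)
  list(record = rec, screenshot = if (keep_screenshot) ss else NULL)
}

#' Built-in calibrated cohort specification
#'
#' Loads the packaged calibration (inst/extdata/calibrated_cohort.yaml),
#' which encodes the per-group target means for the four metrics -- per
#' tooth and trial where reported, interpolated otherwise (cells marked in
#' the file) -- together with the default cohort sizes and dispersions.
#'
#' @param seed master seed (default 1).
#' @param groups subset of groups to include (default all four).
#' @param trials trials to simulate (default both).
#' @return a [cohort_spec()].
#' @export
calibrated_cohort_spec <- function(seed = 1, groups = GROUP_LEVELS,
                                   trials = c(1L, 2L)) {
  path <- system.file("extdata", "calibrated_cohort.yaml",
                      package = "mirrorsim")
  read_cohort_yaml(path, seed = seed, groups = groups, trials = trials)
}

#' Read a cohort specification from YAML
#'
#' @param path YAML file; see the packaged `calibrated_cohort.yaml` for the
#'   format.
#' @param seed master seed.
#' @param groups,trials subsets as in [calibrated_cohort_spec()].
#' @return a [cohort_spec()].
#' @export
read_cohort_yaml <- function(path, seed = 1, groups = NULL, trials = NULL) {
  y <- yaml::read_yaml(path)
  gnames <- names(y$groups)
  if (!is.null(groups)) gnames <- intersect(gnames, groups)
  disp <- y$dispersion %||% list()
  as_tt <- function(x) {
    if (length(x) == 1) return(as.numeric(x))
    m <- do.call(rbind, lapply(x, as.numeric))
    rownames(m) <- TOOTH_KEYS
    m
  }
  profiles <- lapply(gnames, function(g) {
    gg <- y$groups[[g]]
    skill_profile(
      group = g,
      distance_mean_mm = as_tt(gg$distance_mean_mm),
      ellipticity_mean = as_tt(gg$ellipticity_mean),
      ratio_mean_pct = as_tt(gg$ratio_mean_pct),
      time_mean_s = as_tt(gg$time_mean_s),
      offset_shape = disp$offset_shape %||% 4,
      ellipticity_sd = disp$ellipticity_sd %||% 0.075,
      ratio_sd_pct = disp$ratio_sd_pct %||% 0.43,
      time_sdlog = disp$time_sdlog %||% 0.55,
      mirror_tilt_mean_deg = disp$mirror_tilt_mean_deg %||% 8,
      mirror_tilt_shape = disp$mirror_tilt_shape %||% 4
    )
  })
  names(profiles) <- gnames
  n_per_group <- vapply(gnames,
                        function(g) as.integer(y$groups[[g]]$n_participants),
                        integer(1))
  cohort_spec(profiles, n_per_group, seed = seed,
              trials = trials %||% c(1L, 2L),
              camera = y$camera %||% list())
}
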