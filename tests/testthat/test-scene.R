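test_that("default scene has the expected structure and is deterministic", {
  sc <- build_default_scene()
  expect_s3_class(sc, "scene_model")
  expect_true(all(c("12", "21", "31", "42") %in% names(sc$teeth)))
  expect_length(sc$teeth, 8)                      # targets plus neighbours
  expect_identical(sc, build_default_scene())
  # occlusal plane normal is horizontal: the plane is perpendicular to the
  # ground plane y = 0
  expect_equal(sc$occlusal_plane_normal[2], 0)
  # frame box encloses every tooth capsule
  for (th in sc$teeth) {
    for (p in list(th$p0, th$p1)) {
      expect_true(all(p - th$radius >= sc$frame_box$min))
      expect_true(all(p + th$radius <= sc$frame_box$max))
    }
  }
  expect_error(build_default_scene(list(arch_width_mm = -1)),
               "configuration")
})

test_that("lesion placement anchors on the chosen tooth", {
  sc <- build_default_scene()
  l21 <- place_lesion(sc, 21)
  expect_equal(l21$center, sc$teeth[["21"]]$anchor)
  expect_equal(l21$diameter_mm, 3)
  l31 <- place_lesion(sc, 31)
  expect_equal(sqrt(sum(l31$normal^2)), 1, tolerance = 1e-12)
  expect_error(place_lesion(sc, 13), "12, 21, 31, 42")
})

test_that("validity criteria flag off-screen, occluded and penetrating mirrors", {
  sc <- build_default_scene()
  cam <- viewer_camera(c(0, 10, 250), c(0, 0, -1), vfov_deg = 12,
                       width_px = 600, height_px = 600)

  # far outside the viewport
  off <- mirror_disc(c(500, 10, 0), c(0, 0, 1), 20)
  expect_false(check_criteria(sc, cam, off, 1)$mirror_fully_visible)

  # centred inside the tongue ellipsoid
  sunk <- mirror_disc(sc$tongue$center, c(0, 0, 1), 20)
  expect_false(check_criteria(sc, cam, sunk, 1)$no_penetration)

  # free-floating mirror in the open inter-arch space: both criteria pass
  free <- mirror_disc(c(0, 5, -4), c(0, 0.1, 0.995), 20)
  camf <- viewer_camera(c(0, 30, 245), c(0, -0.1, -0.995), vfov_deg = 12,
                        width_px = 600, height_px = 600)
  fl <- check_criteria(sc, camf, free, 1)
  expect_true(fl$mirror_fully_visible)
  expect_true(fl$no_penetration)
  expect_true(is.na(fl$tip_in_box))

  # trial 2 needs a tip
  expect_error(check_criteria(sc, camf, free, 2), "tip")
})

test_that("trial-2 tip criteria follow point-in-box and point-in-ellipse", {
  sc <- build_default_scene()
  free <- mirror_disc(c(0, 5, -4), c(0, 0.1, 0.995), 20)
  camf <- viewer_camera(c(0, 30, 245), c(0, -0.1, -0.995), vfov_deg = 12,
                        width_px = 600, height_px = 600)
  les <- lesion_disc(free$center + c(3, 0, 0), free$normal, 3, 21)

  box_ctr <- (unlist(sc$frame_box$min) + unlist(sc$frame_box$max)) / 2
  tip_in <- handpiece_tip(box_ctr)
  fl <- check_criteria(sc, camf, free, 2, tip_in, les)
  expect_true(fl$tip_in_box)

  # independent oracle: project the tip and test the ellipse quadratic form
  mv <- mirror_view(camf, free, les)
  tp <- project_points(tip_in$tip, camf)
  phi <- mv$bc$phi_deg * pi / 180
  dx <- tp[1] - mv$bc$cx_px; dy <- tp[2] - mv$bc$cy_px
  q <- ((dx * cos(phi) + dy * sin(phi)) / mv$bc$a_px)^2 +
       ((-dx * sin(phi) + dy * cos(phi)) / mv$bc$b_px)^2
  expect_identical(fl$tip_clear_of_bc, q > 1)

  tip_out <- handpiece_tip(unlist(sc$frame_box$max) + c(5, 5, 5))
  expect_false(check_criteria(sc, camf, free, 2, tip_out, les)$tip_in_box)
})

test_that("criteria are invariant under a joint rigid transformation", {
  sc <- build_default_scene()
  cam <- viewer_camera(c(0, 30, 245), c(0, -0.1, -0.995), vfov_deg = 12,
                       width_px = 600, height_px = 600)
  mir <- mirror_disc(c(0, 5, -4), c(0, 0.1, 0.995), 20)

  # rigid map: rotate 90 degrees about y, then translate (keeps the frame
  # box axis-aligned so the boxed criteria stay well defined)
  shift <- c(40, -15, 60)
  rot <- function(p) c(p[3], p[2], -p[1])
  tf_pt <- function(p) rot(p) + shift
  tf_dir <- function(d) rot(d)

  sc2 <- sc
  for (nm in names(sc2$teeth)) {
    th <- sc2$teeth[[nm]]
    th$p0 <- tf_pt(th$p0); th$p1 <- tf_pt(th$p1)
    th$anchor <- tf_pt(th$anchor); th$anchor_normal <- tf_dir(th$anchor_normal)
    sc2$teeth[[nm]] <- th
  }
  sc2$tongue$center <- tf_pt(sc2$tongue$center)
  sc2$tongue$axes <- sc2$tongue$axes[c(3, 2, 1)]
  corners <- rbind(tf_pt(unlist(sc$frame_box$min)),
                   tf_pt(unlist(sc$frame_box$max)))
  sc2$frame_box <- list(min = apply(corners, 2, min),
                        max = apply(corners, 2, max))

  cam2 <- viewer_camera(tf_pt(cam$eye), tf_dir(cam$gaze), tf_dir(cam$up),
                        cam$vfov_deg, cam$width_px, cam$height_px)
  mir2 <- mirror_disc(tf_pt(mir$center), tf_dir(mir$normal), 20)

  f1 <- check_criteria(sc, cam, mir, 1)
  f2 <- check_criteria(sc2, cam2, mir2, 1)
  expect_identical(f1$mirror_fully_visible, f2$mirror_fully_visible)
  expect_identical(f1$no_penetration, f2$no_penetration)
})

test_that("sessions cover each target tooth exactly once per trial", {
  for (s in 1:10) {
    ses <- make_session(s)
    expect_equal(nrow(ses), 8)
    expect_equal(sort(ses$tooth[ses$trial == 1]), c(12, 21, 31, 42))
    expect_equal(sort(ses$tooth[ses$trial == 2]), c(12, 21, 31, 42))
  }
})
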