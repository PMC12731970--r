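test_that("planar reflection has the mirror symmetries", {
  pl <- mirror_plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(reflect_point(c(1, 2, 3), pl), c(1, 2, -3))
  expect_equal(reflect_point(c(4, -1, 0), pl), c(4, -1, 0))  # fixed point

  set.seed(11)
  for (i in 1:50) {
    pt <- rnorm(3, sd = 40)
    pln <- mirror_plane(rnorm(3, sd = 20), rnorm(3))
    expect_equal(reflect_point(reflect_point(pt, pln), pln), pt,
                 tolerance = 1e-12)
  }
})

test_that("reflection is an isometry on random triples", {
  set.seed(12)
  for (i in 1:30) {
    pln <- mirror_plane(rnorm(3, sd = 15), rnorm(3))
    pts <- matrix(rnorm(9, sd = 30), 3, 3)
    ref <- reflect_point(pts, pln)
    expect_equal(as.numeric(dist(ref)), as.numeric(dist(pts)),
                 tolerance = 1e-12)
  }
})

test_that("virtual image of a disc mirrors pose and preserves size", {
  pl <- mirror_plane(c(0, 0, 0), c(0, 0, 1))
  on_plane <- lesion_disc(c(2, 1, 0), c(0, 1, 0), 3, 21)
  expect_equal(virtual_image_of_disc(on_plane, pl)$center, c(2, 1, 0))

  behind <- lesion_disc(c(0, 0, -5), c(0, 0, 1), 3, 21)
  img <- virtual_image_of_disc(behind, pl)
  expect_equal(img$center, c(0, 0, 5))
  expect_equal(img$diameter_mm, 3)

  set.seed(13)
  for (i in 1:20) {
    d <- lesion_disc(rnorm(3, sd = 10), rnorm(3), runif(1, 1, 30), 12)
    pln <- mirror_plane(rnorm(3, sd = 5), rnorm(3))
    img <- virtual_image_of_disc(d, pln)
    expect_equal(img$diameter_mm, d$diameter_mm)
    expect_equal(vapply(list(img$normal), function(v) sqrt(sum(v^2)),
                        numeric(1)), 1, tolerance = 1e-9)
  }
})

test_that("face-on disc projects to the closed-form circle f*r/d", {
  cam <- default_test_camera(d = 250, vfov = 60, px = 1000)
  f <- focal_px(cam)
  e <- project_disc(mirror_disc(c(0, 0, 0), c(0, 0, 1), 20), cam)
  expect_equal(e$a_px, f * 10 / 250, tolerance = 1e-3)
  expect_equal(e$b_px, f * 10 / 250, tolerance = 1e-3)
  expect_equal(e$cx_px, 500, tolerance = 1e-6)
  expect_equal(e$cy_px, 500, tolerance = 1e-6)
})

test_that("tilted disc ellipticity approaches cos(tilt) in the orthographic limit", {
  cam <- default_test_camera(d = 600, vfov = 60, px = 1000)  # d/r = 60
  for (tilt in c(10, 25, 40, 60) * pi / 180) {
    d <- mirror_disc(c(0, 0, 0),
                     c(0, sin(tilt), cos(tilt)), 20)
    e <- project_disc(d, cam)
    expect_equal(e$b_px / e$a_px, cos(tilt), tolerance = 0.01)
    # centred on the optical axis regardless of tilt
    expect_equal(e$cx_px, 500, tolerance = 0.2)
  }
})

test_that("projection commutes with camera roll", {
  set.seed(14)
  base_up <- c(0, 1, 0)
  d <- mirror_disc(c(3, -2, 0), c(0.2, 0.3, 0.93), 16)
  e0 <- project_disc(d, viewer_camera(c(0, 0, 300), c(0, 0, -1), base_up))
  for (alpha in c(20, 65, 130)) {
    a <- alpha * pi / 180
    up_r <- c(sin(a), cos(a), 0)   # roll about the optical axis
    e1 <- project_disc(d, viewer_camera(c(0, 0, 300), c(0, 0, -1), up_r))
    expect_equal(e1$a_px, e0$a_px, tolerance = 1e-6)
    expect_equal(e1$b_px, e0$b_px, tolerance = 1e-6)
    dphi <- (e1$phi_deg - e0$phi_deg) %% 180
    # the roll rotates the ellipse orientation by alpha mod 180 (the sense
    # depends on the y-down image convention)
    expect_true(min(abs(dphi - alpha), abs(dphi - alpha + 180),
                    abs(dphi - alpha - 180),
                    abs(dphi + alpha - 180), abs(dphi + alpha)) < 1e-4)
  }
})

test_that("discs behind the camera are rejected", {
  cam <- default_test_camera()
  expect_error(project_disc(mirror_disc(c(0, 0, 500), c(0, 0, 1), 20), cam),
               "behind")
})

test_that("mirror view composes reflection with projection", {
  cam <- default_test_camera(d = 250)
  mir <- mirror_disc(c(0, 0, 0), c(0, 0, 1), 20)

  # coplanar lesion: the mirror is transparent to objects in its own plane
  les <- lesion_disc(c(2, 0, 0), c(0, 0, 1), 3, 21)
  mv <- mirror_view(cam, mir, les)
  direct <- project_disc(les, cam)
  expect_equal(mv$bc$cx_px, direct$cx_px, tolerance = 1e-6)
  expect_equal(mv$bc$a_px, direct$a_px, tolerance = 1e-6)
  expect_false(mv$bc_clipped)

  # general pose: bc equals project . virtual_image composition
  set.seed(15)
  for (i in 1:10) {
    mir2 <- mirror_disc(c(0, 0, 0), vunit_test(c(rnorm(2, 0, 0.15), 1)), 20)
    les2 <- lesion_disc(c(rnorm(2, 0, 3), -runif(1, 0, 6)),
                        rnorm(3), 3, 21)
    mv2 <- mirror_view(cam, mir2, les2)
    comp <- project_disc(
      virtual_image_of_disc(les2, mirror_plane(mir2$center, mir2$normal)),
      cam)
    expect_equal(mv2$bc$cx_px, comp$cx_px, tolerance = 1e-9)
    expect_equal(mv2$bc$b_px, comp$b_px, tolerance = 1e-9)
  }

  # lesion image displaced beyond the mirror radius is reported clipped
  far <- lesion_disc(c(11, 0, 0), c(0, 0, 1), 3, 21)
  expect_true(mirror_view(cam, mir, far)$bc_clipped)

  # mirror facing away is an error
  away <- mirror_disc(c(0, 0, 0), c(0, 0, -1), 20)
  expect_error(mirror_view(cam, away, les), "faces away")
})
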