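# Shared fixtures: cameras, discs and random pose generators used across
# the test files. Everything is generated in code; no binary fixtures.

default_test_camera <- function(d = 250, vfov = 60, px = 1000) {
  viewer_camera(eye = c(0, 0, d), gaze = c(0, 0, -1), up = c(0, 1, 0),
                vfov_deg = vfov, width_px = px, height_px = px)
}

focal_px <- function(cam) (cam$height_px / 2) / tan(cam$vfov_deg * pi / 360)

# A random image-ellipse pair (mirror + contained lesion) that fits well
# inside a `px`-sized canvas with mirror semi-axes >= 40 px and lesion
# semi-axes >= 20 px.
random_ellipse_pair <- function(px = 600) {
  a_dm <- runif(1, 80, 150)
  b_dm <- runif(1, 0.6, 1) * a_dm
  phi_dm <- runif(1, 0, 180)
  cx <- px / 2 + runif(1, -30, 30)
  cy <- px / 2 + runif(1, -30, 30)
  dm <- image_ellipse(cx, cy, a_dm, b_dm, phi_dm)
  a_bc <- runif(1, 20, 0.3 * b_dm)
  b_bc <- runif(1, 0.6, 1) * a_bc
  off <- runif(1, 0, 0.4 * b_dm)
  ang <- runif(1, 0, 2 * pi)
  bc <- image_ellipse(cx + off * cos(ang), cy + off * sin(ang),
                      a_bc, b_bc, runif(1, 0, 180))
  list(dm = dm, bc = bc)
}

# Minimal one-group skill profile for pipeline tests.
test_profile <- function(group = "ID", dist = 1.2, ell = 0.89,
                         ratio = 2.9, time = 8, ...) {
  skill_profile(group, dist, ell, ratio, time, ...)
}

# Exact rank-sum p-value by full enumeration of group assignments
# (two-sided, statistic = sum of ranks in x), for tie-free small samples.
rank_sum_exact_p <- function(x, y) {
  nx <- length(x)
  all <- c(x, y)
  r <- rank(all)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(all), nx)
  stat <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (length(all) + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

vunit_test <- function(v) v / sqrt(sum(v^2))
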