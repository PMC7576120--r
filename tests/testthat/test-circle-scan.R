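make_map <- function(values, extent = 6, center = c(0, 0)) {
  thickness_map(values, extent = extent, center = center, eye_id = "fix")
}

test_that("bilinear resampling preserves constants exactly", {
  m <- make_map(matrix(100, 64, 64))
  pr <- resample_circle(m, c(0, 0), radius = 1.5, n_samples = 720)
  expect_identical(unique(pr$thickness), 100)
  expect_equal(pr$angles[1], 0)
  expect_identical(pr$n_samples, 720L)
})

test_that("bilinear resampling is exact for affine ramps", {
  g <- 64; extent <- 6
  xs <- -extent / 2 + (seq_len(g) - 0.5) * extent / g
  alpha <- 7; beta <- 40
  vals <- matrix(rep(alpha * xs + beta, each = g), nrow = g)  # columns vary in x
  m <- make_map(vals)
  pr <- resample_circle(m, c(0.4, -0.3), radius = 1.2, n_samples = 360)
  expect_equal(mean(pr$thickness), alpha * 0.4 + beta, tolerance = 1e-10)
})

test_that("a circle leaving the raster reports the first offending angle", {
  m <- make_map(matrix(50, 64, 64))
  expect_error(resample_circle(m, c(2, 0), radius = 1.73), "angle")
})

test_that("reposition_center shifts along the per-eye foveo-BMO axis", {
  expect_equal(reposition_center(c(4.215, 0), c(0, 0), 465), c(4.68, 0))
  expect_equal(reposition_center(c(4.215, 0), c(0, 0), 0), c(4.215, 0))
  c2 <- c(4.18, -0.55)
  u <- c2 / sqrt(sum(c2^2))
  expect_equal(reposition_center(c2, c(0, 0), 465), c2 + 0.465 * u)
  expect_error(reposition_center(c(1, 1), c(1, 1), 465), "coincide")
})

test_that("clock-hour binning follows the canonical sector convention", {
  ang <- seq(0, 359.5, by = 0.5)
  # constant profile
  pc <- siodscan:::new_rnfl_profile(c(0, 0), 1.73, ang, rep(100, 720))
  ch <- clock_hour_summary(pc, "right")
  expect_equal(unname(ch$sector_means), rep(100, 12))
  expect_identical(ch$n_per_sector, 60)
  # temporal indicator lights up hour 9 only
  ind <- as.numeric(ang < 15 | ang >= 345)
  pi9 <- siodscan:::new_rnfl_profile(c(0, 0), 1.73, ang, ind)
  ch9 <- clock_hour_summary(pi9, "right")
  expect_equal(unname(ch9$sector_means["9"]), 1)
  expect_equal(sum(ch9$sector_means), 1)
  # cosine profile against the analytic per-sector integral
  pco <- siodscan:::new_rnfl_profile(c(0, 0), 1.73, ang, 2 + cos(pi * ang / 180))
  chc <- clock_hour_summary(pco, "right")
  for (h in 1:12) {
    ctr <- ((h - 9) * 30) %% 360
    oracle <- stats::integrate(function(a) 2 + cos(pi * a / 180),
                               ctr - 15, ctr + 15)$value / 30
    # half-sample offset of the [c-15, c+15) grid bounds the discrete mean
    expect_equal(unname(chc$sector_means[as.character(h)]), oracle,
                 tolerance = 5e-3)
  }
  expect_error(clock_hour_summary(
    siodscan:::new_rnfl_profile(c(0, 0), 1.73, c(0, 90, 180, 271),
                                rep(1, 4))), "divisible")
})

test_that("left-eye extraction mirrors profiles so sector semantics match", {
  r <- generate_scene(noiseless_params(), group = "siod", rng_seed = 8)
  l <- generate_scene(noiseless_params(), group = "siod", rng_seed = 8,
                      laterality = "left")
  mr <- render_thickness_map(r, grid = 200, noise_seed = 1)
  ml <- render_thickness_map(l, grid = 200, noise_seed = 1)
  axr <- foveo_bmo_axis_angle(r$fovea, r$bmo_center)
  cl <- canonical_scene(l)
  axl <- foveo_bmo_axis_angle(cl$fovea, cl$bmo_center)
  expect_equal(axl, axr)
  pr <- resample_circle(mr, r$bmo_center, axis_deg = axr)
  pl <- resample_circle(ml, l$bmo_center, axis_deg = axl)
  expect_equal(pl$thickness, pr$thickness, tolerance = 1e-10)
  expect_equal(clock_hour_summary(pl)$sector_means,
               clock_hour_summary(pr)$sector_means, tolerance = 1e-10)
  expect_identical(clock_hour_summary(pl)$laterality, "left")
})

test_that("peak locations recover the generator hump angles and crowding", {
  s <- generate_scene(noiseless_params(), group = "control", rng_seed = 1)
  ax <- foveo_bmo_axis_angle(s$fovea, s$bmo_center)
  ctrl <- analytic_circle_profile(s, center = s$arch_center, axis_deg = ax)
  pk <- peak_locations(ctrl)
  expect_false(pk$degenerate)
  expect_equal(pk$superior_deg, 75)
  expect_equal(pk$inferior_deg, 285)

  d <- generate_scene(noiseless_params(), group = "siod", rng_seed = 2,
                      displacement = 465)
  axd <- foveo_bmo_axis_angle(d$fovea, d$bmo_center)
  pre <- analytic_circle_profile(d, center = d$bmo_center, axis_deg = axd)
  pk_pre <- peak_locations(pre)
  expect_gt(pk_pre$superior_deg, 75)
  expect_lt(pk_pre$inferior_deg, 285)
  post <- analytic_circle_profile(
    d, center = reposition_center(d$bmo_center, d$fovea, 465), axis_deg = axd)
  pk_post <- peak_locations(post)
  expect_lt(abs(pk_post$superior_deg - 75), 2)
  expect_lt(abs(pk_post$inferior_deg - 285), 2)

  flat <- siodscan:::new_rnfl_profile(c(0, 0), 1.73,
                                      seq(0, 359.5, 0.5), rep(80, 720))
  expect_true(peak_locations(flat)$degenerate)
})

test_that("nasally shifting a control eye crowds its peaks temporally", {
  s <- generate_scene(noiseless_params(), group = "control", rng_seed = 3)
  ax <- foveo_bmo_axis_angle(s$fovea, s$bmo_center)
  pre <- analytic_circle_profile(s, center = s$bmo_center, axis_deg = ax)
  shifted <- analytic_circle_profile(
    s, center = reposition_center(s$bmo_center, s$fovea, 465), axis_deg = ax)
  pk0 <- peak_locations(pre); pk1 <- peak_locations(shifted)
  expect_lt(pk1$superior_deg, pk0$superior_deg)   # toward temporal (0)
  expect_gt(pk1$inferior_deg, pk0$inferior_deg)   # toward temporal (360)
})

test_that("repositioning by zero reproduces the clock-hour summary exactly", {
  s <- generate_scene(group = "siod", rng_seed = 4)
  m <- render_thickness_map(s, grid = 100, noise_seed = 5)
  ax <- foveo_bmo_axis_angle(s$fovea, s$bmo_center)
  a <- resample_circle(m, s$bmo_center, axis_deg = ax)
  b <- resample_circle(m, reposition_center(s$bmo_center, s$fovea, 0),
                       axis_deg = ax)
  expect_identical(clock_hour_summary(a)$sector_means,
                   clock_hour_summary(b)$sector_means)
})

test_that("bilinear sampling agrees with a supersampled nearest-neighbor oracle", {
  s <- generate_scene(noiseless_params(), group = "control", rng_seed = 6)
  m <- render_thickness_map(s, grid = 200, noise_seed = 1)
  hi <- render_thickness_map(s, grid = 200 * 8, noise_seed = 1)
  ax <- foveo_bmo_axis_angle(s$fovea, s$bmo_center)
  pr <- resample_circle(m, s$bmo_center, n_samples = 90, axis_deg = ax)
  # nearest-neighbor lookup on the supersampled raster
  idx <- siodscan:::map_index(hi, s$bmo_center[1] + 1.73 *
                                siodscan:::tsnit_dirs(pr$angles + ax, FALSE)$x,
                              s$bmo_center[2] + 1.73 *
                                siodscan:::tsnit_dirs(pr$angles + ax, FALSE)$y)
  nn <- hi$values[cbind(round(idx$row), round(idx$col))]
  expect_lt(max(abs(pr$thickness - nn)), 1.5)
})
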