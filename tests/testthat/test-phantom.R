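test_that("hu_to_density maps the calibration points and clamps below air", {
  expect_equal(hu_to_density(0), 1.000)
  expect_equal(hu_to_density(-1000), 0.00121)
  expect_equal(hu_to_density(-1001), hu_to_density(-1000))
  expect_equal(hu_to_density(-740), 0.26)
  # monotone non-decreasing over a dense HU grid
  hu <- seq(-1000, 3000, by = 1)
  expect_true(all(diff(hu_to_density(hu)) >= 0))
  # array shape preserved
  a <- array(c(-1000, 0, 40, 1300), c(2, 2, 1))
  expect_equal(dim(hu_to_density(a)), dim(a))
  expect_error(hu_to_density(NA_real_), "finite")
})

test_that("make_phantom rasterizes organs with consistent CT and density", {
  sp <- phantom_spec(c(24, 24, 12),
                     organs = list(organ_spec(1, "blob", "ellipsoid",
                                              c(12.5, 12.5, 6.5),
                                              c(7, 7, 4),
                                              material = "soft",
                                              activity = 1000)),
                     background = "air")
  ph <- make_phantom(sp)
  inside <- unclass(ph$labels) == 1
  expect_true(any(inside))
  expect_true(all(unclass(ph$activity)[inside] == 1000))
  expect_true(all(unclass(ph$activity)[!inside] == 0))
  expect_true(all(unclass(ph$density)[inside] == 1.0))
  expect_true(all(unclass(ph$ct)[!inside] == -1000))
  # lung cuboid density from the material table
  sp2 <- phantom_spec(c(16, 16, 8),
                      organs = list(organ_spec(1, "lung", "cuboid",
                                               c(8.5, 8.5, 4.5), c(4, 4, 2),
                                               material = "lung",
                                               activity = 10)))
  ph2 <- make_phantom(sp2)
  expect_equal(unique(unclass(ph2$density)[unclass(ph2$labels) == 1]),
               0.26)
})

test_that("phantom generation is deterministic and overlap goes to the last organ", {
  sp <- demo_phantom_spec("torso", c(24, 24, 12), seed = 4)
  a <- make_phantom(sp); b <- make_phantom(sp)
  expect_identical(unclass(a$activity), unclass(b$activity))
  expect_identical(unclass(a$ct), unclass(b$ct))
  # overlapping organs: later organ wins
  sp2 <- phantom_spec(c(12, 12, 6), organs = list(
    organ_spec(1, "big", "cuboid", c(6.5, 6.5, 3.5), c(4, 4, 2),
               material = "soft", activity = 5),
    organ_spec(2, "small", "cuboid", c(6.5, 6.5, 3.5), c(2, 2, 1),
               material = "bone", activity = 9)))
  ph2 <- make_phantom(sp2)
  expect_equal(unclass(ph2$activity)[6, 6, 3], 9)
  expect_equal(unclass(ph2$labels)[6, 6, 3], 2)
})

test_that("voxelized mass matches the analytic ellipsoid mass within 2%", {
  # ellipsoid >= 20 voxels across in every direction
  sp <- phantom_spec(c(48, 48, 30),
                     organs = list(organ_spec(1, "blob", "ellipsoid",
                                              c(24.5, 24.5, 15.5),
                                              c(14, 14, 11),
                                              material = "soft",
                                              activity = 1)),
                     background = "air")
  ph <- make_phantom(sp)
  vox_ml <- voxel_volume_ml(ph$density)
  mass <- sum(unclass(ph$density)[unclass(ph$labels) == 1]) * vox_ml
  vs <- attr(ph$density, "voxel_size") / 10   # cm
  analytic <- 4 / 3 * pi * (14 * vs[1]) * (14 * vs[2]) * (11 * vs[3]) * 1.0
  expect_lt(abs(mass - analytic) / analytic, 0.02)
})

test_that("dynamic series applies per-organ clearance and background physical decay", {
  sp <- phantom_spec(c(12, 12, 6), organs = list(
    organ_spec(1, "fast", "cuboid", c(4.5, 6.5, 3.5), c(2, 2, 1),
               material = "soft", activity = 100, half_time_min = 62),
    organ_spec(2, "frozen", "cuboid", c(9.5, 6.5, 3.5), c(1, 1, 1),
               material = "soft", activity = 50, half_time_min = Inf)),
    background = "soft", background_activity = 10)
  ph <- make_phantom(sp)
  ds <- make_dynamic_series(ph, c(1, 4, 7, 10, 15, 30, 46, 62))
  expect_length(ds$frames, 8)
  expect_equal(ds$time_points_min, c(1, 4, 7, 10, 15, 30, 46, 62))
  lab <- unclass(ph$labels)
  # organ decays by 2^(-t/T): exact frame ratios between consecutive frames
  for (i in 2:8) {
    dt <- ds$time_points_min[i] - ds$time_points_min[i - 1]
    r <- unclass(ds$frames[[i]])[lab == 1][1] /
      unclass(ds$frames[[i - 1]])[lab == 1][1]
    expect_equal(r, 2^(-dt / 62))
  }
  # half-time organ halves at t = 62 relative to t = 0 concentration
  ds0 <- make_dynamic_series(ph, c(62))
  expect_equal(unclass(ds0$frames[[1]])[lab == 1][1], 50)
  # infinite half-time organ never decays
  expect_true(all(unclass(ds$frames[[8]])[lab == 2] == 50))
  # background follows the physical half-life
  expect_equal(unclass(ds$frames[[8]])[lab == 0][1],
               10 * 2^(-62 / GA68_HALF_LIFE_MIN))
  expect_error(make_dynamic_series(ph, c(5, 5)), "increasing")
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(c(8, 8, 4), organs = list(
    organ_spec(1, "big", "ellipsoid", c(4, 4, 2), c(10, 2, 1),
               material = "soft"))), "outside the grid")
  expect_error(organ_spec(1, "x", "ellipsoid", c(1, 1, 1), c(1, 1, 1),
                          material = "soft", half_time_min = 0),
               "positive")
  expect_error(organ_spec(1, "x", "ellipsoid", c(1, 1, 1), c(1, 1, 1),
                          material = "jelly"))
  # zero-volume organ
  expect_error(make_phantom(phantom_spec(c(12, 12, 6), organs = list(
    organ_spec(1, "tiny", "ellipsoid", c(6.25, 6.25, 3.25),
               c(0.1, 0.1, 0.1), material = "soft")))),
    "zero voxels")
})
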