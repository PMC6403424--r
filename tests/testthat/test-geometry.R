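helix_radial_extent <- function(h) {
  pts <- h$centerline
  2 * max(sqrt(pts[, 1]^2 + pts[, 2]^2))
}

test_that("helix external diameter equals the toroid's for any length", {
  g <- toroid_geometry(chirality = 1)
  for (n in c(1, 10, 100)) {
    h <- build_helix(g, n)
    expect_equal(helix_radial_extent(h) + g$tube_diameter, 12,
                 tolerance = 1e-9)
    expect_equal(h$external_diameter, 12)
    expect_equal(h$axial_length, n * g$pitch)
  }
})

test_that("contour length scales with the number of one-turn units", {
  g <- toroid_geometry(chirality = 1)
  one <- build_helix(g, 1, points_per_turn = 256)
  ten <- build_helix(g, 10, points_per_turn = 256)
  expect_equal(ten$contour_length, 10 * one$contour_length,
               tolerance = 1e-4)
  # arc length of the parametric helix: n * sqrt((2 pi R)^2 + pitch^2)
  Rc <- (g$external_diameter - g$tube_diameter) / 2
  expect_equal(one$contour_length, sqrt((2 * pi * Rc)^2 + g$pitch^2),
               tolerance = 1e-3)
})

test_that("handedness follows chirality and flips under reflection", {
  hS <- build_helix(toroid_geometry(chirality = 1), 5)
  hR <- build_helix(toroid_geometry(chirality = -1), 5)
  expect_equal(handedness_of(hS), 1L)
  expect_equal(handedness_of(hR), -1L)
  # R-built helix is the point-wise mirror image of the S-built one
  expect_equal(reflect_helix(hS)$centerline, hR$centerline)
  expect_equal(handedness_of(reflect_helix(hS)), -1L)
  expect_error(handedness_of(hS$centerline[1:3, ]), "points")
})

test_that("racemic toroids refuse to build helices", {
  expect_error(build_helix(toroid_geometry(chirality = 0), 5),
               "unable to polymerize")
  expect_error(toroid_geometry(chirality = 2), "chirality")
  expect_error(toroid_geometry(external_diameter = 2, tube_diameter = 3),
               "external_diameter")
})

test_that("spherocylinder solution matches the closed form", {
  # conserved area pi d^2 with rod 1000 nm: 2000 pi r = 4 pi 250^2
  v <- vesicle_shape(1000, sphere_diameter = 500)
  expect_equal(v$cap_radius, 125)
  expect_equal(v$aspect_ratio, 4)
  expect_equal(v$area, 4 * pi * 250^2, tolerance = 1e-9)
  expect_equal(v$total_length, 1000)

  # short rods leave the sphere untouched
  v0 <- vesicle_shape(0)
  expect_equal(v0$aspect_ratio, 1)
  expect_equal(v0$cap_radius, 250)
  vb <- vesicle_shape(500)  # boundary case: rod = diameter
  expect_equal(vb$aspect_ratio, 1)
  expect_error(vesicle_shape(-1), "rod_length")
})

test_that("aspect ratio grows continuously and monotonically with rod length", {
  rods <- seq(500, 5000, by = 100)
  asp <- vapply(rods, function(L) vesicle_shape(L)$aspect_ratio, numeric(1))
  expect_true(all(diff(asp) > 0))
  # continuity at the spherical boundary
  expect_equal(vesicle_shape(500 + 1e-6)$aspect_ratio, 1, tolerance = 1e-4)
  # area is conserved along the whole family
  areas <- vapply(rods, function(L) vesicle_shape(L)$area, numeric(1))
  expect_true(all(abs(areas - 4 * pi * 250^2) < 1e-6))
})

test_that("fixed-volume mode conserves volume and both modes report infeasibility", {
  vv <- vesicle_shape(1500, constraint = "fixed_volume")
  expect_equal(vv$volume, 4 / 3 * pi * 250^3, tolerance = 1e-6)
  expect_equal(vv$total_length, 1500)
  err <- tryCatch(vesicle_shape(1e6), error = conditionMessage)
  expect_match(err, "maximum supportable rod length")
})

test_that("recovery restores the area-equivalent sphere", {
  v <- vesicle_shape(1000)
  r <- vesicle_recovery(v)
  expect_equal(r$aspect_ratio, 1)
  expect_equal(r$cap_radius, 250, tolerance = 1e-9)
  expect_equal(r$area, v$area)  # deform-recover cycle conserves area
  s <- vesicle_shape(0)
  expect_equal(vesicle_recovery(s)$cap_radius, s$cap_radius)
})

test_that("helix centerlines export losslessly to CSV and XYZ", {
  h <- build_helix(toroid_geometry(chirality = 1), 2, points_per_turn = 8)
  csv <- tempfile(fileext = ".csv")
  write_helix(h, csv, "csv")
  back <- as.matrix(utils::read.csv(csv))
  expect_equal(unname(back), unname(h$centerline), tolerance = 1e-6)
  xyz <- tempfile(fileext = ".xyz")
  write_helix(h, xyz, "xyz")
  lines <- readLines(xyz)
  expect_equal(as.integer(lines[1]), nrow(h$centerline))
  expect_length(lines, nrow(h$centerline) + 2)
})
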