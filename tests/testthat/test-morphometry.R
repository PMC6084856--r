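test_that("the palatal plane is built from ANS, PNS and a lateral point", {
  lms <- landmarks(list(ANS = c(0, 40, 0), PNS = c(0, -10, 0),
                        lateral = c(30, 0, 0)))
  pl <- palatal_plane(lms)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$origin, c(0, 40, 0))
  bad <- landmarks(list(ANS = c(0, 0, 0), PNS = c(0, 10, 0),
                        lateral = c(0, 20, 0)))
  expect_error(palatal_plane(bad), "collinear|degenerate")
})

test_that("section metrics follow the shoelace formula and axis extents", {
  # 1 mm unit square
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m <- section_metrics(sq)
  expect_equal(m$A_cm2, 0.01)
  expect_equal(m$AP_cm, 0.1)
  expect_equal(m$Lat_cm, 0.1)
  # 20 x 10 mm rectangle (x by y)
  r <- rbind(c(0, 0), c(20, 0), c(20, 10), c(0, 10))
  m2 <- section_metrics(r)
  expect_equal(m2$Lat_cm, 2)
  expect_equal(m2$AP_cm, 1)
  expect_equal(m2$A_cm2, 2)
  # rotating the rectangle 90 degrees in plane swaps AP and Lat
  rot <- r %*% t(matrix(c(0, -1, 1, 0), 2, 2, byrow = TRUE))
  m3 <- section_metrics(rot)
  expect_equal(m3$Lat_cm, m2$AP_cm)
  expect_equal(m3$AP_cm, m2$Lat_cm)
  expect_equal(m3$A_cm2, m2$A_cm2)
  # shoelace equals the cross-product oracle on a convex polygon
  set.seed(4)
  th <- sort(runif(12, 0, 2 * pi))
  poly <- cbind(7 * cos(th), 4 * sin(th))
  cross_area <- 0
  for (i in seq_len(nrow(poly))) {
    j <- i %% nrow(poly) + 1
    cross_area <- cross_area +
      (poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]) / 2
  }
  expect_equal(section_metrics(poly)$A_cm2, abs(cross_area) / 100,
               tolerance = 1e-12)
  expect_error(section_metrics(poly[1:2, , drop = FALSE]), "degenerate")
})

test_that("cylinder slices match the analytic area at every station", {
  cyl <- make_fixture("cylinder", radius = 10, length = 50, n_theta = 128)
  plane <- list(origin = c(0, 0, 0), normal = c(0, 0, 1))
  prof <- slice_airway(cyl, plane, spacing = 1)
  expect_true(all(abs(prof$sections$area_cm2 - pi) / pi < 0.02))
  expect_true(all(abs(prof$sections$ap_cm - 2) < 0.02))
  expect_true(all(abs(prof$sections$lat_cm - 2) < 0.02))
  expect_equal(diff(prof$sections$station),
               rep(1, nrow(prof$sections) - 1))
})

test_that("the hourglass waist area matches the analytic constriction", {
  hg <- make_fixture("hourglass", radius = 10, waist_radius = 5,
                     length = 50, waist_extent = 10, n_theta = 128,
                     dz = 0.25)
  plane <- list(origin = c(0, 0, 0), normal = c(0, 0, 1))
  prof <- slice_airway(hg, plane, spacing = 1)
  expect_equal(min(prof$sections$area_cm2), pi * 25 / 100,
               tolerance = 0.02)
  # degenerate case: waist radius equal to the tube radius = plain cylinder
  none <- make_fixture("hourglass", radius = 10, waist_radius = 10,
                       length = 50, n_theta = 64)
  p2 <- slice_airway(none, plane, spacing = 1)
  expect_lt(diff(range(p2$sections$area_cm2)) / pi, 0.01)
})

test_that("tilted and elliptical cylinders give the analytic slice areas", {
  # elliptical cylinder, semiaxes 10 and 6: area pi*a*b
  ell <- make_fixture("cylinder", radius = 10, length = 40, n_theta = 128)
  ell$vertices[, 2] <- 0.6 * ell$vertices[, 2]
  plane <- list(origin = c(0, 0, 0), normal = c(0, 0, 1))
  p1 <- slice_airway(ell, plane, spacing = 1)
  expect_equal(median(p1$sections$area_cm2), pi * 10 * 6 / 100,
               tolerance = 0.02)
  # circular cylinder tilted 20 degrees: slice area pi r^2 / cos(20)
  th <- 20 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  tilt <- make_fixture("cylinder", radius = 10, length = 60, n_theta = 128)
  tilt$vertices <- tilt$vertices %*% t(Rx)
  p2 <- slice_airway(tilt, plane, spacing = 1)
  mid <- p2$sections[abs(p2$sections$station -
                           median(p2$sections$station)) < 10, ]
  expect_equal(median(mid$area_cm2), pi / cos(th), tolerance = 0.02)
})

test_that("slice-area error shrinks under angular refinement", {
  plane <- list(origin = c(0, 0, 0), normal = c(0, 0, 1))
  dev_at <- function(n_theta) {
    cyl <- make_fixture("cylinder", radius = 10, length = 20,
                        n_theta = n_theta)
    prof <- slice_airway(cyl, plane, spacing = 1)
    max(abs(prof$sections$area_cm2 - pi)) / pi
  }
  expect_lt(dev_at(48), dev_at(24) / 2)
})

test_that("open surfaces are rejected for slicing", {
  pl <- make_fixture("parallel_plates", gap = 1)$A
  expect_error(slice_airway(pl, list(origin = c(0, 0, 0),
                                     normal = c(0, 0, 1))),
               "watertight")
})

test_that("region partition follows landmarks or explicit bounds", {
  hg <- make_fixture("hourglass", radius = 10, waist_radius = 4,
                     length = 60, waist_z = 40, waist_extent = 8,
                     n_theta = 64)
  lms <- landmarks(list(ANS = c(0, 30, 60), PNS = c(0, -30, 60),
                        lateral = c(30, 0, 60),
                        soft_palate_tip = c(0, 0, 25),
                        epiglottis_tip = c(0, 0, 10)))
  plane <- palatal_plane(lms)
  prof <- partition_regions(slice_airway(hg, plane), lms)
  secs <- prof$sections
  # VPX between the palatal plane (station 0) and the soft-palate tip (-35)
  expect_true(all(secs$region[secs$station > -35 & secs$station < 0] ==
                    "VPX"))
  expect_true(all(secs$region[secs$station < -50] == "LPX"))
  # constriction at z=40 (station -20) lies in VPX: narrowest VPX = waist
  expect_equal(narrowest_section(prof, "VPX")$station, -20)
  expect_equal(narrowest_section(prof, "VPX")$area_cm2, pi * 16 / 100,
               tolerance = 0.02)
  # explicit numeric bounds override landmarks exactly
  prof2 <- partition_regions(prof, vpx_bounds = c(-10, 0),
                             lpx_bounds = c(-60, -50))
  expect_true(all(prof2$sections$region[prof2$sections$station >= -10] ==
                    "VPX"))
  # bounds covering everything as VPX leave LPX empty, flagged
  expect_warning(partition_regions(prof, vpx_bounds = c(-60, 0),
                                   lpx_bounds = c(-100, -90)),
                 "LPX region is empty")
})

test_that("narrowest-section ties resolve to the inferior-most station", {
  prof <- structure(list(
    sections = data.frame(station = c(-3, -2, -1),
                          area_cm2 = c(2, 1.5, 1.5),
                          ap_cm = 1, lat_cm = 1, region = "VPX"),
    spacing = 1), class = "airway_profile")
  expect_equal(narrowest_section(prof, "VPX")$station, -2)
  expect_error(narrowest_section(prof, "LPX"), "empty region")
})

test_that("AP and Lat are covariant under in-plane rotation of the scene", {
  ell <- make_fixture("cylinder", radius = 10, length = 30, n_theta = 96)
  ell$vertices[, 2] <- 0.5 * ell$vertices[, 2] # Lat 2.0 cm, AP 1.0 cm
  plane <- list(origin = c(0, 0, 0), normal = c(0, 0, 1))
  p1 <- slice_airway(ell, plane, spacing = 5)
  rot <- ell
  rot$vertices <- rot$vertices %*% t(rotation_z(90))
  p2 <- slice_airway(rot, plane, spacing = 5)
  expect_equal(p2$sections$area_cm2, p1$sections$area_cm2,
               tolerance = 1e-9)
  expect_equal(p2$sections$ap_cm, p1$sections$lat_cm, tolerance = 1e-9)
  expect_equal(p2$sections$lat_cm, p1$sections$ap_cm, tolerance = 1e-9)
})
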