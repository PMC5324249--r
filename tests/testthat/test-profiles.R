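test_that("plane sampling follows the tangent at the stated spacing", {
  z <- seq(0, 100, by = 0.5)
  straight <- centerline(cbind(0, 0, z))
  pl <- sample_planes(straight, 2)
  expect_equal(nrow(pl), 51L)
  expect_true(all(abs(pl$nx) < 1e-12 & abs(pl$ny) < 1e-12 &
                    abs(pl$nz - 1) < 1e-12))
  expect_error(sample_planes(straight, 200), "exceeds")
  expect_error(sample_planes(straight, 0), "positive")

  fx <- fix_arch()
  pla <- sample_planes(fx$cl, 2)
  # plane normals are the local tangents: unit and tangent-aligned
  rs <- vesselgauge:::resample_polyline(fx$cl$points, 2)
  tg <- vesselgauge:::polyline_tangents(rs$points)
  dots <- rowSums(cbind(pla$nx, pla$ny, pla$nz) * tg[seq_len(nrow(pla)), ])
  expect_true(all(abs(dots - 1) < 1e-9))
})

test_that("section contours recover the analytic cross-section", {
  fx <- fix_cylinder()
  sec <- section_contour(fx$mesh, c(0, 0, 50), c(0, 0, 1))
  expect_false(sec$excluded)
  r <- sqrt(rowSums(sec$contour^2))
  expect_true(all(abs(r - 12.5) < 0.2))

  # horizontal plane through both arch limbs: two closed loops, the one
  # enclosing the centerline point is returned
  ar <- fix_arch()
  p <- c(0, 0, 20)
  sec2 <- section_contour(ar$mesh, p, c(0, 0, 1), center_point = p)
  expect_false(sec2$excluded)
  ctr <- colMeans(sec2$contour3d)
  # ascending limb section (x near 5), not the descending limb at x ~ 75
  expect_lt(ctr[1], 20)
  expect_true(vesselgauge:::point_in_polygon(c(0, 0), sec2$contour))
})

test_that("contour metrics match closed forms and a brute-force oracle", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(12.5 * cos(th), 12.5 * sin(th))
  m <- contour_metrics(circ)
  expect_equal(m$max_diameter, 25, tolerance = 1e-4)
  expect_equal(m$area, pi * 12.5^2, tolerance = 1e-4)

  ell <- cbind(15 * cos(th), 10 * sin(th))
  me <- contour_metrics(ell)
  expect_equal(me$max_diameter, 30, tolerance = 1e-4)
  expect_equal(me$area, pi * 15 * 10, tolerance = 1e-4)

  set.seed(7)
  for (rep in 1:5) {
    ang <- sort(stats::runif(25, 0, 2 * pi))
    rad <- stats::runif(1, 5, 20)
    poly <- cbind(rad * cos(ang), rad * sin(ang))
    mm <- contour_metrics(poly)
    expect_equal(mm$max_diameter, max(dist(poly)), tolerance = 1e-12)
    # fan triangulation area oracle
    area_fan <- sum(vapply(2:(nrow(poly) - 1), function(i) {
      v1 <- poly[i, ] - poly[1, ]
      v2 <- poly[i + 1, ] - poly[1, ]
      (v1[1] * v2[2] - v1[2] * v2[1]) / 2
    }, numeric(1)))
    expect_equal(mm$area, abs(area_fan), tolerance = 1e-12)
  }

  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(contour_metrics(bowtie), "self-intersecting")
})

test_that("cylinder profile is flat at the analytic diameter and area", {
  fx <- fix_cylinder()
  interior <- fx$profile$s_mm >= 4 & fx$profile$s_mm <= 96 &
    !fx$profile$excluded
  d <- fx$profile$max_diameter_mm[interior]
  a <- fx$profile$area_mm2[interior]
  expect_true(all(abs(d - 25) / 25 < 0.005))
  expect_true(all(abs(a - pi * 12.5^2) / (pi * 12.5^2) < 0.01))
})

test_that("coarctation profile finds the constriction depth and place", {
  fx <- fix_coarct()
  ok <- !fx$profile$excluded & fx$profile$s_mm > 10 & fx$profile$s_mm < 290
  prof <- fx$profile[ok, ]
  i <- which.min(prof$max_diameter_mm)
  expect_lt(abs(prof$max_diameter_mm[i] - 12) / 12, 0.03)
  expect_lte(abs(prof$s_mm[i] - 150), 2)
})

test_that("branch stubs are excluded automatically, elsewhere kept", {
  fx <- fix_stubs()
  prof <- fx$profile
  for (s0 in c(85, 100, 115)) {
    win <- prof$s_mm > s0 - 5 & prof$s_mm < s0 + 5
    expect_gte(sum(prof$excluded[win]), 1L)
  }
  outside <- prof$s_mm < 75 | prof$s_mm > 125
  expect_false(any(prof$excluded[outside] & prof$s_mm[outside] > 2 &
                     prof$s_mm[outside] < max(prof$s_mm) - 2))
  # a plane through an ostium is excluded as an open contour
  expect_true(any(prof$reason[prof$excluded] == "open contour"))
})

test_that("manual branch windows flag stations", {
  fx <- fix_cylinder()
  prof <- measure_profile(fx$mesh, fx$cl,
                          branch_windows = list(c(30, 40)))
  inw <- prof$s_mm >= 30 & prof$s_mm <= 40
  expect_true(all(prof$excluded[inw]))
  expect_true(all(prof$reason[inw] == "branch window"))
})

test_that("landmark stations map to nearest non-excluded stations", {
  fx <- fix_cylinder()
  st <- c(stj = 5, aa_mid = 15, aa_dist = 25, prox_arch = 40,
          dist_arch = 55, isthmus = 65, da_mid = 80, da_caudal = 95)
  mapped <- map_stations(fx$profile, st)
  expect_equal(nrow(mapped), 8L)
  expect_true(all(abs(mapped$max_diameter_mm - 25) / 25 < 0.01))
  # nearest rule: landmark between stations takes the nearer one
  m2 <- map_stations(fx$profile, c(x = 10.9))
  expect_equal(m2$s_station_mm, 10)
  # landmark inside an excluded span falls back with a warning
  prof <- measure_profile(fx$mesh, fx$cl, branch_windows = list(c(30, 40)))
  expect_warning(m3 <- map_stations(prof, c(branch = 34)), "excluded")
  expect_false(prof$excluded[match(m3$s_station_mm, prof$s_mm)])
  expect_error(map_stations(fx$profile, c(bad = 1e4)), "outside")
})

test_that("profile alignment shifts and resamples correctly", {
  fx <- fix_cylinder()
  a <- fx$profile
  expect_equal(align_profiles(a, a, 50, 50)$max_diameter_mm,
               a$max_diameter_mm, tolerance = 1e-9)
  # construct b = a shifted by +6 mm
  b <- a
  b$s_mm <- a$s_mm + 6
  al <- align_profiles(a, b, 56, 50)
  ok <- !is.na(al$max_diameter_mm) & !is.na(a$max_diameter_mm)
  expect_true(all(abs(al$max_diameter_mm[ok] - a$max_diameter_mm[ok]) <
                    0.1))
  expect_error(align_profiles(a, b, 500, 0), "overlap")
})

test_that("visit-to-visit change classification honours the threshold", {
  fx <- fix_cylinder()
  a <- fx$profile
  expect_true(all(classify_change(a, a)$class %in%
                    c("stable", "excluded")))
  b <- a
  b$max_diameter_mm <- a$max_diameter_mm + 2
  cls <- classify_change(a, b, threshold = 1.5)
  expect_true(all(cls$class[!a$excluded] == "growth"))
  cls2 <- classify_change(a, b, threshold = 2.5)
  expect_true(all(cls2$class[!a$excluded] == "stable"))
})

test_that("a dilation patch is classified as growth only inside the patch", {
  fx <- fixture("dilation_pair", function() {
    mk <- function(amp) {
      ph <- make_phantom(phantom_preset(
        "dilation", dilation_patch = list(center = 100, amplitude = amp,
                                          width = 10)), capped = FALSE)
      cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(0, 0, 200))
      measure_profile(ph$mesh, cl)
    }
    list(a = mk(0), b = mk(1.5))
  })
  al <- align_profiles(fx$a, fx$b, 0, 0)
  cls <- classify_change(fx$a, al, threshold = 1.5)
  grown <- cls$s_mm[cls$class == "growth"]
  # diameter change 3 exp(-(s-100)^2/200) exceeds 1.5 for |s-100| < 11.8
  expect_true(all(abs(grown - 100) <= 14))
  expect_true(all(cls$class[abs(cls$s_mm - 100) <= 8] == "growth"))
})

test_that("profiles are invariant under rigid motion of the mesh", {
  fx <- fix_cylinder()
  R <- rotation_z(25)
  tr <- rigid_transform(R, c(8, -4, 11))
  mesh2 <- apply_transform(fx$mesh, tr)
  cl2 <- centerline(apply_transform(fx$cl$points, tr))
  prof2 <- measure_profile(mesh2, cl2)
  ok <- !fx$profile$excluded & !prof2$excluded
  expect_true(all(abs(prof2$max_diameter_mm[ok] -
                        fx$profile$max_diameter_mm[ok]) < 0.1))
})

test_that("diameter and area trends agree on a monotone phantom", {
  fx <- fixture("cone_phantom", function() {
    sp <- phantom_spec(Inf, 100, 0,
                       tube_radius = function(s) 8 + 0.05 * s)
    ph <- make_phantom(sp, capped = FALSE)
    cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(0, 0, 100))
    measure_profile(ph$mesh, cl)
  })
  ok <- !fx$excluded
  expect_gt(cor(fx$max_diameter_mm[ok], fx$area_mm2[ok],
                method = "spearman"), 0.9)
})
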