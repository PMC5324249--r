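test_that("cylinder distance field is the tube radius everywhere", {
  fx <- fix_cylinder()
  axis <- centerline(cbind(0, 0, seq(0, 100, by = 0.5)))
  fld <- euclidean_field(fx$mesh, axis)
  mid <- fld$s_mm > 5 & fld$s_mm < 95
  expect_true(all(abs(fld$distance_mm[mid] - 12.5) < 0.2))
  expect_true(all(fld$distance_mm > 0))
  expect_error(euclidean_field(fx$mesh, list()), "empty")
})

test_that("the field equals a brute-force nearest-point scan", {
  sp <- phantom_spec(Inf, 30, 0, 8,
                     mesh_resolution = c(axial = 16, circumferential = 24))
  ph <- make_phantom(sp, capped = FALSE)
  axis <- centerline(cbind(0, 0, seq(0, 30, by = 0.5)))
  fld <- euclidean_field(ph$mesh, axis)
  expect_lte(nrow(ph$mesh$vertices), 5000L)
  brute <- apply(ph$mesh$vertices, 1, function(v)
    sqrt(min(colSums((t(axis$points) - v)^2))))
  expect_equal(fld$distance_mm, brute, tolerance = 1e-12)
})

test_that("elliptical sections show the analytic circumferential range", {
  fx <- fix_ellipse()
  mid <- fx$field$s_mm > 10 & fx$field$s_mm < 90
  d <- fx$field$distance_mm[mid]
  expect_lt(abs(min(d) - 10), 0.3)
  expect_lt(abs(max(d) - 15), 0.3)
})

test_that("a dilation patch raises the local field maximum by its amplitude", {
  sp <- phantom_spec(Inf, 120, 0, 10,
                     dilation_patch = list(center = 60, amplitude = 2,
                                           width = 10, angle_center = 0,
                                           angle_width = pi / 2))
  ph <- make_phantom(sp, capped = FALSE)
  axis <- centerline(cbind(0, 0, seq(0, 120, by = 0.5)))
  fld <- euclidean_field(ph$mesh, axis)
  patch <- abs(fld$s_mm - 60) < 5
  expect_lt(abs(max(fld$distance_mm[patch]) - 12), 0.3)
  away <- fld$s_mm > 5 & fld$s_mm < 115 & abs(fld$s_mm - 60) > 40
  expect_lt(max(fld$distance_mm[away]), 10.3)
})

test_that("branch vertices bind to the branch path of a branched centerline", {
  fx <- fix_stubs()
  main <- fx$cl
  # straight branch polylines along the stub axes (outer arch wall)
  branches <- lapply(c(85, 100, 115), function(s0) {
    g <- vesselgauge:::phantom_geometry(
      phantom_spec(40, 40, 40, 10))
    dirn <- -as.vector(g$frame_u(s0))
    base <- as.vector(g$pos(s0))
    centerline(t(vapply(seq(0, 24, by = 0.5), function(t) base + t * dirn,
                        numeric(3))))
  })
  fld <- euclidean_field(fx$mesh, c(list(main), branches))
  # vertices outside the main tube are stub wall: they bind to a branch
  # path and sit about one stub radius (3 mm) from it
  d_main <- RANN::nn2(main$points, fx$mesh$vertices, k = 1)$nn.dists
  stub_verts <- as.vector(d_main) > 10.8
  expect_gt(sum(stub_verts), 100)
  expect_true(all(is.na(fld$s_mm[stub_verts])))
  expect_lt(median(abs(fld$distance_mm[stub_verts] - 3)), 0.5)
})

test_that("regional summaries split by arc-length cut points", {
  sp <- phantom_spec(Inf, 100, 0,
                     tube_radius = function(s)
                       ifelse(s < 45, 13, ifelse(s > 55, 10,
                                                 13 - 3 * (s - 45) / 10)))
  ph <- make_phantom(sp, capped = FALSE)
  axis <- centerline(cbind(0, 0, seq(0, 100, by = 0.5)))
  fld <- euclidean_field(ph$mesh, axis)
  fld2 <- fld[fld$s_mm > 3 & fld$s_mm < 97, ]
  class(fld2) <- class(fld)
  rs <- summarize_regions(fld2, c(45, 55))
  expect_equal(rs$region, c("ascending", "arch", "descending"))
  expect_lt(abs(rs$mean_mm[1] - 13), 0.3)
  expect_lt(abs(rs$mean_mm[3] - 10), 0.3)
  expect_true(all(rs$max_mm >= rs$mean_mm, na.rm = TRUE))
  expect_equal(sum(rs$n_vertices), nrow(fld2))
  # degenerate cuts: everything in one region
  rs2 <- summarize_regions(fld2, c(1e5, 1e6))
  expect_equal(rs2$n_vertices[2:3], c(0L, 0L))
  expect_error(summarize_regions(fld2, c(60, 40)), "increasing")
})

test_that("asymmetry index separates circular from elliptical tubes", {
  fx <- fix_cylinder()
  axis <- centerline(cbind(0, 0, seq(0, 100, by = 0.5)))
  circ <- asymmetry_index(euclidean_field(fx$mesh, axis))
  mid <- circ$s_mm > 5 & circ$s_mm < 95
  expect_lt(max(circ$asymmetry[mid]), 0.02)

  ell <- fix_ellipse()
  ai <- asymmetry_index(ell$field)
  mide <- ai$s_mm > 10 & ai$s_mm < 90
  expect_true(all(abs(ai$asymmetry[mide] - 0.4) / 0.4 < 0.1))
})

test_that("the field is isometry-invariant and scales linearly", {
  sp <- phantom_spec(Inf, 40, 0, 9,
                     mesh_resolution = c(axial = 21, circumferential = 32))
  ph <- make_phantom(sp, capped = FALSE)
  axis <- centerline(cbind(0, 0, seq(0, 40, by = 0.5)))
  f0 <- euclidean_field(ph$mesh, axis)

  tr <- rigid_transform(rotation_z(40), c(3, 4, -5))
  f1 <- euclidean_field(apply_transform(ph$mesh, tr),
                        centerline(apply_transform(axis$points, tr)))
  expect_equal(f1$distance_mm, f0$distance_mm, tolerance = 1e-9)

  scaled <- ph$mesh
  scaled$vertices <- 2 * scaled$vertices
  f2 <- euclidean_field(scaled, centerline(2 * axis$points))
  expect_equal(f2$distance_mm, 2 * f0$distance_mm, tolerance = 1e-9)

  a1 <- asymmetry_index(f0)
  a2 <- asymmetry_index(f1)
  expect_equal(a2$asymmetry, a1$asymmetry, tolerance = 1e-9)
})

test_that("PLY export writes a readable scalar mesh", {
  fx <- fix_cylinder()
  axis <- centerline(cbind(0, 0, seq(0, 100, by = 0.5)))
  fld <- euclidean_field(fx$mesh, axis)
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply_scalar(fx$mesh, fld$distance_mm, f)
  head <- readLines(f, n = 10)
  expect_equal(head[1], "ply")
  expect_true(any(grepl("property float euclid_mm", head)))
  expect_equal(length(readLines(f)),
               10 + nrow(fx$mesh$vertices) + nrow(fx$mesh$faces))
})
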