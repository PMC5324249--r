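test_that("landmark alignment recovers a constructed rigid transform", {
  set.seed(5)
  src <- matrix(stats::runif(30, -20, 20), 10, 3)
  expect_equal(landmark_align(src, src)$rotation, diag(3),
               tolerance = 1e-12)

  R <- rotation_z(15)
  t <- c(5, -3, 2)
  tgt <- src %*% t(R) + matrix(t, 10, 3, byrow = TRUE)
  tr <- landmark_align(src, tgt)
  ang_err <- acos(pmin(1, (sum(diag(t(tr$rotation) %*% R)) - 1) / 2))
  expect_lt(ang_err, 1e-6)
  expect_equal(tr$translation, t, tolerance = 1e-9)

  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(landmark_align(coll, coll + 1), "collinear")
  expect_error(landmark_align(src[1:2, ], tgt[1:2, ]), "at least 3")
})

test_that("noisy landmark fit is at least as good as a grid search", {
  set.seed(8)
  src <- matrix(stats::runif(36, -25, 25), 12, 3)
  R <- rotation_z(12)
  t <- c(4, 7, -2)
  tgt <- src %*% t(R) + matrix(t, 12, 3, byrow = TRUE) +
    matrix(stats::rnorm(36, 0, 0.5), 12, 3)
  tr <- landmark_align(src, tgt)
  rms <- function(trans) {
    moved <- apply_transform(src, trans)
    sqrt(mean(rowSums((moved - tgt)^2)))
  }
  # grid-search oracle over z-rotations with the optimal translation each
  grid_rms <- vapply(seq(-20, 20, by = 0.05), function(deg) {
    Rg <- rotation_z(deg)
    tg <- colMeans(tgt) - as.vector(Rg %*% colMeans(src))
    rms(rigid_transform(Rg, tg))
  }, numeric(1))
  expect_lte(rms(tr), min(grid_rms) + 1e-3)
})

test_that("ICP refines a landmark initialization to sub-0.05 mm RMS", {
  mesh <- fixture("icp_mesh", function()
    make_phantom(phantom_spec(Inf, 100, 0, 12.5,
                              section_eccentricity = 1.2))$mesh)
  expect_identical_tr <- function(tr) {
    expect_lt(attr(tr, "rms"), 1e-9)
  }
  # identical clouds, identity init
  tr0 <- icp(mesh$vertices, mesh)
  expect_identical_tr(tr0)

  R <- rotation_z(10)
  true_tr <- rigid_transform(R, c(10, 4, -6))
  moved <- apply_transform(mesh, true_tr)
  idx <- c(11, 901, 2801, 5501)
  init <- landmark_align(moved$vertices[idx, ] +
                           matrix(stats::rnorm(12, 0, 1), 4, 3),
                         mesh$vertices[idx, ])
  tr <- icp(moved$vertices, mesh, init = init)
  expect_lt(attr(tr, "rms"), 0.05)
  # recovered transform inverts the constructed one (within the shallow
  # rotational conditioning of a mildly elliptical tube)
  Rrec <- tr$rotation %*% true_tr$rotation
  ang <- acos(pmin(1, (sum(diag(Rrec)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
  # the RMS trace never rises across accepted iterations
  expect_true(all(diff(attr(tr, "rms_trace")) < 1e-9))
})

test_that("seeded subsampling reproduces the full-cloud ICP transform", {
  mesh <- fixture("icp_mesh", function() stop("unused"))
  true_tr <- rigid_transform(rotation_z(5), c(3, -2, 4))
  moved <- apply_transform(mesh, true_tr)
  idx <- c(11, 901, 2801, 5501)
  init <- landmark_align(moved$vertices[idx, ], mesh$vertices[idx, ])
  full <- icp(moved$vertices, mesh, init = init)
  half <- icp(moved$vertices, mesh, init = init, subsample = 0.5, seed = 3)
  half2 <- icp(moved$vertices, mesh, init = init, subsample = 0.5, seed = 3)
  expect_equal(half$rotation, half2$rotation, tolerance = 1e-12)
  ang <- acos(pmin(1, (sum(diag(t(half$rotation) %*% full$rotation)) - 1) /
                     2)) * 180 / pi
  expect_lt(ang, 0.1)
  expect_lt(sqrt(sum((half$translation - full$translation)^2)), 0.1)
})

test_that("change maps are zero for identity, signed for offsets", {
  mesh <- fixture("icp_mesh", function() stop("unused"))
  cm0 <- change_map(mesh, mesh)
  expect_lt(max(abs(cm0$change_mm)), 1e-9)

  vn <- vertex_normals(mesh)
  grown <- mesh
  grown$vertices <- mesh$vertices + 1 * vn
  cm1 <- change_map(mesh, grown)
  expect_equal(median(cm1$change_mm), 1, tolerance = 0.1)
  cm2 <- change_map(grown, mesh)
  expect_equal(median(cm1$change_mm), -median(cm2$change_mm),
               tolerance = 0.2)
})

test_that("a localized constriction shows as negative change inside the patch only", {
  base <- make_phantom(phantom_spec(Inf, 200, 0, 12), capped = FALSE)$mesh
  worse <- make_phantom(phantom_spec(Inf, 200, 0, 12,
                                     coarctation = list(center = 100,
                                                        depth = 2 / 12,
                                                        width = 10)),
                        capped = FALSE)$mesh
  cm <- change_map(base, worse)
  z <- attr(cm, "mesh")$vertices[, 3]
  inside <- abs(z - 100) < 4
  outside <- abs(z - 100) > 50 & z > 5 & z < 195
  expect_lt(median(cm$change_mm[inside]), -1.6)
  expect_lt(abs(median(cm$change_mm[outside])), 0.2)
})

test_that("point-to-triangle distances match brute force exactly", {
  sp <- phantom_spec(Inf, 25, 0, 7,
                     mesh_resolution = c(axial = 14, circumferential = 24))
  mesh <- make_phantom(sp)$mesh
  expect_lte(nrow(mesh$faces), 2000L)
  set.seed(9)
  pts <- cbind(stats::runif(40, -10, 10), stats::runif(40, -10, 10),
               stats::runif(40, -5, 30))
  hit <- vesselgauge:::.cpp_closest_on_surface(pts, mesh$vertices,
                                               mesh$faces)
  v <- mesh$vertices
  f <- mesh$faces
  tri_dist <- tri_dist_exact
  for (q in c(1, 7, 19, 33)) {
    brute <- min(vapply(seq_len(nrow(f)), function(t)
      tri_dist(pts[q, ], v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ]),
      numeric(1)))
    expect_equal(hit$distance[q], brute, tolerance = 1e-6)
  }
})

test_that("transforms compose and serialize", {
  t1 <- rigid_transform(rotation_z(30), c(1, 2, 3))
  t2 <- rigid_transform(rotation_z(-10), c(-4, 0, 2))
  p <- matrix(stats::runif(15), 5, 3)
  expect_equal(apply_transform(apply_transform(p, t1), t2),
               apply_transform(p, compose_transforms(t2, t1)),
               tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(t1, f)
  t1b <- read_transform_json(f)
  expect_equal(t1b$rotation, t1$rotation, tolerance = 1e-12)
  expect_equal(t1b$translation, t1$translation, tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "orthonormal")
})
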