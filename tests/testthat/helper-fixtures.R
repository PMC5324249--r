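# Shared phantom fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fix_cylinder <- function() fixture("cylinder", function() {
  ph <- make_phantom(phantom_preset("cylinder"), capped = FALSE)
  cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(0, 0, 100))
  list(mesh = ph$mesh, truth = ph$truth, cl = cl,
       profile = measure_profile(ph$mesh, cl))
})

fix_arch <- function() fixture("arch", function() {
  ph <- make_phantom(phantom_preset("arch"), capped = FALSE)
  cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(80, 0, 0))
  list(mesh = ph$mesh, truth = ph$truth, cl = cl,
       geom = centerline_geometry(cl, c(0, 0, 1)))
})

fix_coarct <- function() fixture("coarct", function() {
  ph <- make_phantom(phantom_preset("coarctation"), capped = FALSE)
  cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(0, 0, 300))
  list(mesh = ph$mesh, truth = ph$truth, cl = cl,
       profile = measure_profile(ph$mesh, cl))
})

# small closed cube mesh (unit edge, mm)
cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge),
                             z = c(0, edge)))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  surface_mesh(v, f)
}

# lat-long sphere mesh
uv_sphere <- function(r = 10, n_lat = 24L, n_lon = 48L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2L)
  lat <- lat[-c(1, length(lat))]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  grid <- expand.grid(lon = lon, lat = lat)
  v <- r * cbind(cos(grid$lat) * cos(grid$lon),
                 cos(grid$lat) * sin(grid$lon),
                 sin(grid$lat))
  id <- function(i, j) (i - 1L) * n_lon + j  # i = lat ring, j = lon
  f <- list()
  for (i in seq_len(n_lat - 1L)) {
    j <- seq_len(n_lon)
    jn <- c(2:n_lon, 1L)
    f[[i]] <- rbind(cbind(id(i, j), id(i, jn), id(i + 1L, jn)),
                    cbind(id(i, j), id(i + 1L, jn), id(i + 1L, j)))
  }
  np <- n_lat * n_lon
  v <- rbind(v, c(0, 0, -r), c(0, 0, r))
  south <- np + 1L
  north <- np + 2L
  j <- seq_len(n_lon)
  jn <- c(2:n_lon, 1L)
  f[[length(f) + 1L]] <- cbind(id(1L, jn), id(1L, j), south)
  f[[length(f) + 1L]] <- cbind(id(n_lat, j), id(n_lat, jn), north)
  surface_mesh(v, do.call(rbind, f))
}

# voxelized solid sphere mask
sphere_mask <- function(r = 20, spacing = 1) {
  half <- ceiling(r / spacing) + 2L
  cc <- (-half:half) * spacing
  g <- expand.grid(x = cc, y = cc, z = cc)
  n <- length(cc)
  list(mask = array(sqrt(g$x^2 + g$y^2 + g$z^2) <= r, dim = c(n, n, n)),
       spacing = rep(spacing, 3), origin = rep(cc[1], 3))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# vertex normals by area-weighted face-normal averaging
vertex_normals <- function(mesh) {
  fn <- vesselgauge:::face_normals(mesh, normalize = FALSE)
  idx <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  vn <- rowsum(rbind(fn, fn, fn), idx)
  vn / pmax(sqrt(rowSums(vn^2)), 1e-12)
}

sort_rows <- function(m) m[do.call(order, as.data.frame(m)), ]

# icosphere: subdivided icosahedron, near-uniform vertex distribution
icosphere <- function(r = 10, subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (k in seq_len(subdiv)) {
    nf <- nrow(f)
    newf <- vector("list", nf)
    mid_env <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_env[[key]]
      if (!is.null(hit)) return(hit)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_env[[key]] <- nrow(v)
      nrow(v)
    }
    for (t in seq_len(nf)) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[[t]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                         c(ab, bc, ca))
    }
    f <- do.call(rbind, newf)
  }
  v <- v * r / sqrt(rowSums(v^2))
  surface_mesh(v, f)
}

fix_stubs <- function() fixture("stub_phantom", function() {
  sp <- phantom_spec(arch_radius = 40, ascending_length = 40,
                     descending_length = 40, tube_radius = 10,
                     branch_stubs = list(list(s = 85, radius = 3,
                                              length = 12),
                                         list(s = 100, radius = 3,
                                              length = 12),
                                         list(s = 115, radius = 3,
                                              length = 12)))
  ph <- make_phantom(sp, capped = FALSE)
  cl <- compute_centerline(ph$mesh, c(0, 0, 0), c(80, 0, 0))
  list(spec = sp, mesh = ph$mesh, cl = cl,
       profile = measure_profile(ph$mesh, cl))
})

fix_ellipse <- function() fixture("ellipse_tube", function() {
  sp <- phantom_spec(Inf, 100, 0, 10, section_eccentricity = 1.5)
  ph <- make_phantom(sp, capped = FALSE)
  axis <- centerline(cbind(0, 0, seq(0, 100, by = 0.5)))
  list(mesh = ph$mesh, field = euclidean_field(ph$mesh, axis))
})

# exact closest-distance from a point to a triangle, written independently
# of the compiled kernel (plane projection + exact edge distances)
seg_dist_exact <- function(p, a, b) {
  ab <- b - a
  t0 <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
  sqrt(sum((a + t0 * ab - p)^2))
}
tri_dist_exact <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a
  n <- pracma::cross(ab, ac)
  n <- n / sqrt(sum(n^2))
  best <- min(seg_dist_exact(p, a, b), seg_dist_exact(p, b, c3),
              seg_dist_exact(p, c3, a))
  proj <- p - sum((p - a) * n) * n
  w <- tryCatch(solve(cbind(ab, ac, n), proj - a),
                error = function(e) c(-1, -1, 0))
  if (w[1] >= 0 && w[2] >= 0 && w[1] + w[2] <= 1)
    best <- min(best, sqrt(sum((proj - p)^2)))
  best
}
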