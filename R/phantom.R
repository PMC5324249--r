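#' Specify a parametric aorta-like phantom
#'
#' A "candy-cane" tube: straight ascending segment, semicircular arch,
#' straight descending segment, with elliptical cross-sections and optional
#' localized narrowing (coarctation), localized dilation and short branch
#' stubs on the arch outer wall.  Every geometric quantity the measurement
#' pipeline estimates is available in closed form from the same formulas,
#' which makes the phantom the package's analytic ground truth.
#'
#' Arc length `s` runs from 0 at the ascending inlet.  The centerline is
#' the segment (0,0,0) to (0,0,La), the semicircle of radius `arch_radius`
#' in the x-z plane, then the segment descending from (2R,0,La).
#'
#' @param arch_radius arch (centerline) radius in mm; `Inf` degenerates to
#'   a straight tube.
#' @param ascending_length,descending_length straight segment lengths (mm).
#' @param tube_radius base cross-section radius in mm, or a function of
#'   arc length returning mm.
#' @param section_eccentricity major/minor axis ratio (>= 1); the major
#'   axis lies in the arch plane.
#' @param coarctation optional `list(center=, depth=, width=)`: Gaussian
#'   narrowing at arc length `center` (mm), fractional `depth` in (0,1),
#'   standard-deviation `width` (mm), scaling the whole section.
#' @param dilation_patch optional `list(center=, amplitude=, width=,
#'   angle_center=, angle_width=)`: Gaussian outward bulge of `amplitude`
#'   mm; when `angle_center` is NULL the bulge is circumferentially
#'   uniform, otherwise a raised-cosine angular window of half-width
#'   `angle_width` (radians) centred on `angle_center`.
#' @param branch_stubs optional list of `list(s=, radius=, length=)` stubs
#'   planted on the arch outer wall (used to exercise branch exclusion).
#' @param mesh_resolution `c(axial=, circumferential=)` vertex counts;
#'   axial defaults to about one ring per mm.
#' @param seed integer seed used by [voxelize()] noise.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(arch_radius = 40,
                         ascending_length = 60,
                         descending_length = 80,
                         tube_radius = 12.5,
                         section_eccentricity = 1,
                         coarctation = NULL,
                         dilation_patch = NULL,
                         branch_stubs = NULL,
                         mesh_resolution = c(axial = NA, circumferential = 64),
                         seed = 1L) {
  if (!is.infinite(arch_radius) && arch_radius <= 0)
    stop("arch_radius must be positive (or Inf for a straight tube)")
  if (ascending_length < 0 || descending_length < 0)
    stop("segment lengths must be >= 0")
  if (section_eccentricity < 1) stop("section_eccentricity must be >= 1")
  if (!is.null(coarctation)) {
    stopifnot(coarctation$depth > 0, coarctation$depth < 1,
              coarctation$width > 0)
  }
  nc <- mesh_resolution[["circumferential"]]
  if (!is.na(nc) && nc < 16) stop("circumferential resolution must be >= 16")
  structure(list(arch_radius = arch_radius,
                 ascending_length = ascending_length,
                 descending_length = descending_length,
                 tube_radius = tube_radius,
                 section_eccentricity = section_eccentricity,
                 coarctation = coarctation,
                 dilation_patch = dilation_patch,
                 branch_stubs = branch_stubs,
                 mesh_resolution = mesh_resolution,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# piecewise-analytic centerline, frames and radius functions for a spec
phantom_geometry <- function(spec) {
  R <- spec$arch_radius
  La <- spec$ascending_length
  Ld <- spec$descending_length
  straight <- is.infinite(R)
  arc_len <- if (straight) 0 else pi * R
  L <- La + arc_len + Ld
  if (L <= 0) stop("phantom has zero length")

  pos <- function(s) {
    s <- pmin(pmax(s, 0), L)
    if (straight) return(cbind(0, 0, s))
    out <- matrix(0, length(s), 3)
    seg1 <- s <= La
    seg2 <- s > La & s <= La + arc_len
    seg3 <- s > La + arc_len
    out[seg1, ] <- cbind(0, 0, s[seg1])
    th <- (s[seg2] - La) / R
    out[seg2, ] <- cbind(R - R * cos(th), 0, La + R * sin(th))
    out[seg3, ] <- cbind(2 * R, 0, La - (s[seg3] - La - arc_len))
    out
  }
  tanv <- function(s) {
    s <- pmin(pmax(s, 0), L)
    if (straight) return(cbind(0, 0, rep(1, length(s))))
    out <- matrix(0, length(s), 3)
    seg1 <- s <= La
    seg2 <- s > La & s <= La + arc_len
    seg3 <- s > La + arc_len
    if (any(seg1))
      out[seg1, ] <- matrix(c(0, 0, 1), sum(seg1), 3, byrow = TRUE)
    th <- (s[seg2] - La) / R
    out[seg2, ] <- cbind(sin(th), 0, cos(th))
    if (any(seg3))
      out[seg3, ] <- matrix(c(0, 0, -1), sum(seg3), 3, byrow = TRUE)
    out
  }
  # parallel-transport frame of the planar curve: v = +y constant,
  # u = v x t (in plane); u x v = t so (u, v, t) is right-handed
  frame_u <- function(s) {
    t <- tanv(s)
    cbind(t[, 3], 0, -t[, 1])
  }
  frame_v <- function(s) cbind(0, rep(1, length(s)), 0)

  r0 <- if (is.function(spec$tube_radius)) spec$tube_radius else
    function(s) rep(spec$tube_radius, length(s))
  coarct_scale <- function(s) {
    if (is.null(spec$coarctation)) return(rep(1, length(s)))
    co <- spec$coarctation
    1 - co$depth * exp(-(s - co$center)^2 / (2 * co$width^2))
  }
  axis_a <- function(s) spec$section_eccentricity * r0(s) * coarct_scale(s)
  axis_b <- function(s) r0(s) * coarct_scale(s)
  dil_axial <- function(s) {
    if (is.null(spec$dilation_patch)) return(rep(0, length(s)))
    dp <- spec$dilation_patch
    dp$amplitude * exp(-(s - dp$center)^2 / (2 * dp$width^2))
  }
  dil_angular <- function(phi) {
    dp <- spec$dilation_patch
    if (is.null(dp) || is.null(dp$angle_center)) return(rep(1, length(phi)))
    d <- atan2(sin(phi - dp$angle_center), cos(phi - dp$angle_center))
    w <- abs(d) < dp$angle_width
    ifelse(w, cos(pi * d / (2 * dp$angle_width))^2, 0)
  }
  # polar radius of the section at (s, phi); vectorized over equal lengths
  rho <- function(s, phi) {
    a <- axis_a(s)
    b <- axis_b(s)
    base <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    base + dil_axial(s) * dil_angular(phi)
  }
  list(L = L, La = La, arc_len = arc_len, straight = straight, R = R,
       pos = pos, tanv = tanv, frame_u = frame_u, frame_v = frame_v,
       rho = rho, axis_a = axis_a, axis_b = axis_b, dil_axial = dil_axial,
       dil_angular = dil_angular)
}

#' Generate a phantom surface mesh and its analytic ground truth
#'
#' @param spec a [phantom_spec()].
#' @param capped close the tube with flat end caps (watertight; default
#'   TRUE).  Clip the caps off with [clip_mesh()] to obtain inlet/outlet
#'   rims.
#' @return a list with elements `mesh` (a closed `surface_mesh`) and
#'   `truth` (a `phantom_truth`: sampled centerline with arc length,
#'   vectorized `max_radius(s)`, `max_diameter(s)`, `area(s)` functions,
#'   `tortuosity`, `apex_curvature`, `apex_s`, `length`).
#' @export
make_phantom <- function(spec, capped = TRUE) {
  g <- phantom_geometry(spec)
  nc <- spec$mesh_resolution[["circumferential"]]
  if (is.na(nc)) nc <- 64L
  na <- spec$mesh_resolution[["axial"]]
  if (is.na(na)) na <- max(8L, ceiling(g$L) + 1L)
  s_grid <- seq(0, g$L, length.out = na)
  phi <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]

  if (!g$straight) {
    rho_max <- max(vapply(s_grid, function(s)
      max(g$rho(rep(s, length(phi)), phi)), numeric(1)))
    if (rho_max >= g$R)
      stop("self-intersecting spec: tube radius ", signif(rho_max, 4),
           " mm >= arch radius ", g$R, " mm")
  }

  verts <- matrix(0, na * nc, 3)
  for (i in seq_len(na)) {
    s <- s_grid[i]
    c0 <- g$pos(s)
    u <- g$frame_u(s)
    v <- g$frame_v(s)
    r <- g$rho(rep(s, nc), phi)
    ring <- matrix(c0, nc, 3, byrow = TRUE) +
      r * cos(phi) %o% as.vector(u) + r * sin(phi) %o% as.vector(v)
    verts[(i - 1L) * nc + seq_len(nc), ] <- ring
  }
  # quad strip faces
  f <- vector("list", na - 1L)
  jj <- seq_len(nc)
  jn <- c(2:nc, 1L)
  for (i in seq_len(na - 1L)) {
    a <- (i - 1L) * nc + jj
    b <- (i - 1L) * nc + jn
    c2 <- i * nc + jj
    d2 <- i * nc + jn
    f[[i]] <- rbind(cbind(a, b, d2), cbind(a, d2, c2))
  }
  faces <- do.call(rbind, f)
  if (capped) {
    cs <- rbind(g$pos(0), g$pos(g$L))
    verts <- rbind(verts, cs)
    i0 <- nrow(verts) - 1L
    i1 <- nrow(verts)
    cap0 <- cbind(jj, jn, i0)
    top <- (na - 1L) * nc
    cap1 <- cbind(top + jn, top + jj, i1)
    faces <- rbind(faces, cap0, cap1)
  }
  mesh <- surface_mesh(verts, faces)
  mesh <- add_branch_stubs(mesh, spec, g)
  list(mesh = mesh, truth = phantom_truth(spec, g))
}

# plant short open cylinders on the arch outer wall and open matching
# ostium holes in the main wall; the junction is left as touching open
# rims (sufficient for branch-exclusion and branched-centerline tests)
add_branch_stubs <- function(mesh, spec, g) {
  if (is.null(spec$branch_stubs)) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  for (st in spec$branch_stubs) {
    c0 <- as.vector(g$pos(st$s))
    u <- as.vector(g$frame_u(st$s))
    tg <- as.vector(g$tanv(st$s))
    dirn <- -u  # outer wall of the arch
    base <- c0 + as.vector(g$rho(st$s, pi)) * dirn
    # drop main-wall faces whose centroid lies inside the stub cylinder
    cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
    rel <- cent - matrix(base, nrow(cent), 3, byrow = TRUE)
    ax <- as.vector(rel %*% dirn)
    rad <- sqrt(rowSums((rel - ax %o% dirn)^2))
    drop <- rad < st$radius & abs(ax) < st$length
    f <- f[!drop, , drop = FALSE]
    # stub tube from just inside the lumen outward
    e1 <- tg
    e2 <- pracma::cross(dirn, e1)
    nphi <- 24L
    phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-(nphi + 1L)]
    tt <- seq(-min(2, st$length / 2), st$length, length.out = 8L)
    ring0 <- nrow(v)
    sv <- matrix(0, length(tt) * nphi, 3)
    for (i in seq_along(tt)) {
      ctr <- base + tt[i] * dirn
      sv[(i - 1L) * nphi + seq_len(nphi), ] <-
        matrix(ctr, nphi, 3, byrow = TRUE) +
        st$radius * cos(phi) %o% e1 + st$radius * sin(phi) %o% e2
    }
    v <- rbind(v, sv)
    jj <- seq_len(nphi)
    jn <- c(2:nphi, 1L)
    sf <- vector("list", length(tt) - 1L)
    for (i in seq_len(length(tt) - 1L)) {
      a <- ring0 + (i - 1L) * nphi + jj
      b <- ring0 + (i - 1L) * nphi + jn
      c2 <- ring0 + i * nphi + jj
      d2 <- ring0 + i * nphi + jn
      sf[[i]] <- rbind(cbind(a, b, d2), cbind(a, d2, c2))
    }
    f <- rbind(f, do.call(rbind, sf))
  }
  surface_mesh(v, f)
}

phantom_truth <- function(spec, g = phantom_geometry(spec)) {
  s_fine <- seq(0, g$L, by = 0.5)
  if (s_fine[length(s_fine)] < g$L) s_fine <- c(s_fine, g$L)
  pts <- g$pos(s_fine)
  p0 <- g$pos(0)
  p1 <- g$pos(g$L)
  chord <- sqrt(sum((p1 - p0)^2))
  phi_grid <- seq(0, 2 * pi, length.out = 721L)[-721L]
  max_radius <- function(s) vapply(s, function(si)
    max(g$rho(rep(si, length(phi_grid)), phi_grid)), numeric(1))
  max_diameter <- function(s) vapply(s, function(si) {
    r <- g$rho(rep(si, length(phi_grid)), phi_grid)
    x <- r * cos(phi_grid)
    y <- r * sin(phi_grid)
    hull <- grDevices::chull(x, y)
    max(dist(cbind(x[hull], y[hull])))
  }, numeric(1))
  area <- function(s) vapply(s, function(si) {
    r <- g$rho(rep(si, length(phi_grid)), phi_grid)
    sum(r^2) * (2 * pi / length(phi_grid)) / 2
  }, numeric(1))
  structure(list(
    centerline = tibble::tibble(s_mm = s_fine, x = pts[, 1], y = pts[, 2],
                                z = pts[, 3]),
    centerline_fun = g$pos,
    max_radius = max_radius,
    max_diameter = max_diameter,
    area = area,
    tortuosity = g$L / chord,
    apex_curvature = if (g$straight) 0 else 1 / g$R,
    apex_s = if (g$straight) NA_real_ else g$La + g$arc_len / 2,
    length = g$L,
    spec = spec), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("phantom_truth: length %.1f mm, tortuosity %.4f, ",
                     "apex curvature %s /mm\n"),
              x$length, x$tortuosity, signif(x$apex_curvature, 4)))
  invisible(x)
}

#' Built-in phantom presets
#'
#' `"cylinder"`: straight tube r = 12.5 mm, L = 100 mm.
#' `"arch"`: semicircular arch only, R = 40 mm, r = 10 mm.
#' `"coarctation"`: r = 12 mm tube with a depth-0.5 Gaussian narrowing.
#' `"dilation"`: cylinder with a +2 mm circumferentially uniform bulge.
#' `"eta"`: elongated transverse arch with elliptical sections.
#' @param name preset name.
#' @param ... overrides passed to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
phantom_preset <- function(name = c("cylinder", "arch", "coarctation",
                                    "dilation", "eta"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    cylinder = list(arch_radius = Inf, ascending_length = 100,
                    descending_length = 0, tube_radius = 12.5),
    arch = list(arch_radius = 40, ascending_length = 0,
                descending_length = 0, tube_radius = 10),
    coarctation = list(arch_radius = Inf, ascending_length = 300,
                       descending_length = 0, tube_radius = 12,
                       coarctation = list(center = 150, depth = 0.5,
                                          width = 12)),
    dilation = list(arch_radius = Inf, ascending_length = 200,
                    descending_length = 0, tube_radius = 12.5,
                    dilation_patch = list(center = 100, amplitude = 2,
                                          width = 10)),
    eta = list(arch_radius = 35, ascending_length = 50,
               descending_length = 70, tube_radius = 11,
               section_eccentricity = 1.3))
  over <- list(...)
  do.call(phantom_spec, utils::modifyList(base, over))
}

#' Voxelize a phantom spec or a closed surface mesh
#'
#' Produces a grey-value image: `lumen_gv` inside the surface,
#' `background_gv` outside, plus optional seeded Gaussian noise.  A
#' `phantom_spec` is voxelized from its analytic inside test; a
#' `surface_mesh` (closed) by ray-crossing parity.
#'
#' @param x a `phantom_spec` or closed `surface_mesh`.
#' @param spacing voxel edge length (mm), isotropic or length-3.
#' @param lumen_gv,background_gv grey values (defaults 475 / 100, inside
#'   and outside the default 310-640 threshold window).
#' @param noise_sd Gaussian noise SD in grey values (0 = none).
#' @param seed seed for the noise; for a `phantom_spec` defaults to the
#'   spec's own seed.
#' @param margin empty border added around the object, mm.
#' @return a `voxel_image`.
#' @export
voxelize <- function(x, spacing = 1, lumen_gv = 475, background_gv = 100,
                     noise_sd = 0, seed = NULL, margin = 3) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (inherits(x, "phantom_spec")) {
    g <- phantom_geometry(x)
    if (min(spacing) > max(g$axis_b(seq(0, g$L, length.out = 64))))
      warning("voxel spacing is coarser than the tube radius")
    s_ref <- seq(0, g$L, length.out = 512)
    pts <- g$pos(s_ref)
    rmax <- max(g$axis_a(s_ref)) + max(g$dil_axial(s_ref)) +
      max(vapply(x$branch_stubs %||% list(),
                 function(st) st$length + st$radius, numeric(1)), 0)
    lo <- apply(pts, 2, min) - rmax - margin
    hi <- apply(pts, 2, max) + rmax + margin
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    centers <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 1) *
                        spacing[d])
    gp <- as.matrix(expand.grid(x = centers[[1]], y = centers[[2]],
                                z = centers[[3]]))
    inside <- phantom_inside(gp, x, g)
    vals <- array(ifelse(inside, lumen_gv, background_gv), dim = dims)
    seed <- seed %||% x$seed
    origin <- lo
  } else if (inherits(x, "surface_mesh")) {
    if (length(x$boundary_loops) > 0L)
      stop("parity voxelization requires a closed mesh")
    lo <- apply(x$vertices, 2, min) - margin
    hi <- apply(x$vertices, 2, max) + margin
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    inside <- .cpp_voxelize_parity(x$vertices, x$faces - 1L, dims, spacing,
                                   lo)
    vals <- array(ifelse(inside, lumen_gv, background_gv), dim = dims)
    seed <- seed %||% 1L
    origin <- lo
  } else stop("x must be a phantom_spec or surface_mesh")
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd),
                         dim = dim(vals))
  }
  voxel_image(vals, spacing = spacing, origin = origin)
}

# analytic inside test for phantom voxelization
phantom_inside <- function(points, spec, g = phantom_geometry(spec)) {
  n <- nrow(points)
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  cand_s <- matrix(NA_real_, n, 3)
  cand_d <- matrix(Inf, n, 3)
  # ascending segment (or whole straight tube)
  La <- if (g$straight) g$L else g$La
  s1 <- pmin(pmax(pz, 0), La)
  cand_s[, 1] <- s1
  cand_d[, 1] <- sqrt(px^2 + py^2 + (pz - s1)^2)
  if (!g$straight) {
    gx <- px - g$R
    gz <- pz - g$La
    psi <- atan2(gz, gx)
    th <- pmin(pmax(pi - psi, 0), pi)
    s2 <- g$La + g$R * th
    q <- g$pos(s2)
    cand_s[, 2] <- s2
    cand_d[, 2] <- sqrt((px - q[, 1])^2 + py^2 + (pz - q[, 3])^2)
    if (spec$descending_length > 0) {
      t3 <- pmin(pmax(g$La - pz, 0), spec$descending_length)
      s3 <- g$La + g$arc_len + t3
      cand_s[, 3] <- s3
      cand_d[, 3] <- sqrt((px - 2 * g$R)^2 + py^2 + (pz - (g$La - t3))^2)
    }
  }
  pick <- max.col(-cand_d, ties.method = "first")
  s_star <- cand_s[cbind(seq_len(n), pick)]
  c0 <- g$pos(s_star)
  u <- g$frame_u(s_star)
  v <- g$frame_v(s_star)
  tg <- g$tanv(s_star)
  off <- points - c0
  ou <- rowSums(off * u)
  ov <- rowSums(off * v)
  ot <- rowSums(off * tg)
  phi <- atan2(ov, ou)
  inside <- sqrt(ou^2 + ov^2) <= g$rho(s_star, phi) & abs(ot) < 1e-9 &
    s_star > 0 & s_star < g$L
  # allow voxels exactly at the flat ends inward of the caps
  inside[s_star <= 0 | s_star >= g$L] <- FALSE
  # branch stubs
  for (st in spec$branch_stubs %||% list()) {
    base <- as.vector(g$pos(st$s)) +
      as.vector(g$rho(st$s, pi)) * (-as.vector(g$frame_u(st$s)))
    dirn <- -as.vector(g$frame_u(st$s))
    rel <- points - matrix(base, n, 3, byrow = TRUE)
    ax <- as.vector(rel %*% dirn)
    rad2 <- rowSums(rel^2) - ax^2
    inside <- inside | (ax >= 0 & ax <= st$length & rad2 <= st$radius^2)
  }
  inside
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
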