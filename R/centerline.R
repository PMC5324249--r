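#' Construct a centerline object
#'
#' Ordered interior polyline with arc length (mm, from the inlet),
#' per-point maximal inscribed-sphere radius (distance to the lumen wall)
#' and unit tangents.
#' @param points n x 3 matrix (mm).
#' @param inscribed_radius per-point wall distance (mm), optional.
#' @return a `centerline`.
#' @export
centerline <- function(points, inscribed_radius = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  keep <- c(TRUE, seg > 1e-12)
  points <- points[keep, , drop = FALSE]
  if (!is.null(inscribed_radius)) inscribed_radius <- inscribed_radius[keep]
  seg <- sqrt(rowSums(diff(points)^2))
  structure(list(points = points,
                 arc_length = c(0, cumsum(seg)),
                 inscribed_radius = inscribed_radius,
                 tangents = polyline_tangents(points)),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.1f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

polyline_tangents <- function(points) {
  n <- nrow(points)
  d <- if (n == 2L) rbind(points[2, ] - points[1, ],
                          points[2, ] - points[1, ])
  else rbind(points[2, ] - points[1, ],
             points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE],
             points[n, ] - points[n - 1, ])
  d / pmax(sqrt(rowSums(d^2)), .Machine$double.eps)
}

resample_polyline <- function(points, step, values = NULL) {
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  s_new <- seq(0, L, by = step)
  if (s_new[length(s_new)] < L - 1e-9) s_new <- c(s_new, L)
  out <- cbind(approx(s, points[, 1], xout = s_new)$y,
               approx(s, points[, 2], xout = s_new)$y,
               approx(s, points[, 3], xout = s_new)$y)
  if (is.null(values)) return(list(points = out, s = s_new))
  list(points = out, s = s_new,
       values = approx(s, values, xout = s_new)$y)
}

# close open rims with centroid fans so parity voxelization sees a solid
cap_boundary_loops <- function(mesh) {
  loops <- mesh$boundary_loops
  if (length(loops) == 0L) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  for (loop in loops) {
    ctr <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, ctr)
    ci <- nrow(v)
    nxt <- c(loop[-1], loop[1])
    f <- rbind(f, cbind(loop, nxt, ci))
  }
  structure(list(vertices = v, faces = f, boundary_loops = list()),
            class = "surface_mesh")
}

#' Extract the interior centerline between two endpoints
#'
#' The lumen interior is voxelized (open rims are temporarily capped), the
#' wall distance computed by Euclidean distance transform, and the
#' centerline traced as the minimum-cost path between the endpoints on the
#' 26-neighbour voxel graph with edge cost
#' `length / wall_distance^p`.  Penalizing wall proximity drives the path
#' onto the ridge of maximal inscribed spheres, the same centrality notion
#' as a Voronoi-based medial axis.  The raw voxel path is lightly smoothed,
#' resampled at `step` mm, and the inscribed radius recomputed as the exact
#' point-to-surface distance.
#'
#' @param mesh a `surface_mesh` (open rims or closed).
#' @param source,target 3D points on or near the inlet/outlet.
#' @param pitch voxel pitch in mm (default 1, refined automatically when
#'   coarser than a fifth of the local radius).
#' @param p wall-distance exponent in the edge cost (default 2).
#' @param step resampling step, mm (default 0.5).
#' @return a `centerline`.
#' @export
compute_centerline <- function(mesh, source, target, pitch = NULL, p = 2,
                               step = 0.5) {
  source <- as.numeric(source)
  target <- as.numeric(target)
  if (length(mesh$boundary_loops) >= 2L) {
    nearest_loop <- function(p) which.min(vapply(
      mesh$boundary_loops, function(l) min(colSums(
        (t(mesh$vertices[l, , drop = FALSE]) - p)^2)), numeric(1)))
    if (nearest_loop(source) == nearest_loop(target))
      stop("source and target lie on the same boundary loop")
  }
  capped <- cap_boundary_loops(mesh)
  pitch0 <- pitch %||% 1
  vox <- interior_voxels(capped, pitch0)
  rmax <- max(vox$dist)
  if (is.null(pitch) && rmax / 5 < pitch0 && rmax > 0) {
    pitch0 <- max(rmax / 5, 0.25)
    vox <- interior_voxels(capped, pitch0)
  }
  if (length(vox$idx) == 0L) stop("mesh interior is empty at this pitch")

  path_pts <- dijkstra_centerline(vox, source, target, p)
  cl <- centerline(path_pts)
  cl <- smooth_centerline(cl, window = 3 * pitch0)
  cl <- refine_medial(cl, mesh, pitch0)
  # pin the path to the requested endpoints (rim centres)
  cl <- centerline(rbind(source, cl$points, target))
  cl <- smooth_centerline(cl, window = 4 * pitch0, mesh = mesh)
  rs <- resample_polyline(cl$points, step)
  cl <- centerline(rs$points)
  cl$inscribed_radius <-
    .cpp_closest_on_surface(cl$points, mesh$vertices, mesh$faces)$distance
  if (any(cl$inscribed_radius <= 0))
    warning("centerline touches the wall; consider a finer pitch")
  cl
}

interior_voxels <- function(capped, pitch) {
  lo <- apply(capped$vertices, 2, min) - 2 * pitch
  hi <- apply(capped$vertices, 2, max) + 2 * pitch
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / pitch)) + 1L)
  spacing <- rep(pitch, 3)
  inside <- .cpp_voxelize_parity(capped$vertices, capped$faces - 1L, dims,
                                 spacing, lo)
  labels <- .cpp_label_components(inside, dims)
  if (all(labels == 0L)) return(list(idx = integer(0)))
  main <- which.max(tabulate(labels))
  mask <- labels == main
  dist <- .cpp_edt(mask, dims, spacing)
  idx <- which(mask)
  list(idx = idx, dist = dist[idx], dims = dims, origin = lo,
       pitch = pitch, mask = mask)
}

dijkstra_centerline <- function(vox, source, target, p) {
  dims <- vox$dims
  idx <- vox$idx
  n <- length(idx)
  rank <- integer(prod(dims))
  rank[idx] <- seq_len(n)
  ijk <- arrayInd(idx, dims)
  centers <- sweep((ijk - 1) * vox$pitch, 2, vox$origin, `+`)

  # 13 unique neighbour offsets (half of the 26-neighbourhood)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  edges_from <- integer(0)
  edges_to <- integer(0)
  edges_w <- numeric(0)
  dvals <- pmax(vox$dist, vox$pitch / 4)
  for (r in seq_len(nrow(offs))) {
    nb <- ijk + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- rep(0L, n)
    lin[ok] <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1L) +
      dims[1] * dims[2] * (nb[ok, 3] - 1L)
    tr <- rep(0L, n)
    tr[ok] <- rank[lin[ok]]
    has <- tr > 0L
    len <- sqrt(sum(offs[r, ]^2)) * vox$pitch
    w <- len * 0.5 * (1 / dvals[has]^p + 1 / dvals[tr[has]]^p)
    edges_from <- c(edges_from, which(has))
    edges_to <- c(edges_to, tr[has])
    edges_w <- c(edges_w, w)
  }
  g <- igraph::make_graph(as.vector(rbind(edges_from, edges_to)), n = n,
                          directed = FALSE)
  src <- which.min(colSums((t(centers) - source)^2))
  dst <- which.min(colSums((t(centers) - target)^2))
  if (src == dst) stop("source and target map to the same interior voxel")
  sp <- igraph::shortest_paths(g, from = src, to = dst, weights = edges_w,
                               output = "vpath")
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2L)
    stop("no interior path between source and target (disconnected lumen?)")
  centers[vp, , drop = FALSE]
}

# push each point onto the medial locus (maximal inscribed sphere centre)
# by pattern search on the exact point-to-surface distance, restricted to
# the plane normal to the local tangent; accepted moves strictly increase
# clearance, so points can neither leave the lumen nor diverge
refine_medial <- function(cl, mesh, pitch, h_min = 0.02) {
  pts <- cl$points
  tg <- cl$tangents  # frozen during refinement
  ref <- ifelse(abs(tg[, 3]) < 0.9, 0, 1)
  u <- cbind(-tg[, 2], tg[, 1], 0) * (1 - ref) +
    cbind(tg[, 3], 0, -tg[, 1]) * ref
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
  v <- cbind(tg[, 2] * u[, 3] - tg[, 3] * u[, 2],
             tg[, 3] * u[, 1] - tg[, 1] * u[, 3],
             tg[, 1] * u[, 2] - tg[, 2] * u[, 1])
  dist_at <- function(p) .cpp_closest_on_surface(p, mesh$vertices,
                                                 mesh$faces)$distance
  d0 <- dist_at(pts)
  h <- pitch
  while (h > h_min) {
    for (dir in list(u, v, -u, -v)) {
      cand <- pts + h * dir
      dc <- dist_at(cand)
      better <- dc > d0 + 1e-12
      pts[better, ] <- cand[better, , drop = FALSE]
      d0[better] <- dc[better]
    }
    h <- h * 0.6
  }
  centerline(pts)
}

#' Smooth a centerline by an arc-length moving average
#'
#' Each point is replaced by the average of the points within a window
#' that shrinks symmetrically toward the ends, so the endpoints stay
#' pinned.  When `mesh` is given, any smoothed point that leaves the lumen
#' is restored to its unsmoothed position.
#' @param cl a `centerline`.
#' @param window full window width, mm.
#' @param mesh optional `surface_mesh` for the inside check.
#' @return smoothed `centerline`.
#' @export
smooth_centerline <- function(cl, window, mesh = NULL) {
  pts <- cl$points
  s <- cl$arc_length
  n <- nrow(pts)
  half <- pmin(window / 2, s - s[1], s[n] - s)
  out <- pts
  for (i in seq_len(n)) {
    if (half[i] <= 0) next
    sel <- which(abs(s - s[i]) <= half[i])
    out[i, ] <- colMeans(pts[sel, , drop = FALSE])
  }
  if (!is.null(mesh)) {
    chk <- .cpp_closest_on_surface(out, mesh$vertices, mesh$faces)
    fn <- face_normals(mesh)[chk$face, , drop = FALSE]
    outside <- rowSums((out - chk$closest) * fn) > 0
    out[outside, ] <- pts[outside, ]
  }
  centerline(out, cl$inscribed_radius)
}

#' Differential geometry of a centerline
#'
#' Tortuosity (total arc length over endpoint chord), a curvature profile
#' from the circumscribed circle of three points `stencil` mm apart, and
#' the arch apex taken as the point furthest along `elevation_axis`.
#' @param cl a `centerline`.
#' @param elevation_axis unit vector defining "up" (default +z).
#' @param stencil three-point stencil half-spacing, mm (default 2, the
#'   plane spacing).
#' @param apex_window half-width (mm) of the window around the apex over
#'   which the apex curvature is taken as the median of the profile; the
#'   local median damps discretization ripple that the three-point stencil
#'   amplifies (default 5).
#' @return a `centerline_geometry`: list with `tortuosity`,
#'   `curvature_profile` (per point, 1/mm), `apex_index`, `apex_curvature`.
#' @export
centerline_geometry <- function(cl, elevation_axis = c(0, 0, 1),
                                stencil = 2, apex_window = 5) {
  pts <- cl$points
  s <- cl$arc_length
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points")
  chord <- sqrt(sum((pts[n, ] - pts[1, ])^2))
  if (chord < 1e-9) stop("coincident endpoints: tortuosity undefined")
  tortuosity <- s[n] / chord

  interp <- function(si) {
    cbind(approx(s, pts[, 1], xout = si)$y,
          approx(s, pts[, 2], xout = si)$y,
          approx(s, pts[, 3], xout = si)$y)
  }
  curv <- rep(NA_real_, n)
  ok <- s >= stencil & s <= s[n] - stencil
  if (any(ok)) {
    a <- interp(s[ok] - stencil)
    b <- pts[ok, , drop = FALSE]
    c3 <- interp(s[ok] + stencil)
    curv[ok] <- menger_curvature(a, b, c3)
  }
  if (any(is.na(curv)) && any(!is.na(curv))) {
    first <- which(!is.na(curv))[1]
    last <- tail(which(!is.na(curv)), 1)
    curv[seq_len(first - 1)] <- curv[first]
    if (last < n) curv[(last + 1):n] <- curv[last]
  }
  elev <- as.vector(pts %*% (elevation_axis / sqrt(sum(elevation_axis^2))))
  apex <- which.max(elev)
  near_apex <- abs(s - s[apex]) <= apex_window & !is.na(curv)
  apex_curv <- if (any(near_apex)) median(curv[near_apex]) else curv[apex]
  structure(list(tortuosity = tortuosity, curvature_profile = curv,
                 apex_index = apex, apex_s = s[apex],
                 apex_curvature = apex_curv),
            class = "centerline_geometry")
}

#' @export
print.centerline_geometry <- function(x, ...) {
  cat(sprintf(
    "centerline_geometry: tortuosity %.4f, apex curvature %.4g /mm at s = %.1f mm\n",
    x$tortuosity, x$apex_curvature, x$apex_s))
  invisible(x)
}

# curvature of the circle through each point triple (rows of a, b, c)
menger_curvature <- function(a, b, c3) {
  ab <- b - a
  ac <- c3 - a
  bc <- c3 - b
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area2 <- sqrt(rowSums(cr^2))  # twice the triangle area
  den <- sqrt(rowSums(ab^2)) * sqrt(rowSums(ac^2)) * sqrt(rowSums(bc^2))
  ifelse(den > 0, 2 * area2 / den, 0)
}

#' Export a centerline as a data frame
#' @param cl a `centerline`.
#' @param geometry optional `centerline_geometry` whose curvature profile
#'   is joined on.
#' @return a tibble with s_mm, x, y, z, r_inscribed_mm and optionally
#'   curvature_per_mm.
#' @export
centerline_table <- function(cl, geometry = NULL) {
  out <- tibble::tibble(s_mm = cl$arc_length,
                        x = cl$points[, 1], y = cl$points[, 2],
                        z = cl$points[, 3],
                        r_inscribed_mm = cl$inscribed_radius %||%
                          rep(NA_real_, nrow(cl$points)))
  if (!is.null(geometry))
    out$curvature_per_mm <- geometry$curvature_profile
  out
}
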