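#' Sample measurement planes along a centerline
#'
#' Stations at arc lengths 0, spacing, 2*spacing, ... with the plane normal
#' equal to the local tangent.
#' @param cl a `centerline`.
#' @param spacing station spacing, mm (default 2).
#' @return tibble with s_mm, plane point (x, y, z) and normal (nx, ny, nz).
#' @export
sample_planes <- function(cl, spacing = 2) {
  if (spacing <= 0) stop("spacing must be positive")
  L <- max(cl$arc_length)
  if (spacing > L) stop("spacing exceeds the centerline length")
  s_new <- seq(0, L, by = spacing)
  rs <- resample_polyline(cl$points, spacing)
  pts <- rs$points[match(round(s_new, 9), round(rs$s, 9)), , drop = FALSE]
  tg <- polyline_tangents(rs$points)[match(round(s_new, 9),
                                           round(rs$s, 9)), , drop = FALSE]
  tibble::tibble(s_mm = s_new,
                 x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 nx = tg[, 1], ny = tg[, 2], nz = tg[, 3])
}

# orthonormal in-plane basis for a unit normal
plane_basis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- pracma::cross(ref, normal)
  u <- u / sqrt(sum(u^2))
  v <- pracma::cross(normal, u)
  list(u = u, v = v, n = normal)
}

#' Intersect a mesh with a plane and pick the section around a point
#'
#' All intersection polylines of the mesh with the plane are chained from
#' per-triangle segments (welded on shared mesh edges).  The closed loop
#' enclosing `center_point` (or, failing that, the closed loop whose
#' centroid is nearest) is projected to 2D plane coordinates.  If the only
#' candidate chains are open -- the plane cuts a rim or a branch ostium --
#' the section is flagged excluded with reason `"open contour"`.
#'
#' @param mesh a `surface_mesh`.
#' @param point,normal the plane (point in mm, normal need not be unit).
#' @param center_point the centerline point the section must enclose
#'   (defaults to `point`).
#' @return a `cross_section`: list with `contour` (k x 2, closed, 2D plane
#'   coordinates), `contour3d`, `closed`, `excluded`, `reason`, `frame`.
#' @export
section_contour <- function(mesh, point, normal, center_point = point) {
  fr <- plane_basis(as.numeric(normal))
  point <- as.numeric(point)
  v <- mesh$vertices
  f <- mesh$faces
  sd <- as.vector((v - matrix(point, nrow(v), 3, byrow = TRUE)) %*% fr$n)
  side <- sd > 0
  fs <- matrix(side[f], ncol = 3)
  ncross <- rowSums(fs)
  hit <- which(ncross == 1L | ncross == 2L)
  if (length(hit) == 0L)
    return(empty_section("plane misses mesh", fr))
  nvv <- nrow(v)
  segs_a <- matrix(0, length(hit), 3)
  segs_b <- matrix(0, length(hit), 3)
  key_a <- numeric(length(hit))
  key_b <- numeric(length(hit))
  for (i in seq_along(hit)) {
    t <- hit[i]
    idx <- f[t, ]
    pos <- if (ncross[t] == 1L) which(fs[t, ]) else which(!fs[t, ])
    apex <- idx[pos]
    o1 <- idx[(pos %% 3) + 1]
    o2 <- idx[((pos + 1) %% 3) + 1]
    w1 <- sd[apex] / (sd[apex] - sd[o1])
    w2 <- sd[apex] / (sd[apex] - sd[o2])
    segs_a[i, ] <- v[apex, ] + w1 * (v[o1, ] - v[apex, ])
    segs_b[i, ] <- v[apex, ] + w2 * (v[o2, ] - v[apex, ])
    key_a[i] <- min(apex, o1) * (nvv + 1) + max(apex, o1)
    key_b[i] <- min(apex, o2) * (nvv + 1) + max(apex, o2)
  }
  chains <- chain_segments(key_a, key_b)
  if (length(chains$loops) == 0L)
    return(empty_section("open contour", fr))
  # project loops to 2D; prefer the smallest loop enclosing the center
  ctr3 <- as.numeric(center_point - point)
  c2 <- c(sum(ctr3 * fr$u), sum(ctr3 * fr$v))
  cands <- lapply(chains$loops, function(loop) {
    p3 <- matrix(0, length(loop$seg), 3)
    p3[loop$from_a, ] <- segs_a[loop$seg[loop$from_a], , drop = FALSE]
    p3[!loop$from_a, ] <- segs_b[loop$seg[!loop$from_a], , drop = FALSE]
    rel <- p3 - matrix(point, nrow(p3), 3, byrow = TRUE)
    p2 <- cbind(rel %*% fr$u, rel %*% fr$v)
    list(p2 = p2, p3 = p3,
         encloses = point_in_polygon(c2, p2),
         area = abs(polygon_area(p2)),
         cdist = sqrt(sum((colMeans(p2) - c2)^2)))
  })
  enc <- vapply(cands, `[[`, logical(1), "encloses")
  if (!any(enc) && chains$n_open > 0L)
    return(empty_section("open contour", fr))
  best <- if (any(enc)) {
    inn <- cands[enc]
    inn[[which.min(vapply(inn, `[[`, numeric(1), "area"))]]
  } else {
    cands[[which.min(vapply(cands, `[[`, numeric(1), "cdist"))]]
  }
  # drop duplicate points left where the plane hits a mesh vertex exactly
  keep <- c(TRUE, sqrt(rowSums(diff(best$p2)^2)) > 1e-9)
  if (sqrt(sum((best$p2[nrow(best$p2), ] - best$p2[1, ])^2)) <= 1e-9)
    keep[length(keep)] <- FALSE
  structure(list(contour = best$p2[keep, , drop = FALSE],
                 contour3d = best$p3[keep, , drop = FALSE], closed = TRUE,
                 excluded = FALSE, reason = NA_character_, frame = fr),
            class = "cross_section")
}

empty_section <- function(reason, fr) {
  structure(list(contour = NULL, contour3d = NULL, closed = FALSE,
                 excluded = TRUE, reason = reason, frame = fr),
            class = "cross_section")
}

# chain segments whose endpoints are keyed by the mesh edge they lie on;
# returns only closed loops (ordered segment indices + which endpoint leads)
chain_segments <- function(key_a, key_b) {
  n <- length(key_a)
  keys <- unique(c(key_a, key_b))
  ka <- match(key_a, keys)
  kb <- match(key_b, keys)
  # adjacency: each edge key should appear in exactly 2 segments for a loop
  inc <- vector("list", length(keys))
  for (i in seq_len(n)) {
    inc[[ka[i]]] <- c(inc[[ka[i]]], i)
    inc[[kb[i]]] <- c(inc[[kb[i]]], i)
  }
  used <- rep(FALSE, n)
  loops <- list()
  n_open <- 0L
  for (start in seq_len(n)) {
    if (used[start]) next
    seg_seq <- integer(0)
    from_a <- logical(0)
    cur <- start
    enter_key <- ka[start]  # walk out through kb
    closed <- FALSE
    repeat {
      used[cur] <- TRUE
      seg_seq <- c(seg_seq, cur)
      from_a <- c(from_a, enter_key == ka[cur])
      exit_key <- if (enter_key == ka[cur]) kb[cur] else ka[cur]
      if (exit_key == ka[start] && length(seg_seq) >= 3L) {
        closed <- TRUE
        break
      }
      nxts <- setdiff(inc[[exit_key]], cur)
      nxts <- nxts[!used[nxts]]
      if (length(nxts) == 0L) break
      cur <- nxts[1]
      enter_key <- exit_key
    }
    if (closed) loops[[length(loops) + 1L]] <-
        list(seg = seg_seq, from_a = from_a)
    else n_open <- n_open + 1L
  }
  list(loops = loops, n_open = n_open)
}

point_in_polygon <- function(p, poly) {
  x <- poly[, 1] - p[1]
  y <- poly[, 2] - p[2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  crosses <- ((y > 0) != (yn > 0)) &
    (x + (0 - y) * (xn - x) / (yn - y) > 0)
  sum(crosses) %% 2 == 1
}

polygon_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Maximum diameter and area of a section contour
#'
#' Maximum diameter is the largest point-pair distance of the contour
#' (computed on the convex hull, which carries the diametral pair); area is
#' the shoelace magnitude.  Errors on self-intersecting polygons.
#' @param contour k x 2 closed polygon (first point not repeated).
#' @return list with `max_diameter` (mm) and `area` (mm^2).
#' @export
contour_metrics <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) stop("contour needs at least 3 vertices")
  if (polygon_self_intersects(contour))
    stop("contour polygon is self-intersecting")
  hull <- grDevices::chull(contour[, 1], contour[, 2])
  hp <- contour[hull, , drop = FALSE]
  max_d <- max(dist(hp))
  list(max_diameter = max_d, area = abs(polygon_area(contour)))
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n > 2000L) return(FALSE)  # chained mesh sections are simple
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- ii < jj & jj != ii + 1L & !(ii == 1L & jj == n)
  ii <- ii[keep]; jj <- jj[keep]
  p1 <- a[ii, , drop = FALSE]; p2 <- b[ii, , drop = FALSE]
  p3 <- a[jj, , drop = FALSE]; p4 <- b[jj, , drop = FALSE]
  d1 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  d2 <- (p2[, 1] - p1[, 1]) * (p4[, 2] - p1[, 2]) -
    (p2[, 2] - p1[, 2]) * (p4[, 1] - p1[, 1])
  d3 <- (p4[, 1] - p3[, 1]) * (p1[, 2] - p3[, 2]) -
    (p4[, 2] - p3[, 2]) * (p1[, 1] - p3[, 1])
  d4 <- (p4[, 1] - p3[, 1]) * (p2[, 2] - p3[, 2]) -
    (p4[, 2] - p3[, 2]) * (p2[, 1] - p3[, 1])
  eps <- 1e-9 * max(abs(poly))^2
  any(d1 * d2 < -eps & d3 * d4 < -eps)
}

#' Continuous cross-sectional profile of a vessel
#'
#' Measures maximum diameter and area on planes normal to the centerline at
#' every station.  Stations are flagged excluded when the section is open
#' (rim or branch ostium cut), falls inside a user-supplied branch window,
#' or its area jumps more than `area_jump` relative to both neighbours
#' (automatic branch detection).
#'
#' @param mesh a `surface_mesh`.
#' @param cl the `centerline` computed on this mesh.
#' @param spacing station spacing, mm (default 2).
#' @param branch_windows optional list of `c(start, end)` arc spans (mm) to
#'   exclude.
#' @param area_jump relative area jump flagged as a branch artifact
#'   (default 0.3).
#' @return a `profile_table` tibble: s_mm, max_diameter_mm, area_mm2,
#'   excluded, reason, with the sections kept in the `sections` attribute.
#' @export
measure_profile <- function(mesh, cl, spacing = 2, branch_windows = NULL,
                            area_jump = 0.3) {
  planes <- sample_planes(cl, spacing)
  ns <- nrow(planes)
  dia <- area <- rep(NA_real_, ns)
  excl <- rep(FALSE, ns)
  reason <- rep(NA_character_, ns)
  sections <- vector("list", ns)
  for (i in seq_len(ns)) {
    sec <- section_contour(mesh, point = c(planes$x[i], planes$y[i],
                                           planes$z[i]),
                           normal = c(planes$nx[i], planes$ny[i],
                                      planes$nz[i]))
    sections[[i]] <- sec
    if (sec$excluded) {
      excl[i] <- TRUE
      reason[i] <- sec$reason
    } else {
      m <- contour_metrics(sec$contour)
      dia[i] <- m$max_diameter
      area[i] <- m$area
    }
  }
  for (w in branch_windows %||% list()) {
    inw <- planes$s_mm >= w[1] & planes$s_mm <= w[2]
    reason[inw & !excl] <- "branch window"
    excl[inw] <- TRUE
  }
  # area jump vs both neighbours flags ostium-adjacent stations
  if (ns >= 3L) {
    for (i in 2:(ns - 1L)) {
      if (excl[i] || is.na(area[i])) next
      a0 <- area[i - 1L]; a1 <- area[i + 1L]
      if (!is.na(a0) && !is.na(a1) &&
          abs(area[i] - a0) / a0 > area_jump &&
          abs(area[i] - a1) / a1 > area_jump) {
        excl[i] <- TRUE
        reason[i] <- "area jump"
      }
    }
  }
  out <- tibble::tibble(s_mm = planes$s_mm, max_diameter_mm = dia,
                        area_mm2 = area, excluded = excl, reason = reason)
  attr(out, "sections") <- sections
  attr(out, "spacing") <- spacing
  class(out) <- c("profile_table", class(out))
  out
}

#' Map landmark stations onto a measured profile
#'
#' For each named landmark arc length, the diameter at the nearest
#' non-excluded station; a landmark falling in an excluded span takes the
#' nearest non-excluded neighbour with a warning.
#' @param profile a `profile_table`.
#' @param stations named numeric vector of arc lengths (mm); conventionally
#'   the eight manual stations from the sinotubular junction down to the
#'   descending aorta at the caudal border of the left atrium.
#' @return tibble: landmark, s_landmark_mm, s_station_mm, max_diameter_mm.
#' @export
map_stations <- function(profile, stations) {
  if (any(stations < min(profile$s_mm) - 1e-9) ||
      any(stations > max(profile$s_mm) + 1e-9))
    stop("station positions outside the profile range")
  ok <- !profile$excluded
  if (!any(ok)) stop("profile has no non-excluded stations")
  nm <- names(stations) %||% paste0("station_", seq_along(stations))
  rows <- lapply(seq_along(stations), function(i) {
    s0 <- stations[i]
    nearest_any <- which.min(abs(profile$s_mm - s0))
    j <- which(ok)[which.min(abs(profile$s_mm[ok] - s0))]
    if (profile$excluded[nearest_any])
      warning("landmark ", nm[i], " falls in an excluded span; ",
              "using nearest non-excluded station", call. = FALSE)
    tibble::tibble(landmark = nm[i], s_landmark_mm = unname(s0),
                   s_station_mm = profile$s_mm[j],
                   max_diameter_mm = profile$max_diameter_mm[j])
  })
  dplyr::bind_rows(rows)
}

#' Align a follow-up profile to a reference profile at a landmark
#'
#' Applies the rigid arc-length shift `landmark_a - landmark_b` to `b` and
#' linearly resamples its values onto `a`'s stations (visit-to-visit
#' alignment "at the branches").
#' @param a,b `profile_table`s.
#' @param landmark_a,landmark_b the matching landmark arc length on each.
#' @return `b` shifted and resampled onto `a`'s stations.
#' @export
align_profiles <- function(a, b, landmark_a, landmark_b) {
  shift <- landmark_a - landmark_b
  s_b <- b$s_mm + shift
  if (max(s_b) < min(a$s_mm) || min(s_b) > max(a$s_mm))
    stop("no overlap between profiles after alignment shift")
  ok <- !b$excluded & !is.na(b$max_diameter_mm)
  if (sum(ok) < 2L) stop("not enough valid stations in b")
  dia <- approx(s_b[ok], b$max_diameter_mm[ok], xout = a$s_mm)$y
  are <- approx(s_b[ok], b$area_mm2[ok], xout = a$s_mm)$y
  # excluded spans of b propagate to the nearest target station
  excl <- rep(FALSE, nrow(a))
  if (any(b$excluded)) {
    for (sb in s_b[b$excluded]) {
      j <- which.min(abs(a$s_mm - sb))
      if (abs(a$s_mm[j] - sb) <= (attr(a, "spacing") %||% 2)) excl[j] <- TRUE
    }
  }
  excl <- excl | is.na(dia)
  out <- tibble::tibble(s_mm = a$s_mm, max_diameter_mm = dia,
                        area_mm2 = are, excluded = excl,
                        reason = ifelse(excl, "aligned from b", NA))
  attr(out, "spacing") <- attr(a, "spacing")
  class(out) <- c("profile_table", class(out))
  out
}

#' Classify per-station visit-to-visit change
#'
#' Growth when the follow-up diameter exceeds the reference by more than
#' `threshold`, shrinkage when it is smaller by more, stable otherwise.
#' The default threshold of 1.5 mm is the scale of manual inter-observer
#' variability (about one pixel), below which change is not called.
#' @param a reference `profile_table`.
#' @param b follow-up `profile_table`, aligned onto `a`'s stations.
#' @param threshold mm (default 1.5).
#' @return tibble: s_mm, diameter_a_mm, diameter_b_mm, change_mm, class
#'   (growth/shrinkage/stable/excluded).
#' @export
classify_change <- function(a, b, threshold = 1.5) {
  if (!isTRUE(all.equal(a$s_mm, b$s_mm)))
    stop("profiles are not on common stations; align first")
  d <- b$max_diameter_mm - a$max_diameter_mm
  cls <- dplyr::case_when(
    a$excluded | b$excluded | is.na(d) ~ "excluded",
    d > threshold ~ "growth",
    d < -threshold ~ "shrinkage",
    TRUE ~ "stable")
  tibble::tibble(s_mm = a$s_mm, diameter_a_mm = a$max_diameter_mm,
                 diameter_b_mm = b$max_diameter_mm, change_mm = d,
                 class = cls)
}
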