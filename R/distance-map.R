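#' Per-vertex Euclidean distance from the lumen surface to the centerline
#'
#' The size field: for every mesh vertex, the distance to the nearest
#' point of the (densely resampled) centerline.  For a branched vessel
#' pass a list of centerlines (main vessel plus one polyline per branch);
#' the minimum over all of them is taken, so vertices near an ostium bind
#' to the branch path.
#'
#' @param mesh a `surface_mesh`.
#' @param cl a `centerline`, or a list of them.
#' @param step centerline resampling step, mm (default 0.5, which keeps
#'   the chord-sampling error below about 0.05 mm).
#' @return a `distance_field` tibble: vertex, distance_mm, s_mm (arc
#'   length of the nearest main-path point; NA when a branch is nearer),
#'   with the mesh in the `mesh` attribute.
#' @export
euclidean_field <- function(mesh, cl, step = 0.5) {
  cls <- if (inherits(cl, "centerline")) list(cl) else cl
  if (length(cls) == 0L) stop("empty centerline")
  pools <- lapply(seq_along(cls), function(i) {
    rs <- resample_polyline(cls[[i]]$points, step)
    cbind(rs$points, s = rs$s, path = i)
  })
  pool <- do.call(rbind, pools)
  nn <- RANN::nn2(pool[, 1:3, drop = FALSE], mesh$vertices, k = 1)
  out <- tibble::tibble(
    vertex = seq_len(nrow(mesh$vertices)),
    distance_mm = as.vector(nn$nn.dists),
    s_mm = ifelse(pool[nn$nn.idx, 5] == 1, pool[nn$nn.idx, 4], NA_real_))
  attr(out, "mesh") <- mesh
  class(out) <- c("distance_field", class(out))
  out
}

#' Regional summaries of a distance field
#'
#' Vertices are assigned to regions (ascending / arch / descending) by the
#' arc length of their nearest main-centerline point, split at two
#' explicit cut points; vertices bound to branch paths are left out.
#' @param field a `distance_field`.
#' @param boundaries two increasing arc-length cut points, mm.
#' @return tibble: region, mean_mm, sd_mm, max_mm, n_vertices.
#' @export
summarize_regions <- function(field, boundaries) {
  if (length(boundaries) != 2L || diff(boundaries) < 0)
    stop("boundaries must be two increasing arc lengths")
  region <- cut(field$s_mm, c(-Inf, boundaries, Inf),
                labels = c("ascending", "arch", "descending"))
  levs <- levels(region)
  rows <- lapply(levs, function(rg) {
    d <- field$distance_mm[!is.na(region) & region == rg]
    tibble::tibble(region = rg,
                   mean_mm = if (length(d)) mean(d) else NA_real_,
                   sd_mm = if (length(d) > 1) sd(d) else NA_real_,
                   max_mm = if (length(d)) max(d) else NA_real_,
                   n_vertices = length(d))
  })
  dplyr::bind_rows(rows)
}

#' Per-station circumferential asymmetry of a distance field
#'
#' Vertices are binned by the arc length of their nearest centerline
#' point; each bin's index is (max - min) / mean of the distances, zero
#' for a circular section and positive for out-of-round ones.  Bins with
#' fewer than `min_vertices` vertices are skipped.
#' @param field a `distance_field`.
#' @param spacing bin width, mm (default 2).
#' @param min_vertices minimum bin occupancy (default 8).
#' @return tibble: s_mm (bin centre), asymmetry, n_vertices.
#' @export
asymmetry_index <- function(field, spacing = 2, min_vertices = 8L) {
  ok <- !is.na(field$s_mm)
  s <- field$s_mm[ok]
  d <- field$distance_mm[ok]
  bin <- floor(s / spacing)
  rows <- lapply(sort(unique(bin)), function(b) {
    di <- d[bin == b]
    if (length(di) < min_vertices) return(NULL)
    tibble::tibble(s_mm = (b + 0.5) * spacing,
                   asymmetry = (max(di) - min(di)) / mean(di),
                   n_vertices = length(di))
  })
  dplyr::bind_rows(rows)
}

#' Write a mesh with a per-vertex scalar as ASCII PLY
#'
#' Lets any mesh viewer render the distance or change colour maps.
#' @param mesh a `surface_mesh`.
#' @param scalars per-vertex numeric vector.
#' @param path output path.
#' @param name scalar property name in the PLY header.
#' @return `path`, invisibly.
#' @export
write_ply_scalar <- function(mesh, scalars, path, name = "euclid_mm") {
  v <- mesh$vertices
  f <- mesh$faces
  stopifnot(length(scalars) == nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("property float %s", name),
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3],
                     scalars), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}
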