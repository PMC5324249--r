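#' @useDynLib vesselgauge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd qf pf pt qnorm cor approx var quantile
#' @importFrom utils head tail read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

WELD_TOL <- 1e-6  # mm; STL is triangle soup, vertices must be welded

#' Construct a triangulated surface mesh
#'
#' The common container for all surface operations: an n x 3 matrix of
#' vertex coordinates in millimetres and an m x 3 integer matrix of 1-based
#' vertex indices.  `validate = TRUE` welds coincident vertices, drops
#' degenerate and duplicate faces, checks edge-manifoldness, makes the
#' winding consistent (outward for closed surfaces), and records open
#' boundary loops (rims left by clipping).
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param validate logical; run full validation (default TRUE).
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces` and `boundary_loops` (list of ordered vertex-index cycles;
#'   empty for a closed mesh).
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) == 0L || nrow(vertices) == 0L)
    stop("empty mesh")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces,
                      boundary_loops = list()),
                 class = "surface_mesh")
  if (validate) m <- validate_mesh(m) else m$boundary_loops <- NULL
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  closed <- length(x$boundary_loops) == 0L
  cat(sprintf("surface_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (closed) "closed" else
                sprintf("%d boundary loop(s)", length(x$boundary_loops))))
  invisible(x)
}

weld_vertices <- function(vertices, faces, tol = WELD_TOL) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces[] <- remap[faces]
  list(vertices = vertices, faces = faces)
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    n <- n / pmax(len, .Machine$double.eps)
  }
  n
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @return numeric scalar, mm^2.
#' @export
mesh_area <- function(mesh) {
  n <- face_normals(mesh, normalize = FALSE)
  sum(sqrt(rowSums(n^2))) / 2
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Signed tetrahedron sum; meaningful (and positive, after validation
#' orients the surface outward) only for closed meshes.
#' @param mesh a `surface_mesh`.
#' @return numeric scalar, mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# directed edge list of a face matrix: 3m x 2
directed_edges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

edge_keys <- function(edges, nv) {
  pmin(edges[, 1], edges[, 2]) * (nv + 1) + pmax(edges[, 1], edges[, 2])
}

#' Validate and canonicalize a surface mesh
#'
#' Welds coincident vertices (1e-6 mm), removes degenerate and duplicate
#' faces, errors on non-edge-manifold input (an edge bordered by more than
#' two faces), propagates a consistent winding across each connected
#' component, orients closed surfaces outward (positive enclosed volume),
#' and extracts ordered boundary loops.
#' @param mesh a `surface_mesh` (or bare list with vertices/faces).
#' @return validated `surface_mesh`.
#' @export
validate_mesh <- function(mesh) {
  w <- weld_vertices(mesh$vertices, mesh$faces)
  v <- w$vertices
  f <- w$faces
  # degenerate: repeated vertex or (numerically) zero area
  repeated <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!repeated, , drop = FALSE]
  tmp <- structure(list(vertices = v, faces = f), class = "surface_mesh")
  areas2 <- sqrt(rowSums(face_normals(tmp, normalize = FALSE)^2))
  f <- f[areas2 > (WELD_TOL)^2, , drop = FALSE]
  # duplicate faces (same vertex set)
  fs <- t(apply(f, 1, sort))
  f <- f[!duplicated(fs), , drop = FALSE]
  if (nrow(f) == 0L) stop("mesh has no valid faces after cleaning")

  # drop unreferenced vertices (e.g. left behind by clipping)
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    v <- v[used, , drop = FALSE]
    f[] <- match(f, used)
  }

  nv <- nrow(v)
  de <- directed_edges(f)
  keys <- edge_keys(de, nv)
  cnt <- table(keys)
  if (any(cnt > 2L))
    stop("mesh is not edge-manifold: ", sum(cnt > 2L),
         " edge(s) border more than two faces")

  f <- orient_faces(f, nv)

  m <- structure(list(vertices = v, faces = f, boundary_loops = list()),
                 class = "surface_mesh")
  m$boundary_loops <- boundary_loops(m)
  if (length(m$boundary_loops) == 0L && mesh_volume(m) < 0) {
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}

# propagate consistent winding by frontier BFS over shared edges
orient_faces <- function(f, nv) {
  nf <- nrow(f)
  de <- directed_edges(f)
  keys <- edge_keys(de, nv)
  face_of_edge <- rep(seq_len(nf), 3L)
  ord <- order(keys)
  ks <- keys[ord]
  run_start <- which(c(TRUE, ks[-1] != ks[-length(ks)]))
  run_len <- diff(c(run_start, length(ks) + 1L))
  shared <- run_start[run_len == 2L]
  if (length(shared) == 0L) return(f)
  e1 <- ord[shared]
  e2 <- ord[shared + 1L]
  f1 <- face_of_edge[e1]
  f2 <- face_of_edge[e2]
  sdir <- de[e1, 1] == de[e2, 1]  # same direction across the edge = conflict
  from <- c(f1, f2)
  to <- c(f2, f1)
  sd2 <- c(sdir, sdir)
  o2 <- order(from)
  from <- from[o2]; to <- to[o2]; sd2 <- sd2[o2]
  ptr <- c(0L, cumsum(tabulate(from, nbins = nf)))  # CSR row pointers
  flip <- rep(NA, nf)
  remaining <- seq_len(nf)
  while (length(remaining)) {
    seed <- remaining[1]
    flip[seed] <- FALSE
    frontier <- seed
    while (length(frontier)) {
      idx <- sequence(ptr[frontier + 1L] - ptr[frontier],
                      from = ptr[frontier] + 1L)
      if (length(idx) == 0L) break
      src <- from[idx]
      dst <- to[idx]
      want <- ifelse(sd2[idx], !flip[src], flip[src])
      new <- is.na(flip[dst]) & !duplicated(dst)
      flip[dst[new]] <- want[new]
      frontier <- dst[new]
    }
    remaining <- remaining[is.na(flip[remaining])]
  }
  flip[is.na(flip)] <- FALSE
  if (any(flip)) f[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]
  f
}

# ordered cycles of boundary (single-face) edges
boundary_loops <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  de <- directed_edges(f)
  keys <- edge_keys(de, nv)
  cnt <- table(keys)
  bkeys <- names(cnt)[cnt == 1L]
  if (length(bkeys) == 0L) return(list())
  bedges <- de[keys %in% as.numeric(bkeys), , drop = FALSE]
  # with consistent winding, boundary edges chain head-to-tail
  nxt <- bedges[match(seq_len(nv), bedges[, 1]), 2]
  loops <- list()
  used <- rep(FALSE, nrow(bedges))
  starts <- bedges[, 1]
  visited <- rep(FALSE, nv)
  for (s in starts) {
    if (visited[s]) next
    loop <- s
    visited[s] <- TRUE
    cur <- nxt[s]
    guard <- 0L
    while (!is.na(cur) && cur != s && guard < nv) {
      loop <- c(loop, cur)
      visited[cur] <- TRUE
      cur <- nxt[cur]
      guard <- guard + 1L
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Read a surface mesh from an STL file
#'
#' Accepts both the ASCII and binary (80-byte header, little-endian,
#' uint32 triangle count) dialects.  STL stores a triangle soup; coincident
#' vertices are welded at 1e-6 mm and the result validated.
#' @param path file path.
#' @return a validated `surface_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  head_bytes <- readBin(con, "raw", n = 80L)
  close(con)
  if (length(head_bytes) == 0L) stop("empty STL file: ", path)
  is_ascii <- identical(rawToChar(head_bytes[1:5]), "solid") &&
    grepl("facet", paste(readLines(path, n = 20L, warn = FALSE),
                         collapse = " "), fixed = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("STL file contains no triangles: ", path)
  nt <- nrow(tri) / 3L
  surface_mesh(tri, matrix(seq_len(3L * nt), ncol = 3, byrow = TRUE))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("malformed ASCII STL (vertex count not a multiple of 3) at line ",
         utils::tail(grep("^\\s*vertex\\s", lines), 1L), ": ", path)
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed ASCII STL vertex line ",
         grep("^\\s*vertex\\s", lines)[bad[1]], ": ", path)
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
           byrow = TRUE))
  if (anyNA(coords)) stop("non-numeric vertex coordinates in ASCII STL: ",
                          path)
  coords
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(nt)
  if (is.na(nt) || nt < 0L || expected > sz)
    stop("malformed binary STL: declared ", nt, " triangles needs ",
         expected, " bytes, file has ", sz)
  raw_data <- readBin(con, "raw", n = 50L * nt)
  rec <- matrix(raw_data, nrow = 50L)
  tri <- matrix(0, nrow = 3L * nt, ncol = 3L)
  for (corner in 0:2) {
    block <- rec[(13L + 12L * corner):(24L + 12L * corner), , drop = FALSE]
    vals <- readBin(as.vector(block), "double", size = 4L, n = 3L * nt,
                    endian = "little")
    tri[seq_len(nt) * 3L - 2L + corner, ] <- matrix(vals, ncol = 3,
                                                    byrow = TRUE)
  }
  tri
}

#' Write a surface mesh to an STL file
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param ascii write the ASCII dialect instead of binary (default FALSE).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!ascii) {
    # quantize to float32 first so write-read-write is byte-stable
    v <- matrix(readBin(writeBin(as.vector(v), raw(), size = 4L),
                        "double", size = 4L, n = length(v)),
                ncol = 3L)
    mesh <- structure(list(vertices = v, faces = f), class = "surface_mesh")
  }
  n <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid vesselgauge", con)
    for (t in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[t, 1], n[t, 2], n[t, 3]), con)
      writeLines("    outer loop", con)
      for (c3 in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           v[f[t, c3], 1], v[f[t, c3], 2], v[f[t, c3], 3]),
                   con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid vesselgauge", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("vesselgauge binary STL"),
               raw(80 - nchar("vesselgauge binary STL"))), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    # per-triangle record: normal, 3 vertices (float32), attribute uint16
    for (t in seq_len(nrow(f))) {
      writeBin(as.vector(t(rbind(n[t, ], v[f[t, ], , drop = FALSE]))), con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Smooth a surface mesh (Taubin lambda/mu scheme)
#'
#' Alternating positive/negative Laplacian steps give feature smoothing
#' without the volume shrinkage of plain Laplacian smoothing; at the
#' defaults a closed surface's volume changes by well under 1 percent.
#' Topology is untouched.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations number of lambda/mu passes (default 30).
#' @param factor positive step in (0,1) (default 0.5); the negative step is
#'   derived from the usual pass-band relation 1/mu = 1/lambda - k_pb with
#'   k_pb = 0.02.
#' @return smoothed `surface_mesh` (same topology).
#' @export
smooth_mesh <- function(mesh, iterations = 30L, factor = 0.5) {
  if (!is.finite(factor) || factor <= 0 || factor >= 1)
    stop("smoothing factor must lie in (0, 1)")
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  if (iterations == 0L) return(mesh)
  lambda <- factor
  mu <- 1 / (0.02 - 1 / lambda)  # negative step, |mu| slightly > lambda
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  # vertex adjacency from edges (uniform weights)
  de <- directed_edges(f)
  ekeys <- edge_keys(de, nv)
  e <- de[!duplicated(ekeys), , drop = FALSE]
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  deg <- tabulate(i, nbins = nv)
  lap <- function(x) {
    acc <- matrix(0, nv, 3)
    acc[, 1] <- rowsum(x[j, 1], i, reorder = TRUE)
    acc[, 2] <- rowsum(x[j, 2], i, reorder = TRUE)
    acc[, 3] <- rowsum(x[j, 3], i, reorder = TRUE)
    acc / pmax(deg, 1L) - x
  }
  for (it in seq_len(iterations)) {
    v <- v + lambda * lap(v)
    v <- v + mu * lap(v)
  }
  out <- mesh
  out$vertices <- v
  out
}

#' Define a clipping plane
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized internally.
#' @param keep_side `+1` keeps the half-space the normal points into,
#'   `-1` the opposite one.
#' @return a `clip_plane` object.
#' @export
clip_plane <- function(point, normal, keep_side = 1) {
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be non-zero")
  structure(list(point = as.numeric(point), normal = as.numeric(normal) / nn,
                 keep_side = sign(keep_side)), class = "clip_plane")
}

#' Clip a mesh by one or more planes
#'
#' Faces entirely on the discard side are removed and crossing triangles
#' are re-cut exactly at the plane, leaving a clean planar rim that is
#' recorded as a new boundary loop.  A plane that misses the mesh entirely
#' warns and is skipped.
#' @param mesh a `surface_mesh`.
#' @param planes a `clip_plane` or list of them.
#' @return clipped, re-validated `surface_mesh`.
#' @export
clip_mesh <- function(mesh, planes) {
  if (inherits(planes, "clip_plane")) planes <- list(planes)
  for (pl in planes) mesh <- clip_one(mesh, pl)
  mesh
}

clip_one <- function(mesh, plane) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- as.vector((v - matrix(plane$point, nrow(v), 3, byrow = TRUE)) %*%
                   plane$normal) * plane$keep_side
  if (all(s >= 0) || all(s <= 0)) {
    if (all(s >= -WELD_TOL)) {
      warning("clip plane does not intersect the mesh; no-op")
      return(mesh)
    }
    stop("clip plane discards the entire mesh")
  }
  keep_v <- s >= 0
  fk <- matrix(keep_v[f], ncol = 3)
  nkeep <- rowSums(fk)
  crossing <- which(nkeep == 1L | nkeep == 2L)
  out_tri <- vector("list", length(crossing) + 1L)
  out_tri[[1L]] <- f[nkeep == 3L, , drop = FALSE]
  slot <- 1L
  newv <- list()
  edge_cache <- new.env(parent = emptyenv())
  cut_point <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- s[a] / (s[a] - s[b])
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    newv[[length(newv) + 1L]] <<- p
    id <- nrow(v) + length(newv)
    edge_cache[[key]] <- id
    id
  }
  for (t in crossing) {
    idx <- f[t, ]
    inside <- fk[t, ]
    slot <- slot + 1L
    if (nkeep[t] == 1L) {
      pos <- which(inside)
      kept <- idx[pos]
      nxt <- idx[(pos %% 3) + 1]; prv <- idx[((pos + 1) %% 3) + 1]
      p1 <- cut_point(kept, nxt)
      p2 <- cut_point(kept, prv)
      out_tri[[slot]] <- matrix(c(kept, p1, p2), 1, 3)
    } else {
      pos <- which(!inside)
      dropped <- idx[pos]
      nxt <- idx[(pos %% 3) + 1]; prv <- idx[((pos + 1) %% 3) + 1]
      p1 <- cut_point(dropped, nxt)  # on edge dropped->next
      p2 <- cut_point(dropped, prv)  # on edge dropped->prev
      out_tri[[slot]] <- rbind(c(p1, nxt, prv), c(p1, prv, p2))
    }
  }
  v2 <- rbind(v, do.call(rbind, newv))
  f2 <- do.call(rbind, out_tri)
  if (is.null(f2) || nrow(f2) == 0L) stop("clipping removed every face")
  surface_mesh(v2, f2)
}
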