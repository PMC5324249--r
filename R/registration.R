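#' Rigid transform (rotation + translation)
#' @param rotation 3 x 3 rotation matrix (det = +1).
#' @param translation length-3 vector, mm.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be a proper orthonormal matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1))
  cat(sprintf("rigid_transform: rotation %.3f deg, translation %.3f mm\n",
              ang * 180 / pi, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to points or a mesh
#' @param x n x 3 matrix or `surface_mesh`.
#' @param transform a `rigid_transform`.
#' @return transformed object of the same type.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "surface_mesh")) {
    x$vertices <- apply_transform(x$vertices, transform)
    return(x)
  }
  x %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x), 3, byrow = TRUE)
}

#' Compose two rigid transforms (apply `first`, then `second`)
#' @param second,first `rigid_transform`s.
#' @return their composition.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.vector(second$rotation %*% first$translation) +
                    second$translation)
}

#' Least-squares rigid fit to corresponding point pairs (Kabsch)
#'
#' The proper rotation and translation minimizing the RMS distance between
#' `transform(source)` and `target`; no scaling, no reflection.
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   not collinear).
#' @return a `rigid_transform`.
#' @export
landmark_align <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) != nrow(target) || nrow(source) < 3L)
    stop("need at least 3 corresponding point pairs")
  cs <- colMeans(source)
  ct <- colMeans(target)
  ps <- sweep(source, 2, cs)
  pt <- sweep(target, 2, ct)
  sv <- svd(crossprod(ps, pt))  # H = Ps' Pt
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("point pairs are collinear; the rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

#' Iterative closest point rigid registration to a target surface
#'
#' Alternates exact closest-point-on-surface correspondences with a Kabsch
#' fit until the correspondence RMS changes by less than `tol`.
#' Correspondences farther than `reject_factor` times the median distance
#' are dropped each iteration (robustness near clipped rims).  Optional
#' seeded subsampling of the source points.
#'
#' @param source n x 3 point matrix or a `surface_mesh` (its vertices).
#' @param target a `surface_mesh`.
#' @param init initial `rigid_transform` (e.g. from [landmark_align()]).
#' @param max_iter,tol iteration cap and RMS-change tolerance (mm).
#' @param reject_factor correspondence rejection multiple (default 10).
#' @param subsample optional fraction (0,1] of source points to use.
#' @param seed seed for the subsampling.
#' @return a `rigid_transform` with attributes `rms` (final RMS, mm),
#'   `iterations`, and `rms_trace`.
#' @export
icp <- function(source, target, init = rigid_transform(), max_iter = 100L,
                tol = 1e-4, reject_factor = 10, subsample = NULL,
                seed = 1L) {
  pts <- if (inherits(source, "surface_mesh")) source$vertices else
    as.matrix(source)
  if (!is.null(subsample) && subsample < 1) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    keep <- sort(sample.int(nrow(pts), max(4L, round(subsample * nrow(pts)))))
    pts <- pts[keep, , drop = FALSE]
  }
  trans <- init
  rms_prev <- Inf
  trace <- numeric(0)
  rises <- 0L
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(pts, trans)
    hit <- .cpp_closest_on_surface(cur, target$vertices, target$faces)
    d <- hit$distance
    keep <- d <= reject_factor * max(median(d), 1e-12)
    rms <- sqrt(mean(d[keep]^2))
    trace <- c(trace, rms)
    if (rms > rms_prev + 1e-12) {
      rises <- rises + 1L
      if (rises >= 5L)
        stop("ICP diverging: RMS increased 5 consecutive iterations; ",
             "trace: ", paste(signif(tail(trace, 6), 4), collapse = " "))
    } else rises <- 0L
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
    step <- landmark_align(cur[keep, , drop = FALSE],
                           hit$closest[keep, , drop = FALSE])
    trans <- compose_transforms(step, trans)
  }
  attr(trans, "rms") <- rms
  attr(trans, "iterations") <- it
  attr(trans, "rms_trace") <- trace
  trans
}

#' Signed surface-to-surface change map
#'
#' For every vertex of the (already registered) target mesh, the minimum
#' distance to the reference surface (exact point-to-triangle), signed by
#' the outward reference normal at the closest point: positive = target
#' outside the reference = growth, negative = shrinkage.
#'
#' @param reference baseline `surface_mesh`.
#' @param target follow-up `surface_mesh`.
#' @param transform `rigid_transform` taking the target into the
#'   reference frame (identity by default).
#' @return a `change_map` tibble: vertex, change_mm, with the transformed
#'   target mesh in the `mesh` attribute.
#' @export
change_map <- function(reference, target, transform = rigid_transform()) {
  tv <- apply_transform(target$vertices, transform)
  hit <- .cpp_closest_on_surface(tv, reference$vertices, reference$faces)
  fn <- face_normals(reference)[hit$face, , drop = FALSE]
  sgn <- sign(rowSums((tv - hit$closest) * fn))
  sgn[sgn == 0] <- 1
  out <- tibble::tibble(vertex = seq_len(nrow(tv)),
                        change_mm = sgn * hit$distance)
  tmesh <- target
  tmesh$vertices <- tv
  attr(out, "mesh") <- tmesh
  attr(out, "transform") <- transform
  class(out) <- c("change_map", class(out))
  out
}

#' Save a rigid transform as a 4x4 homogeneous matrix in JSON
#' @param transform a `rigid_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m,
                            rms = attr(transform, "rms"),
                            iterations = attr(transform, "iterations")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from 4x4 homogeneous JSON
#' @param path file written by [write_transform_json()].
#' @return a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  m <- jsonlite::fromJSON(path)$matrix
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}
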