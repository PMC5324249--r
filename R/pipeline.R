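#' Run configuration for the measurement pipeline
#'
#' @param spacing station spacing, mm.
#' @param smoothing list(iterations=, factor=) for surface smoothing
#'   (iterations = 0 skips it; meshes from the phantom generator are
#'   already smooth).
#' @param pitch centerline voxel pitch, mm (NULL = automatic).
#' @param branch_windows list of c(start, end) arc spans to exclude, mm.
#' @param growth_threshold visit-to-visit change call threshold, mm.
#' @param seed integer seed.
#' @param output_dir where artifacts are written.
#' @return a `run_config` list.
#' @export
run_config <- function(spacing = 2, smoothing = list(iterations = 0,
                                                     factor = 0.5),
                       pitch = NULL, branch_windows = NULL,
                       growth_threshold = 1.5, seed = 1L,
                       output_dir = ".") {
  structure(list(spacing = spacing, smoothing = smoothing, pitch = pitch,
                 branch_windows = branch_windows,
                 growth_threshold = growth_threshold, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

load_mesh_arg <- function(mesh) {
  if (inherits(mesh, "surface_mesh")) return(mesh)
  read_stl(mesh)
}

#' Measure a vessel end to end
#'
#' Reads (or takes) a lumen mesh, optionally smooths it, extracts the
#' centerline between `source` and `target`, measures the continuous
#' diameter/area profile, the centerline geometry and the Euclidean
#' distance field, and writes CSV/JSON/PLY artifacts into the configured
#' output directory.
#'
#' @param mesh path to an STL file or a `surface_mesh`.
#' @param source,target inlet and outlet points (mm).  Defaults to the
#'   centroids of the first two boundary loops when the mesh has open
#'   rims.
#' @param config a [run_config()].
#' @param elevation_axis "up" axis for the arch apex (default +z).
#' @param write write artifact files (default TRUE when `config$output_dir`
#'   exists).
#' @return list: profile (`profile_table`), geometry
#'   (`centerline_geometry`), field (`distance_field`), centerline.
#' @export
run_measure <- function(mesh, source = NULL, target = NULL,
                        config = run_config(), elevation_axis = c(0, 0, 1),
                        write = TRUE) {
  mesh <- load_mesh_arg(mesh)
  if (config$smoothing$iterations > 0)
    mesh <- smooth_mesh(mesh, config$smoothing$iterations,
                        config$smoothing$factor)
  if (is.null(source) || is.null(target)) {
    if (length(mesh$boundary_loops) < 2L)
      stop("mesh has fewer than two open rims; supply source and target")
    rims <- mesh$boundary_loops
    source <- source %||% colMeans(mesh$vertices[rims[[1]], , drop = FALSE])
    target <- target %||% colMeans(mesh$vertices[rims[[2]], , drop = FALSE])
  }
  cl <- compute_centerline(mesh, source, target, pitch = config$pitch)
  geom <- centerline_geometry(cl, elevation_axis)
  profile <- measure_profile(mesh, cl, spacing = config$spacing,
                             branch_windows = config$branch_windows)
  field <- euclidean_field(mesh, cl)
  if (write && dir.exists(config$output_dir %||% "")) {
    od <- config$output_dir
    write.csv(as.data.frame(profile[, c("s_mm", "max_diameter_mm",
                                        "area_mm2", "excluded", "reason")]),
              file.path(od, "profile.csv"), row.names = FALSE)
    write.csv(as.data.frame(centerline_table(cl)),
              file.path(od, "centerline.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(tortuosity = geom$tortuosity,
           apex_curvature_per_mm = geom$apex_curvature,
           apex_s_mm = geom$apex_s,
           length_mm = max(cl$arc_length),
           spacing_mm = config$spacing),
      file.path(od, "geometry.json"), auto_unbox = TRUE, digits = NA)
    write_ply_scalar(mesh, field$distance_mm,
                     file.path(od, "distance_field.ply"), "euclid_mm")
  }
  list(profile = profile, geometry = geom, field = field, centerline = cl)
}

#' Visit-to-visit growth mapping
#'
#' Registers the target (follow-up) mesh to the reference with a landmark
#' fit refined by ICP, computes the signed change map, and classifies
#' per-station growth/shrinkage from the two continuous profiles.
#'
#' @param reference,target STL paths or `surface_mesh`es.
#' @param landmarks list with matrices `source` and `target` (>= 3
#'   corresponding points, target-frame first argument) or NULL to start
#'   ICP from the identity.
#' @param config a [run_config()].
#' @param measure_args extra arguments forwarded to [run_measure()] for
#'   the per-visit profiles (e.g. source/target rim points); set to NULL
#'   to skip profile classification.
#' @return list: transform, map (`change_map`), classification (tibble or
#'   NULL), icp_rms.
#' @export
run_growth <- function(reference, target, landmarks = NULL,
                       config = run_config(), measure_args = list()) {
  reference <- load_mesh_arg(reference)
  target <- load_mesh_arg(target)
  init <- if (!is.null(landmarks))
    landmark_align(landmarks$source, landmarks$target) else rigid_transform()
  trans <- icp(target$vertices, reference, init = init, seed = config$seed)
  map <- change_map(reference, target, trans)
  classification <- NULL
  if (!is.null(measure_args)) {
    ma <- utils::modifyList(list(config = run_config(
      spacing = config$spacing, pitch = config$pitch,
      branch_windows = config$branch_windows, seed = config$seed,
      output_dir = tempdir()), write = FALSE), measure_args)
    pa <- do.call(run_measure, c(list(reference), ma))
    pb <- do.call(run_measure, c(list(apply_transform(target, trans)), ma))
    aligned <- align_profiles(pa$profile, pb$profile, 0, 0)
    classification <- classify_change(pa$profile, aligned,
                                      threshold = config$growth_threshold)
  }
  if (dir.exists(config$output_dir %||% "") && config$output_dir != ".") {
    od <- config$output_dir
    write_transform_json(trans, file.path(od, "transform.json"))
    write_ply_scalar(attr(map, "mesh"), map$change_mm,
                     file.path(od, "change_map.ply"), "change_mm")
    write.csv(as.data.frame(map), file.path(od, "change_map.csv"),
              row.names = FALSE)
    if (!is.null(classification))
      write.csv(as.data.frame(classification),
                file.path(od, "growth_classification.csv"),
                row.names = FALSE)
  }
  list(transform = trans, map = map, classification = classification,
       icp_rms = attr(trans, "rms"))
}
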