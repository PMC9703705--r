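## Pipeline entry points: thin orchestration over the segmentation and
## trait modules, writing PLY/CSV artifacts plus a machine-readable
## provenance record. Reruns on identical inputs reproduce identical
## files (no timestamps in outputs).

.provenance <- function(input, config) {
  list(package = "panicle3d",
       version = as.character(utils::packageVersion("panicle3d")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       input = basename(input),
       input_md5 = unname(tools::md5sum(input)),
       config = config)
}

.write_provenance <- function(prov, path) {
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Segment a panicle cloud from a PLY file
#'
#' Reads a raw reconstruction, runs VARI + connected-component
#' segmentation, and writes the segmented panicle as PLY together with
#' a cluster report CSV and a provenance JSON (configuration, package
#' version, input checksum).
#'
#' @param input path to the input PLY.
#' @param output_dir directory for outputs (created if missing).
#' @param voxel_size clustering resolution; `NULL` for the adaptive
#'   default (`2 x` median nearest-neighbour spacing).
#' @param vari_threshold greenness cutoff for panicle selection
#'   (default 0.1).
#' @param units_per_cm optional metric scale attached to the cloud.
#' @return Invisibly, a list with the `segmentation` result and the
#'   output `paths`.
#' @export
run_segment <- function(input, output_dir, voxel_size = NULL,
                        vari_threshold = 0.1, units_per_cm = NULL) {
  cloud <- read_ply(input, units_per_cm = units_per_cm)
  message(sprintf("read %d points from %s", n_points(cloud), input))
  seg <- segment_panicle(cloud, voxel_size = voxel_size,
                         vari_threshold = vari_threshold)
  message(sprintf("selected cluster %d: %d of %d points",
                  attr(seg$cloud, "label"), n_points(seg$cloud),
                  n_points(cloud)))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sub("\\.ply$", "", basename(input), ignore.case = TRUE)
  paths <- list(
    ply = file.path(output_dir, paste0(stem, "_segmented.ply")),
    report = file.path(output_dir, paste0(stem, "_clusters.csv")),
    provenance = file.path(output_dir, paste0(stem, "_segment_provenance.json")))
  write_ply(seg$cloud, paths$ply)
  write.csv(seg$report, paths$report, row.names = FALSE)
  config <- list(voxel_size = if (is.null(voxel_size)) "auto"
                 else voxel_size,
                 voxel_size_used = seg$labels$voxel_size,
                 vari_threshold = vari_threshold,
                 units_per_cm = units_per_cm,
                 n_points_in = n_points(cloud),
                 n_points_out = n_points(seg$cloud))
  .write_provenance(.provenance(input, config), paths$provenance)
  invisible(list(segmentation = seg, paths = paths))
}

#' Extract digital traits from a segmented PLY
#'
#' Reads a segmented panicle cloud and writes three CSV artifacts —
#' whole-panicle traits (one row), the projection-sweep profile
#' (angle, area) and the slice profile — plus a provenance JSON.
#'
#' @inheritParams run_segment
#' @param step_deg sweep angular step (default 5, i.e. 36 areas).
#' @param n_slices number of axial slices (default 10).
#' @param method boundary method for projected areas.
#' @param color_mode color-proportion mode.
#' @param up_hint capture-rig vertical.
#' @return Invisibly, a list with `traits`, `slices` and the output
#'   `paths`.
#' @export
run_traits <- function(input, output_dir, voxel_size = NULL,
                       step_deg = 5, n_slices = 10,
                       method = c("alpha_shape", "convex_hull",
                                  "raster"),
                       color_mode = c("intensity", "classify"),
                       up_hint = c(0, 0, 1), units_per_cm = NULL) {
  method <- match.arg(method)
  color_mode <- match.arg(color_mode)
  cloud <- read_ply(input, units_per_cm = units_per_cm)
  message(sprintf("read %d points from %s", n_points(cloud), input))
  tr <- extract_traits(cloud, voxel_size = voxel_size,
                       step_deg = step_deg, method = method,
                       up_hint = up_hint, color_mode = color_mode)
  sl <- slice_cloud(cloud, frame = tr$frame, n_slices = n_slices,
                    voxel_size = voxel_size, color_mode = color_mode)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sub("\\.ply$", "", basename(input), ignore.case = TRUE)
  paths <- list(
    traits = file.path(output_dir, paste0(stem, "_traits.csv")),
    sweep = file.path(output_dir, paste0(stem, "_sweep.csv")),
    slices = file.path(output_dir, paste0(stem, "_slices.csv")),
    provenance = file.path(output_dir, paste0(stem, "_traits_provenance.json")))
  tr_row <- cbind(data.frame(id = stem), summary(tr))
  write.csv(tr_row, paths$traits, row.names = FALSE)
  write.csv(data.frame(angle = tr$sweep$angles, area = tr$sweep$areas),
            paths$sweep, row.names = FALSE)
  sl_out <- cbind(data.frame(id = stem),
                  as.data.frame(sl)[c("slice", "point_count",
                                      "voxel_count", "green_prop",
                                      "red_prop")])
  write.csv(sl_out, paths$slices, row.names = FALSE)
  config <- list(step_deg = step_deg, n_slices = n_slices,
                 method = method, color_mode = color_mode,
                 voxel_size = if (is.null(voxel_size)) "auto"
                 else voxel_size,
                 voxel_size_used = tr$voxel_size,
                 units_per_cm = units_per_cm,
                 up_hint = up_hint)
  .write_provenance(.provenance(input, config), paths$provenance)
  invisible(list(traits = tr, slices = sl, paths = paths))
}
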