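# On-disk formats: acquisition series as 4D NIfTI-1 volumes with a JSON
# timing sidecar; quantitative maps as one NIfTI per map; run
# configurations as flat YAML. Voxel data round-trip bit-exactly (float64
# NIfTI), timing lists exactly.

series_paths <- function(prefix) {
  c(nifti = paste0(prefix, ".nii.gz"), sidecar = paste0(prefix, ".json"))
}

#' Write / read an acquisition series
#'
#' `write_series()` stores the volume stack as a 4D NIfTI-1 file
#' (`<prefix>.nii.gz`, float64, with the in-plane voxel size and the slice
#' spacing in `pixdim`) plus a JSON sidecar (`<prefix>.json`) holding the
#' timing list, mode, TR and TE. `read_series()` reverses this; a missing
#' sidecar or a timing/volume count mismatch is an error.
#'
#' @param series A 4D [acquisition_series].
#' @param prefix Path prefix (no extension).
#' @param voxdim Voxel dimensions in mm written to the NIfTI header.
#' @return `write_series()`: the two paths, invisibly. `read_series()`: an
#'   [acquisition_series].
#' @export
write_series <- function(series, prefix, voxdim = c(1.25, 1.25, 6)) {
  if (!inherits(series, "acquisition_series") ||
      length(dim(series$data)) != 4L)
    stop_synthmri("`series` must hold a 4D volume stack", "invalid_series")
  p <- series_paths(prefix)
  img <- RNifti::asNifti(series$data,
                         pixdim = c(voxdim, 1),
                         datatype = "double")
  RNifti::writeNifti(img, p[["nifti"]])
  jsonlite::write_json(
    list(mode = series$mode, tr_ms = series$tr, te_ms = series$te,
         timings_ms = series$timings,
         slice_thickness_mm = 5, slice_gap_mm = voxdim[3] - 5),
    p[["sidecar"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  p <- series_paths(prefix)
  if (!file.exists(p[["nifti"]]))
    stop_synthmri(paste0("series volume file not found: ", p[["nifti"]]),
                  "missing_file")
  if (!file.exists(p[["sidecar"]]))
    stop_synthmri(paste0("timing sidecar not found: ", p[["sidecar"]]),
                  "missing_file")
  img <- RNifti::readNifti(p[["nifti"]])
  data <- array(as.numeric(img), dim(img))
  meta <- jsonlite::read_json(p[["sidecar"]], simplifyVector = TRUE)
  timings <- as.numeric(meta$timings_ms)
  nd <- dim(data)
  if (length(nd) != 4L || nd[4] != length(timings))
    stop_synthmri(sprintf(
      "sidecar lists %d timings but series holds %d volumes",
      length(timings), if (length(nd) == 4L) nd[4] else NA_integer_),
      "series_mismatch")
  acquisition_series(data, timings, mode = meta$mode,
                     tr = as.numeric(meta$tr_ms), te = as.numeric(meta$te_ms))
}

#' Write quantitative maps as NIfTI volumes
#'
#' Emits `<prefix>_pd.nii.gz`, `<prefix>_t1.nii.gz`, `<prefix>_t2.nii.gz`
#' and `<prefix>_label.nii.gz` with the maps' voxel dimensions.
#'
#' @param maps A [quant_maps].
#' @param prefix Path prefix.
#' @return Invisibly, the written paths.
#' @export
write_quant_maps <- function(maps, prefix) {
  if (!inherits(maps, "quant_maps"))
    stop_synthmri("`maps` must be a quant_maps object", "invalid_maps")
  paths <- character(0)
  for (nm in c("pd", "t1", "t2", "label")) {
    p <- sprintf("%s_%s.nii.gz", prefix, nm)
    img <- RNifti::asNifti(maps[[nm]] + 0, pixdim = maps$voxdim,
                           datatype = "double")
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run configuration
#'
#' Flat configuration for the two experiment drivers. A seed is mandatory:
#' every stochastic stage derives its stream from it.
#'
#' @param experiment `"phantom_validation"` or `"brain_cnr"`.
#' @param seed Integer RNG seed (mandatory).
#' @param output_dir Directory reports are written to.
#' @param noise_sigma Rician channel noise sd, a.u.
#' @param ... Experiment-specific fields (see [run_phantom_validation()]
#'   and [run_brain_experiment()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = c("phantom_validation", "brain_cnr"),
                       seed, output_dir = tempfile("synthmri_"),
                       noise_sigma = 0.01, ...) {
  experiment <- match.arg(experiment)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    stop_synthmri("`seed` is mandatory and must be a single integer",
                  "invalid_config")
  structure(list(experiment = experiment, seed = as.integer(seed),
                 output_dir = output_dir, noise_sigma = noise_sigma, ...),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' @param path YAML file with at least `experiment` and `seed` keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_synthmri(paste0("config file not found: ", path), "missing_file")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment) || is.null(cfg$seed))
    stop_synthmri("config must define `experiment` and `seed`",
                  "invalid_config")
  do.call(run_config, cfg)
}

# Provenance record sufficient to re-run byte-identically: resolved config,
# its hash, and the package version. No timestamps, so identical runs give
# identical files.
write_provenance <- function(config, dir) {
  cfg_path <- file.path(dir, "config.json")
  plain <- config[!vapply(config, is.function, logical(1))]
  jsonlite::write_json(plain, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfg_path)),
         seed = config$seed,
         package = "synthmri",
         version = as.character(packageVersion("synthmri"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg_path)
}
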