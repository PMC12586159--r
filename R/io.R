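#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return list with `data` (numeric array), `affine` (4 x 4 voxel-to-world
#'   matrix) and `descrip` (header description string).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error reading '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  hdr <- RNifti::niftiHeader(img)
  aff <- rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  list(data = a, affine = aff, descrip = hdr$descrip)
}

#' Write a NIfTI-1 volume
#'
#' Data are stored as float64 so round-trips are bit-exact. The affine is a
#' diagonal RAS matrix built from `voxel_size` unless given explicitly.
#'
#' @param data numeric array (3D, or 4D e.g. a 6-component tensor volume).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size isotropic voxel size in mm.
#' @param affine optional 4 x 4 affine overriding `voxel_size`.
#' @param descrip header description string (e.g. the tensor component
#'   order).
#' @return the path, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = 1, affine = NULL,
                         descrip = "") {
  img <- RNifti::asNifti(data, datatype = "double")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img$descrip <- substr(descrip, 1, 79)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a ground-truth tensor volume
#'
#' Stores the 6 components as a 4D NIfTI with the component order recorded
#' in the header description.
#'
#' @param tensor array `(x, y, z, 6)`.
#' @param path output path.
#' @param voxel_size mm.
#' @export
write_tensor_volume <- function(tensor, path, voxel_size = 1) {
  stopifnot(length(dim(tensor)) == 4, dim(tensor)[4] == 6)
  write_volume(tensor, path, voxel_size,
               descrip = "tensor components: Dxx,Dxy,Dxz,Dyy,Dyz,Dzz")
}

#' Physiological trace TSV I/O
#'
#' Traces are stored as 2-column tab-separated files (`time_s`,
#' `amplitude`), one file per channel.
#'
#' @param time,amplitude numeric vectors.
#' @param path file path.
#' @return the path (write) / data frame (read).
#' @export
write_trace_tsv <- function(time, amplitude, path) {
  utils::write.table(data.frame(time_s = time, amplitude = amplitude),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Export a shot schedule as a profile TSV
#'
#' Columns: `shot`, `ky`, `kz`, `t_s` (shot start time).
#'
#' @param schedule a [make_shot_schedule()] result.
#' @param path file path.
#' @export
write_profile_tsv <- function(schedule, path) {
  rows <- do.call(rbind, lapply(seq_along(schedule$shots), function(k) {
    sh <- schedule$shots[[k]]
    pr <- schedule$profiles[sh$profile_indices, , drop = FALSE]
    data.frame(shot = k, ky = pr[, 1], kz = pr[, 2], t_s = sh$start_time)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()] object.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
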