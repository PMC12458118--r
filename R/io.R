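#' Write a multi-echo volume as NIfTI plus an echo-time sidecar
#'
#' The 4D signal goes to \code{<prefix>.nii.gz} (echoes on the 4th axis)
#' and the echo times (ms, one per line) to \code{<prefix>_echoes.txt}.
#'
#' @param vol a \code{multi_echo_volume}.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_multi_echo <- function(vol, prefix) {
  stopifnot(inherits(vol, "multi_echo_volume"))
  nii <- RNifti::asNifti(vol$signal)
  RNifti::pixdim(nii) <- c(vol$voxel_size, 1)
  img_path <- paste0(prefix, ".nii.gz")
  te_path <- paste0(prefix, "_echoes.txt")
  RNifti::writeNifti(nii, img_path)
  writeLines(format(vol$echo_times, trim = TRUE), te_path)
  invisible(c(image = img_path, echoes = te_path))
}

#' Read a multi-echo volume from NIfTI plus an echo-time sidecar
#'
#' @param image_path 4D NIfTI file.
#' @param echoes_path text file with one echo time (ms) per line.
#' @return A \code{multi_echo_volume}.
#' @export
read_multi_echo <- function(image_path, echoes_path) {
  nii <- RNifti::readNifti(image_path)
  te <- as.numeric(readLines(echoes_path))
  vox <- RNifti::pixdim(nii)[1:3]
  multi_echo_volume(array(as.numeric(nii), dim = dim(nii)), te, vox)
}

#' Write a 3D volume (map, mask, or labels) as NIfTI
#'
#' @param arr 3D array (logical masks are written as 0/1 integers).
#' @param voxel_size mm per axis.
#' @param path output file (.nii or .nii.gz).
#' @param datatype NIfTI datatype, e.g. \code{"uint8"} for labels/masks or
#'   \code{"double"} for parametric maps.
#' @return Invisibly, \code{path}.
#' @export
write_volume <- function(arr, voxel_size, path, datatype = "double") {
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- voxel_size
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

#' Read a 3D NIfTI volume
#'
#' @param path NIfTI file.
#' @param as_mask coerce to logical (nonzero = TRUE).
#' @return List: \code{data} (3D array), \code{voxel_size}.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  if (as_mask) arr <- array(arr != 0, dim = dim(arr))
  list(data = arr, voxel_size = RNifti::pixdim(nii)[1:3])
}

#' Write a field trace as CSV with metadata header
#'
#' Header lines (\code{# key: value}) carry the sampling rate, stimulus
#' current and stimulus time(s); the body has columns \code{time_ms},
#' \code{voltage_mv}.
#'
#' @param trace a \code{field_trace}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "field_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate: %.10g", trace$sampling_rate),
    sprintf("# stim_current_ua: %.10g", trace$stim_current_ua),
    sprintf("# stim_times_ms: %s",
            paste(format(trace$stim_times_ms, trim = TRUE),
                  collapse = " "))), con)
  utils::write.csv(data.frame(time_ms = trace$time_ms,
                              voltage_mv = trace$voltage_mv),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a field trace written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A \code{field_trace}.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(paste0("^# ", key), hdr, value = TRUE)[1L])
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  new_field_trace(body$time_ms, body$voltage_mv,
                  as.numeric(get("sampling_rate")),
                  as.numeric(strsplit(get("stim_times_ms"), " ")[[1L]]),
                  as.numeric(get("stim_current_ua")))
}

#' Write a T2 map as a set of NIfTI files
#'
#' Writes \code{t2.nii.gz}, \code{s0.nii.gz}, \code{r2.nii.gz},
#' \code{valid.nii.gz} into a directory.
#'
#' @param map a \code{t2_map}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_t2_map <- function(map, dir) {
  stopifnot(inherits(map, "t2_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(t2 = file.path(dir, "t2.nii.gz"),
             s0 = file.path(dir, "s0.nii.gz"),
             r2 = file.path(dir, "r2.nii.gz"),
             valid = file.path(dir, "valid.nii.gz"))
  fill0 <- function(a) { a[!is.finite(a)] <- 0; a }
  write_volume(fill0(map$t2), map$voxel_size, paths["t2"])
  write_volume(fill0(map$s0), map$voxel_size, paths["s0"])
  write_volume(fill0(map$r2), map$voxel_size, paths["r2"])
  write_volume(map$valid, map$voxel_size, paths["valid"], "uint8")
  invisible(paths)
}

#' Write tissue labels as NIfTI with a legend sidecar
#'
#' @param labels a \code{tissue_labels}.
#' @param path output NIfTI path; a JSON legend is written alongside as
#'   \code{<path>.json}.
#' @return Invisibly, \code{path}.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "tissue_labels"))
  write_volume(labels$labels, labels$voxel_size, path, "uint8")
  legend <- list(`0` = "outside", `1` = "uninjured", `2` = "penumbra",
                 `3` = "core")
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
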