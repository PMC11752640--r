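#' Read a NIfTI volume as a plain array
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return Numeric array; voxel dimensions (mm) in attribute `voxel_size_mm`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  arr
}

#' Write an array as NIfTI
#'
#' @param x 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel dimensions in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, voxel_size_mm = c(1.7, 1.7, 4)) {
  x <- array(as.numeric(x), dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(voxel_size_mm,
                           rep(1, length(dim(x)) - 3))[seq_along(dim(x))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write metric maps as one NIfTI file per metric
#'
#' @param maps Named list of 3D maps (e.g. from [metric_maps()]).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @param voxel_size_mm Voxel dimensions in mm.
#' @return Named character vector of paths, invisibly.
#' @export
write_metric_maps <- function(maps, dir, prefix = "", voxel_size_mm = c(1.7, 1.7, 4)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps), function(m) {
    p <- file.path(dir, paste0(prefix, m, ".nii.gz"))
    write_nifti_volume(maps[[m]], p, voxel_size_mm)
    p
  }, character(1))
  invisible(paths)
}
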