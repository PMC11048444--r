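#' Extract a voxel-by-time matrix from a 4D NIfTI volume under a mask
#'
#' Entry point for real data: flattens the masked voxels of a 4D volume
#' into a V x T matrix whose rows follow the x-fastest (column-major) linear
#' order of the mask. The returned index allows spatial maps computed on
#' the matrix to be re-embedded into the mask's grid.
#'
#' @param volume_path path to a 4D NIfTI file.
#' @param mask_path path to a 3D NIfTI mask on the same grid (nonzero =
#'   included).
#' @returns List with `data` (V x T matrix), `index` (linear voxel indices
#'   into the 3D grid), `dim` (3D grid dimensions), and `mask_path`.
#' @export
load_nifti_masked <- function(volume_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_("NIfTI support requires the 'RNifti' package")
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  dv <- dim(vol)
  dm <- dim(msk)
  if (length(dv) != 4L) stop_("`volume_path` must hold a 4D volume")
  if (length(dm) != 3L || !all(dv[1:3] == dm))
    stop_(sprintf("grid mismatch: volume %s vs mask %s",
                  paste(dv[1:3], collapse = "x"), paste(dm, collapse = "x")))
  index <- which(as.array(msk) != 0)
  if (!length(index)) stop_("mask selects no voxels")
  nt <- dv[4]
  mat <- matrix(as.numeric(vol), prod(dv[1:3]), nt)[index, , drop = FALSE]
  list(data = mat, index = index, dim = dv[1:3], mask_path = mask_path)
}

#' Re-embed a voxelwise map into the mask's 3D grid
#'
#' @param map numeric vector with one value per masked voxel.
#' @param masked the list returned by [load_nifti_masked()].
#' @param file optional output path; when given the map is written as a 3D
#'   NIfTI volume (requires \pkg{RNifti}).
#' @param fill value outside the mask.
#' @returns The 3D array (invisibly when written to `file`).
#' @export
embed_map <- function(map, masked, file = NULL, fill = 0) {
  if (length(map) != length(masked$index))
    stop_("`map` length does not match the number of masked voxels")
  arr <- array(fill, dim = masked$dim)
  arr[masked$index] <- map
  if (!is.null(file)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop_("writing NIfTI requires the 'RNifti' package")
    RNifti::writeNifti(RNifti::asNifti(arr), file)
    return(invisible(arr))
  }
  arr
}
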