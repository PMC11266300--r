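#' Read a scalar volume from NIfTI
#'
#' Voxel spacing is taken from the diagonal of the header affine; files
#' whose affine encodes rotation or shear beyond axis scaling are rejected
#' (the pipeline works in scanner-axis-aligned grids).
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return A [VoxelVolume-class].
#' @export
readVolumeNifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  offdiag <- lin
  diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(lin))))
    stop("NIfTI affine encodes rotation/shear beyond axis scaling; ",
         "resample the volume to an axis-aligned grid first")
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions")
  voxelVolume(arr, spacing = abs(diag(lin)), origin = aff[1:3, 4])
}

#' Write a binary mask as NIfTI (uint8)
#'
#' @param mask a [BinaryMask-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeMaskNifti <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  arr <- array(as.integer(mask@data), dim(mask@data))
  img <- RNifti::asNifti(arr, pixdim = mask@spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
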