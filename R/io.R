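# NIfTI and text I/O. Volumes are assumed axis-aligned RAS; only the voxel
# dimensions of the NIfTI header are used for world coordinates.

#' Read / write spine volumes as NIfTI-1
#'
#' @param path file path (.nii or .nii.gz).
#' @param polarity contrast polarity tag to attach on read.
#' @param v a \linkS4class{SpineVolume}.
#' @return \code{readVolume}: a \linkS4class{SpineVolume};
#'   \code{writeVolume}: invisibly, the path.
#' @export
readVolume <- function(path, polarity = "t2_like") {
  if (!file.exists(path)) stop("volume file not found: ", path)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L) stop("expected a 3D volume: ", path)
    nii <- array(nii, dim = d[1:3])
  }
  vx <- RNifti::pixdim(nii)[1:3]
  new("SpineVolume", imageData = array(as.numeric(nii), dim = dim(nii)[1:3]),
      voxelMm = as.numeric(vx), polarity = polarity)
}

#' @rdname readVolume
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "SpineVolume"))
  nii <- RNifti::asNifti(v@imageData)
  RNifti::pixdim(nii) <- v@voxelMm
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read / write centerlines
#'
#' A centerline on disk is either a whitespace-delimited text file with one
#' "x y z" point per line (mm, rostral first) or a binary NIfTI mask from
#' which the per-slice centroid curve is extracted with
#' \code{\link{centerlineFromMask}}.
#'
#' @param path file path (.txt/.csv for points, .nii/.nii.gz for a mask).
#' @param cl a \linkS4class{Centerline}.
#' @return \code{readCenterline}: a \linkS4class{Centerline}.
#' @export
readCenterline <- function(path) {
  if (!file.exists(path)) stop("centerline file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path))
    return(centerlineFromMask(readVolume(path)))
  pts <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(pts) != 3L) stop("centerline text file must have 3 columns (x y z)")
  newCenterline(pts, stepMm = 1)
}

#' @rdname readCenterline
#' @export
writeCenterline <- function(cl, path) {
  utils::write.table(format(cl@coords, digits = 8, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
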