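#' Construct a 4-D volume series
#'
#' Bundles the 4-D signal array (x, y, z, measurement) with its voxel size
#' and acquisition protocol. The 4th-dimension order must follow the
#' protocol's row order; this is validated on construction.
#'
#' @param data 4-D numeric array; non-negative magnitudes.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param protocol An [acquisition_protocol()].
#' @param scan_id Character identifier.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size, protocol, scan_id = "scan") {
  if (length(dim(data)) != 4) {
    stop("data must be a 4-D array (x, y, z, measurement)", call. = FALSE)
  }
  if (dim(data)[4] != n_measurements(protocol)) {
    stop(sprintf(
      "4th dimension (%d) does not match protocol measurement count (%d)",
      dim(data)[4], n_measurements(protocol)), call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("volume data contains non-finite values", call. = FALSE)
  }
  if (any(data < 0)) {
    stop("volume data must be non-negative (magnitude images)", call. = FALSE)
  }
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be 1 or 3 positive values (mm)", call. = FALSE)
  }
  structure(list(data = data, voxel_size = voxel_size, protocol = protocol,
                 scan_id = scan_id),
            class = "volume_series")
}

#' Construct a region-of-interest mask
#'
#' The ROI covers the whole placenta plus the adjacent uterine-wall section.
#' Any nonzero voxel is treated as inside (tolerant of 0/1 and 0/255 mask
#' dialects).
#'
#' @param data 3-D array; nonzero marks ROI voxels.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @return An object of class `roi_mask` (logical 3-D array + voxel size).
#' @export
roi_mask <- function(data, voxel_size) {
  if (length(dim(data)) != 3) stop("mask must be a 3-D array", call. = FALSE)
  m <- array(data != 0, dim = dim(data))
  if (!any(m)) stop("mask is empty", call. = FALSE)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(data = m, voxel_size = voxel_size,
                 label = "placenta_and_uterine_wall"),
            class = "roi_mask")
}

check_mask_matches <- function(series, mask) {
  if (!all(dim(series$data)[1:3] == dim(mask$data))) {
    stop("mask spatial shape does not match the volume series", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a volume series to NIfTI plus a protocol sidecar
#'
#' NIfTI-1 carries no (TE, b) metadata, so the measurement order is stored
#' as a sidecar CSV protocol table next to the volume.
#'
#' @param series A [volume_series()].
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param protocol_path Sidecar CSV path; defaults to `path` with the NIfTI
#'   extension replaced by `_protocol.csv`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, protocol_path = NULL) {
  if (is.null(protocol_path)) protocol_path <- sidecar_path(path)
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, 1)
  RNifti::writeNifti(img, path)
  write_protocol(series$protocol, protocol_path)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_protocol.csv", path)
}

#' Read a volume series from NIfTI plus its protocol sidecar
#'
#' Fails loudly when the 4th dimension does not match the protocol row
#' count, or when the data are not valid magnitudes.
#'
#' @param volume_path NIfTI file.
#' @param protocol_path Protocol CSV; defaults to the sidecar convention of
#'   [write_series()].
#' @param scan_id Identifier; defaults to the file name.
#' @return A [volume_series()].
#' @export
read_series <- function(volume_path, protocol_path = NULL, scan_id = NULL) {
  if (!file.exists(volume_path)) {
    stop("volume file not found: ", volume_path, call. = FALSE)
  }
  if (is.null(protocol_path)) protocol_path <- sidecar_path(volume_path)
  protocol <- read_protocol(protocol_path)
  img <- RNifti::readNifti(volume_path)
  vox <- RNifti::pixdim(img)[1:3]
  if (is.null(scan_id)) {
    scan_id <- sub("\\.nii(\\.gz)?$", "", basename(volume_path))
  }
  volume_series(array(as.numeric(img), dim = dim(img)), vox, protocol, scan_id)
}

#' Write an ROI mask as NIfTI
#' @param mask A [roi_mask()].
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(img) <- mask$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI mask from NIfTI
#' @param path NIfTI file with nonzero values marking the ROI.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img)[1:3])
}

#' ROI volume in mm^3
#'
#' @param mask A [roi_mask()] (or logical 3-D array if `voxel_size` given).
#' @param voxel_size Optional override of the mask's voxel size, mm.
#' @return Volume in mm^3: voxel count times voxel volume.
#' @export
roi_volume <- function(mask, voxel_size = NULL) {
  if (is.array(mask)) {
    if (is.null(voxel_size)) {
      stop("voxel_size required when mask is a bare array", call. = FALSE)
    }
    mask <- roi_mask(mask, voxel_size)
  }
  vs <- voxel_size %||% mask$voxel_size
  if (length(vs) == 1) vs <- rep(vs, 3)
  n <- sum(mask$data)
  if (n == 0) stop("mask is empty", call. = FALSE)
  n * prod(vs)
}

#' Extract the reference volume of a series
#'
#' Returns the 3-D volume of the first b = 0 measurement at the shortest
#' echo time — the image on which the ROI is drawn and the proton-density
#' reference of the signal model.
#'
#' @param series A [volume_series()].
#' @return 3-D numeric array.
#' @export
reference_volume <- function(series) {
  idx <- reference_index(series$protocol)
  series$data[, , , idx, drop = TRUE]
}
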