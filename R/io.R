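#' Read and write label volumes as NIfTI-1
#'
#' Label grids are written as integer NIfTI-1 (.nii or .nii.gz) with the
#' voxel size in the header; the label-code table, head center and
#' generator provenance type go to a sidecar JSON next to the image
#' (same path with a .json extension). The world affine is the identity
#' scaled by the voxel size (phantom coordinates are voxel indices).
#'
#' @param vol a \code{\linkS4class{LabelVolume}}
#' @param path output .nii / .nii.gz path
#' @return \code{writeLabelVolume}: \code{path} invisibly;
#'   \code{readLabelVolume}: a \code{\linkS4class{LabelVolume}}.
#' @export
writeLabelVolume <- function(vol, path) {
  arr <- vol@labels
  attr(arr, "pixdim") <- rep(vol@voxelSize, 3)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  side <- list(label_codes = as.list(vol@labelCodes),
               voxel_mm = vol@voxelSize,
               center_mm = vol@center,
               dim = dim(vol@labels),
               provenance_type = vol@provenance$type)
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname writeLabelVolume
#' @param path input .nii / .nii.gz path (sidecar JSON expected alongside)
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sc <- sidecarPath(path)
  if (!file.exists(sc))
    stop("missing sidecar JSON for ", path, ": ", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("label_codes", "voxel_mm", "center_mm", "dim"))
    if (is.null(side[[key]]))
      stop("sidecar ", sc, " is missing required key '", key, "'")
  lab <- array(as.integer(img), dim(img))
  if (!all(dim(lab) == side$dim))
    stop("shape mismatch between ", path, " (",
         paste(dim(lab), collapse = "x"), ") and sidecar (",
         paste(side$dim, collapse = "x"), ")")
  codes <- unlist(side$label_codes)
  storage.mode(codes) <- "integer"
  pd <- RNifti::pixdim(img)
  vs <- side$voxel_mm
  if (length(pd) >= 1 && abs(pd[1] - vs) > 1e-6)
    warning("voxel size differs between NIfTI header and sidecar; ",
            "using the sidecar value")
  new("LabelVolume", labels = lab, voxelSize = vs,
      labelCodes = codes, center = as.numeric(side$center_mm),
      provenance = list(type = side$provenance_type))
}

#' Read and write scalar fields as NIfTI-1
#'
#' Float NIfTI aligned to the head grid; the units string is carried in
#' both the NIfTI description header and a sidecar JSON.
#'
#' @param field a \code{\linkS4class{PotentialField}}, an
#'   \code{\linkS4class{EFieldVolume}} (its magnitude is written) or a 3-D
#'   array
#' @param path output .nii / .nii.gz path
#' @param voxelSize voxel size (mm); taken from \code{field} when it
#'   carries one
#' @param units units string stored with the image ("V" or "V/m")
#' @return \code{writeField}: \code{path} invisibly; \code{readField}: a
#'   list with \code{values} (3-D array), \code{voxelSize} and
#'   \code{units}.
#' @export
writeField <- function(field, path, voxelSize = NULL, units = "V/m") {
  vol <- if (is(field, "PotentialField")) field@V
  else if (is(field, "EFieldVolume")) field@magnitude
  else field
  if (is.null(voxelSize)) {
    voxelSize <- if (is(field, "PotentialField") ||
                     is(field, "EFieldVolume")) field@voxelSize
    else stop("voxelSize required for a bare array")
  }
  if (is(field, "PotentialField") && missing(units)) units <- "V"
  arr <- vol
  attr(arr, "pixdim") <- rep(voxelSize, 3)
  img <- RNifti::asNifti(arr, datatype = "double")
  hdr <- RNifti::niftiHeader(img)
  hdr$descrip <- units
  img <- RNifti::asNifti(arr, reference = hdr)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(units = units, voxel_mm = voxelSize),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeField
#' @export
readField <- function(path) {
  img <- RNifti::readNifti(path)
  sc <- sidecarPath(path)
  units <- NA_character_
  vs <- RNifti::pixdim(img)[1]
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    units <- side$units
    vs <- side$voxel_mm
  } else {
    units <- RNifti::niftiHeader(img)$descrip
  }
  list(values = array(as.numeric(img), dim(img)), voxelSize = vs,
       units = units)
}

#' Export a solve report as JSON
#'
#' Writes iterations, final relative residual, tolerance, per-electrode
#' currents, conservation error and the residual history.
#'
#' @param report a \code{\linkS4class{SolveReport}}
#' @param path output .json path
#' @return \code{path}, invisibly.
#' @export
writeSolveReport <- function(report, path) {
  jsonlite::write_json(list(
    iterations = report@iterations,
    final_relative_residual = report@finalRelResidual,
    tolerance = report@tolerance,
    converged = report@converged,
    per_electrode_current_A = as.list(report@perElectrodeCurrent),
    conservation_error_A = report@conservationError,
    residual_history = report@residualHistory),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a cortical map as CSV
#'
#' Writes x, y, z (voxel indices), the outward normal, |E| and the signed
#' normal component (positive = inward current).
#'
#' @param cmap a \code{\linkS4class{CorticalMap}}
#' @param path output .csv path
#' @return \code{path}, invisibly.
#' @export
writeCorticalMap <- function(cmap, path) {
  df <- data.frame(
    x = cmap@surface@coords[, 1], y = cmap@surface@coords[, 2],
    z = cmap@surface@coords[, 3],
    nx = cmap@surface@normals[, 1], ny = cmap@surface@normals[, 2],
    nz = cmap@surface@normals[, 3],
    ef_magnitude = cmap@efMagnitude, ef_normal = cmap@efNormal)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
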