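#' @rdname LabelVolume-class
#' @param object,x an object
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))

#' @rdname LabelVolume-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname LabelVolume-class
#' @export
setGeneric("headCenter", function(x) standardGeneric("headCenter"))

#' @rdname ConductivityTable-class
#' @param x a \code{ConductivityTable}
#' @param label tissue/material label name(s)
#' @export
setGeneric("sigmaOf", function(x, label) standardGeneric("sigmaOf"))

#' @rdname Montage-class
#' @param x a \code{Montage} or \code{RasterizedHead}
#' @export
setGeneric("electrodes", function(x) standardGeneric("electrodes"))

#' @rdname Montage-class
#' @export
setGeneric("totalCurrent", function(x) standardGeneric("totalCurrent"))

#' @rdname PotentialField-class
#' @param x a \code{PotentialField}
#' @export
setGeneric("potential", function(x) standardGeneric("potential"))

#' @rdname EFieldVolume-class
#' @param x an \code{EFieldVolume}
#' @export
setGeneric("fieldMagnitude", function(x) standardGeneric("fieldMagnitude"))

setMethod("labels3d", "LabelVolume", function(x) x@labels)
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)
setMethod("voxelSize", "PotentialField", function(x) x@voxelSize)
setMethod("voxelSize", "EFieldVolume", function(x) x@voxelSize)
setMethod("headCenter", "LabelVolume", function(x) x@center)
setMethod("headCenter", "PotentialField", function(x) x@center)
setMethod("headCenter", "EFieldVolume", function(x) x@center)

setMethod("sigmaOf", "ConductivityTable", function(x, label) {
  miss <- setdiff(label, names(x@sigma))
  if (length(miss))
    stop("no conductivity for label(s): ", paste(miss, collapse = ", "))
  unname(x@sigma[label])
})

setMethod("electrodes", "Montage", function(x) x@electrodes)
setMethod("electrodes", "RasterizedHead", function(x) x@montage@electrodes)
setMethod("totalCurrent", "Montage", function(x) x@totalCurrent)
setMethod("totalCurrent", "RasterizedHead", function(x) x@montage@totalCurrent)
setMethod("potential", "PotentialField", function(x) x@V)
setMethod("fieldMagnitude", "EFieldVolume", function(x) x@magnitude)

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("%s: %d x %d x %d voxels at %.3g mm\n", class(object),
              d[1], d[2], d[3], object@voxelSize))
  tab <- table(factor(as.vector(object@labels),
                      levels = object@labelCodes,
                      labels = names(object@labelCodes)))
  tab <- tab[tab > 0]
  cat("  voxels per label:\n")
  for (nm in names(tab))
    cat(sprintf("    %-10s %d\n", nm, as.integer(tab[nm])))
  invisible(object)
})

setMethod("show", "ConductivityTable", function(object) {
  cat("ConductivityTable (S/m):\n")
  for (nm in names(object@sigma))
    cat(sprintf("  %-10s %g\n", nm, object@sigma[nm]))
  invisible(object)
})

setMethod("show", "Electrode", function(object) {
  sz <- if (object@shape == "pad")
    sprintf("%g x %g mm", object@size[1], object@size[2])
  else sprintf("diameter %g mm", object@size[1])
  cat(sprintf("Electrode: %s %s (%s), contact %s %g mm, conductor %g mm\n",
              object@role, object@shape, sz, object@contactMedium,
              object@contactThickness, object@conductorThickness))
  invisible(object)
})

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage '%s': %d electrodes, total current %g mA\n",
              object@name, length(object@electrodes),
              object@totalCurrent * 1e3))
  for (e in object@electrodes) show(e)
  invisible(object)
})

setMethod("show", "PotentialField", function(object) {
  d <- dim(object@V)
  cat(sprintf("PotentialField: %d x %d x %d at %.3g mm, range [%.4g, %.4g] V\n",
              d[1], d[2], d[3], object@voxelSize,
              min(object@V), max(object@V)))
  cat("  reference:", object@reference, "\n")
  invisible(object)
})

setMethod("show", "SolveReport", function(object) {
  cat(sprintf("SolveReport: %d iterations, relative residual %.3g (tol %.3g)%s\n",
              object@iterations, object@finalRelResidual, object@tolerance,
              if (object@converged) "" else " [NOT CONVERGED]"))
  cat("  electrode currents (mA):\n")
  for (nm in names(object@perElectrodeCurrent))
    cat(sprintf("    %-12s %+0.4f\n", nm,
                object@perElectrodeCurrent[nm] * 1e3))
  cat(sprintf("  conservation error: %.3g mA\n",
              object@conservationError * 1e3))
  invisible(object)
})

setMethod("show", "EFieldVolume", function(object) {
  d <- dim(object@magnitude)
  cat(sprintf("EFieldVolume: %d x %d x %d at %.3g mm, |E| max %.4g V/m\n",
              d[1], d[2], d[3], object@voxelSize, max(object@magnitude)))
  invisible(object)
})

setMethod("show", "CorticalSurface", function(object) {
  cat(sprintf("CorticalSurface: %d gray/CSF interface voxels at %.3g mm\n",
              nrow(object@coords), object@voxelSize))
  invisible(object)
})

setMethod("show", "CorticalMap", function(object) {
  cat(sprintf(
    "CorticalMap: %d locations, |E| in [%.4g, %.4g] V/m, E.n in [%.4g, %.4g] V/m\n",
    length(object@efMagnitude), min(object@efMagnitude),
    max(object@efMagnitude), min(object@efNormal), max(object@efNormal)))
  cat("  sign convention: positive normal component = inward current\n")
  invisible(object)
})

setMethod("show", "DoseNormalization", function(object) {
  cat(sprintf(
    "DoseNormalization vs '%s': scale factor %.3f, normalized current %.3g mA\n",
    object@referenceSubject, object@scaleFactor,
    object@normalizedCurrent * 1e3))
  invisible(object)
})
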