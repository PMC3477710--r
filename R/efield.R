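#' Derive the electric field E = -grad V
#'
#' Central differences in the interior; one-sided differences where the
#' central stencil would cross into air (or off the grid), so scalp and
#' surface fields are not contaminated by the unphysical air values.
#'
#' @param potential a \code{\linkS4class{PotentialField}}
#' @param head the \code{\linkS4class{LabelVolume}} /
#'   \code{\linkS4class{RasterizedHead}} the solve was run on (provides the
#'   air mask)
#' @return An \code{\linkS4class{EFieldVolume}} (components and magnitude
#'   in V/m).
#' @export
efieldFromPotential <- function(potential, head) {
  V <- potential@V
  dims <- dim(V)
  hM <- potential@voxelSize * 1e-3
  nonAir <- (head@labels != head@labelCodes[["air"]]) * 1
  E <- array(0, c(dims, 3L))
  for (ax in 1:3) {
    Vp <- shift3d(V, ax, -1L)      # value at i+1
    Vm <- shift3d(V, ax, 1L)       # value at i-1
    wp <- shift3d(nonAir, ax, -1L) # neighbor i+1 exists and is not air
    wm <- shift3d(nonAir, ax, 1L)
    num <- wp * (Vp - V) + wm * (V - Vm)
    den <- (wp + wm) * hM
    grad <- ifelse(den > 0, num / den, 0)
    E[, , , ax] <- -grad
  }
  mag <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  new("EFieldVolume", E = E, magnitude = mag,
      voxelSize = potential@voxelSize, center = potential@center)
}

#' Extract the cortical surface
#'
#' Operational definition: gray-matter voxels with at least one 6-connected
#' CSF neighbor. Outward unit normals are estimated from the gradient of a
#' Gaussian-smoothed brain (gray + white) indicator, pointing from gray
#' toward CSF.
#'
#' @param head a \code{\linkS4class{LabelVolume}} containing gray and CSF
#' @param smoothingSigma smoothing width for the normal estimate, in
#'   voxels (default 2)
#' @return A \code{\linkS4class{CorticalSurface}}.
#' @export
corticalSurface <- function(head, smoothingSigma = 2) {
  codes <- head@labelCodes
  lab <- head@labels
  gray <- lab == codes[["gray"]]
  csf <- (lab == codes[["csf"]]) * 1
  nbCsf <- array(0, dim(lab))
  for (ax in 1:3)
    nbCsf <- nbCsf + shift3d(csf, ax, 1L) + shift3d(csf, ax, -1L)
  surf <- gray & nbCsf > 0
  idx <- which(surf)
  if (!length(idx))
    stop("no gray/CSF adjacency found; cannot extract a cortical surface")
  brain <- (gray | lab == codes[["white"]]) * 1
  m <- smooth3d(brain, smoothingSigma)
  g <- array(0, c(dim(lab), 3L))
  for (ax in 1:3)
    g[, , , ax] <- (shift3d(m, ax, -1L) - shift3d(m, ax, 1L)) / 2
  nx <- -g[, , , 1][idx]
  ny <- -g[, , , 2][idx]
  nz <- -g[, , , 3][idx]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  bad <- nn < .Machine$double.eps
  nn[bad] <- 1
  normals <- cbind(nx / nn, ny / nn, nz / nn)
  dims <- dim(lab)
  coords <- cbind((idx - 1L) %% dims[1] + 1L,
                  ((idx - 1L) %/% dims[1]) %% dims[2] + 1L,
                  (idx - 1L) %/% (dims[1] * dims[2]) + 1L)
  new("CorticalSurface", coords = coords, index = as.integer(idx),
      normals = normals, voxelSize = head@voxelSize, center = head@center,
      dims = as.integer(dims))
}

#' Sample the field on the cortical surface
#'
#' Builds the cortical map: field magnitude |E| and the signed component
#' normal to the cortical surface at each surface location. Sign
#' convention: \code{efNormal = -E . n_outward}, so positive values mean
#' inward (anodal, depolarizing) current and negative values outward
#' (hyperpolarizing) current.
#'
#' @param ef an \code{\linkS4class{EFieldVolume}}
#' @param surface a \code{\linkS4class{CorticalSurface}} on the same grid
#' @return A \code{\linkS4class{CorticalMap}}.
#' @export
normalComponentMap <- function(ef, surface) {
  stopifnot(all(dim(ef@magnitude) == surface@dims))
  idx <- surface@index
  Ex <- ef@E[, , , 1][idx]
  Ey <- ef@E[, , , 2][idx]
  Ez <- ef@E[, , , 3][idx]
  efn <- -(Ex * surface@normals[, 1] + Ey * surface@normals[, 2] +
             Ez * surface@normals[, 3])
  mag <- ef@magnitude[idx]
  # unit-normal rounding can push |E.n| a hair above |E|
  efn <- sign(efn) * pmin(abs(efn), mag)
  new("CorticalMap", surface = surface, efMagnitude = mag, efNormal = efn)
}

#' Extract a 2-D cross-section
#'
#' Returns one axis-aligned slice of a potential or field-magnitude
#' volume, without interpolation.
#'
#' @param field a \code{\linkS4class{PotentialField}} or
#'   \code{\linkS4class{EFieldVolume}} (magnitude is sliced) or 3-D array
#' @param axis 1, 2 or 3 (or "x", "y", "z")
#' @param index slice index along that axis
#' @return A \code{fieldSlice}: list with \code{values} (matrix),
#'   \code{axis}, \code{index}, \code{voxelSize}.
#' @export
crossSection <- function(field, axis, index) {
  vol <- if (is(field, "PotentialField")) field@V
  else if (is(field, "EFieldVolume")) field@magnitude
  else field
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  dims <- dim(vol)
  if (index < 1 || index > dims[axis])
    stop("slice index ", index, " out of range 1..", dims[axis])
  values <- switch(axis, vol[index, , ], vol[, index, ], vol[, , index])
  vs <- if (is(field, "PotentialField") || is(field, "EFieldVolume"))
    field@voxelSize else NA_real_
  structure(list(values = values, axis = axis, index = index,
                 voxelSize = vs), class = "fieldSlice")
}

#' @export
print.fieldSlice <- function(x, ...) {
  cat(sprintf("fieldSlice: axis %d index %d, %d x %d, range [%.4g, %.4g]\n",
              x$axis, x$index, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
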