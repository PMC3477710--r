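#' Rasterize a montage onto a head
#'
#' Overlays each electrode onto the air surrounding the head: contact-medium
#' voxels (sponge or gel) extruded outward from the skin surface along the
#' local outward normal to the contact thickness, then conductor voxels to
#' the conductor thickness. No tissue voxel is overwritten, so stripping the
#' montage labels recovers the original head exactly. For sphere-like heads
#' the outward normal is radial; for slabs it is the face normal.
#'
#' Overlapping electrode footprints are an error (naming both electrodes),
#' as is rasterizing onto a head that already carries montage labels.
#'
#' @param head a \code{\linkS4class{LabelVolume}}
#' @param montage a \code{\linkS4class{Montage}}
#' @return A \code{\linkS4class{RasterizedHead}}; per-electrode conductor /
#'   contact voxel indices and exterior-face counts are recorded for the
#'   solver's current boundary condition.
#' @export
rasterizeMontage <- function(head, montage) {
  codes <- head@labelCodes
  lab <- head@labels
  montCodes <- codes[c("sponge", "gel", "electrode")]
  if (any(lab %in% montCodes))
    stop("head already carries montage labels; rasterization is not ",
         "applied twice")
  dims <- dim(lab)
  owner <- integer(0)          # linear index -> electrode ordinal
  ownerIdx <- integer(0)
  els <- montage@electrodes
  elNames <- names(els)
  if (is.null(elNames)) elNames <- paste0("electrode", seq_along(els))
  voxInfo <- vector("list", length(els))
  names(voxInfo) <- elNames

  for (ei in seq_along(els)) {
    e <- els[[ei]]
    foot <- electrodeFootprint(head, e)
    allIdx <- c(foot$contact, foot$conductor)
    if (!length(foot$contact) || !length(foot$conductor))
      stop("electrode '", elNames[ei],
           "' footprint does not land on the head surface")
    dup <- allIdx %in% ownerIdx
    if (any(dup)) {
      other <- unique(owner[match(allIdx[dup], ownerIdx)])
      stop("electrode footprints overlap: '", elNames[ei], "' and '",
           paste(elNames[other], collapse = "', '"), "'")
    }
    # footprint must sit on the head: inward neighbors of contact voxels
    inw <- inwardNeighbors(head, e, foot$contact)
    inwLab <- lab[inw]
    ok <- inwLab != codes[["air"]]
    if (!any(ok))
      stop("electrode '", elNames[ei], "' does not land on skin/tissue")
    ownerIdx <- c(ownerIdx, allIdx)
    owner <- c(owner, rep.int(ei, length(allIdx)))
    voxInfo[[ei]] <- foot
  }
  for (ei in seq_along(els)) {
    e <- els[[ei]]
    lab[voxInfo[[ei]]$contact] <- codes[[e@contactMedium]]
    lab[voxInfo[[ei]]$conductor] <- codes[["electrode"]]
  }
  # exterior faces of conductor voxels: faces open to air or grid boundary
  for (ei in seq_along(els)) {
    voxInfo[[ei]]$exteriorFaces <-
      countExteriorFaces(lab, codes, voxInfo[[ei]]$conductor, dims)
  }
  new("RasterizedHead", labels = lab, voxelSize = head@voxelSize,
      labelCodes = codes, center = head@center,
      provenance = head@provenance, montage = montage,
      electrodeVoxels = voxInfo)
}

# linear indices of the contact and conductor voxels of one electrode
electrodeFootprint <- function(head, e) {
  if (!is.null(e@position$face)) slabFootprint(head, e)
  else sphericalFootprint(head, e)
}

sphericalFootprint <- function(head, e) {
  h <- head@voxelSize
  dims <- dim(head@labels)
  Rs <- scalpRadius(head)
  # guarantee at least one voxel layer of each material on coarse grids
  tC <- max(e@contactThickness, h)
  tM <- max(e@conductorThickness, 1.5 * h)
  r <- radiusArray(dims, h, head@center)
  shell <- which(r > Rs & r <= Rs + tC + tM + 0.5 * h &
                   head@labels == head@labelCodes[["air"]])
  if (!length(shell)) return(list(contact = integer(0), conductor = integer(0)))
  xyz <- voxelXYZ(shell, dims, h, head@center)
  rs <- r[shell]
  d <- xyz / rs
  u0 <- unitVec(e@position$theta, e@position$phi)
  cosg <- clamp(d %*% u0, -1, 1)
  gamma <- acos(cosg)
  s <- Rs * gamma
  inFoot <- if (e@shape == "disc") {
    s <= e@size[1] / 2
  } else {
    fr <- tangentFrame(e@position$theta, e@position$phi)
    tvec <- d - as.vector(cosg) * matrix(u0, nrow(d), 3, byrow = TRUE)
    tn <- sqrt(rowSums(tvec^2))
    that <- tvec / ifelse(tn > 0, tn, 1)
    x1 <- s * (that %*% fr$e1)
    x2 <- s * (that %*% fr$e2)
    abs(x1) <= e@size[1] / 2 & abs(x2) <= e@size[2] / 2
  }
  inFoot <- as.vector(inFoot)
  list(contact = shell[inFoot & rs <= Rs + tC],
       conductor = shell[inFoot & rs > Rs + tC & rs <= Rs + tC + tM])
}

slabFootprint <- function(head, e) {
  h <- head@voxelSize
  dims <- dim(head@labels)
  codes <- head@labelCodes
  airs <- head@labels == codes[["air"]]
  face <- e@position$face
  stopifnot(face %in% c("zmin", "zmax"))
  nonAirZ <- which(apply(!airs, 3, any))
  zSurf <- if (face == "zmax") max(nonAirZ) else min(nonAirZ)
  # distance (mm) outward from the slab surface plane for each k slice
  kAll <- seq_len(dims[3])
  outDist <- if (face == "zmax") (kAll - zSurf) * h else (zSurf - kAll) * h
  nContact <- which(outDist > 0 & outDist <= e@contactThickness + 1e-9)
  nConduct <- which(outDist > e@contactThickness + 1e-9 &
                      outDist <= e@contactThickness + e@conductorThickness + 1e-9)
  x <- voxelCenters1d(dims[1], h) - head@center[1]
  y <- voxelCenters1d(dims[2], h) - head@center[2]
  inx <- abs(x) <= e@size[1] / 2
  iny <- abs(y) <= e@size[2] / 2
  footXY <- which(outer(inx, iny, "&"))
  nxy <- dims[1] * dims[2]
  mk <- function(ks) {
    idx <- as.integer(outer(footXY, (ks - 1L) * nxy, "+"))
    idx[airs[idx]]
  }
  list(contact = mk(nContact), conductor = mk(nConduct))
}

# inward neighbor (toward the head) of each contact voxel
inwardNeighbors <- function(head, e, idx) {
  dims <- dim(head@labels)
  h <- head@voxelSize
  if (!is.null(e@position$face)) {
    nxy <- dims[1] * dims[2]
    if (e@position$face == "zmax") pmax(idx - nxy, 1L) else
      pmin(idx + nxy, prod(dims))
  } else {
    xyz <- voxelXYZ(idx, dims, h, head@center)
    r <- sqrt(rowSums(xyz^2))
    step <- xyz / r * h
    tgt <- xyz - 2 * step          # two voxels inward to be safely in skin
    ijk <- sweep(tgt, 2, head@center, "+") / h + 0.5
    ijk <- pmin(pmax(round(ijk), 1), matrix(dims, nrow(ijk), 3, byrow = TRUE))
    as.integer(ijk[, 1] + (ijk[, 2] - 1) * dims[1] +
                 (ijk[, 3] - 1) * dims[1] * dims[2])
  }
}

countExteriorFaces <- function(lab, codes, idx, dims) {
  if (!length(idx)) return(integer(0))
  n1 <- dims[1]; n12 <- dims[1] * dims[2]
  i <- (idx - 1L) %% n1 + 1L
  j <- ((idx - 1L) %/% n1) %% dims[2] + 1L
  k <- (idx - 1L) %/% n12 + 1L
  air <- codes[["air"]]
  cnt <- integer(length(idx))
  nb <- function(off, atEdge) {
    out <- atEdge                       # grid boundary counts as exterior
    inside <- !atEdge
    out[inside] <- lab[idx[inside] + off] == air
    out
  }
  cnt <- cnt + nb(-1L, i == 1L) + nb(1L, i == dims[1]) +
    nb(-n1, j == 1L) + nb(n1, j == dims[2]) +
    nb(-n12, k == 1L) + nb(n12, k == dims[3])
  as.integer(cnt)
}

#' Strip montage labels from a rasterized head
#'
#' Replaces sponge, gel and electrode voxels by air, recovering the
#' original head.
#'
#' @param raster a \code{\linkS4class{RasterizedHead}}
#' @return A \code{\linkS4class{LabelVolume}}.
#' @export
stripMontage <- function(raster) {
  codes <- raster@labelCodes
  lab <- raster@labels
  lab[lab %in% codes[c("sponge", "gel", "electrode")]] <- codes[["air"]]
  new("LabelVolume", labels = lab, voxelSize = raster@voxelSize,
      labelCodes = codes, center = raster@center,
      provenance = raster@provenance)
}
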