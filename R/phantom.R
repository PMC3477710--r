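#' Generate a layered-sphere head phantom
#'
#' Builds a voxelized six-tissue digital head: concentric shells of skin,
#' skull, CSF and gray matter around a white-matter core, surrounded by
#' air. Each voxel is classified by the distance of its center from the
#' head center (voxel-center classification, no partial volumes), so the
#' construction is deterministic and directly checkable against analytic
#' shell volumes.
#'
#' @param spec a \code{\link{sphereSpec}}
#' @return A \code{\linkS4class{LabelVolume}}.
#' @export
#' @examples
#' head <- spherePhantom(sphereSpec(60, c(skin = 5, skull = 5, csf = 3, gray = 5),
#'                                  voxelSize = 2.5))
#' head
spherePhantom <- function(spec) {
  validObject(spec)
  geom <- sphereGeometry(spec)
  r <- radiusArray(geom$dims, spec@voxelSize, geom$center)
  lab <- classifyShells(r, geom$breaks)
  new("LabelVolume", labels = lab, voxelSize = spec@voxelSize,
      labelCodes = labelCodes(), center = geom$center,
      provenance = list(type = "sphere", spec = spec))
}

# grid geometry shared by sphere generators
sphereGeometry <- function(spec) {
  h <- spec@voxelSize
  n <- as.integer(2L * ceiling((spec@outerRadius + spec@margin) / h))
  dims <- rep(n, 3L)
  center <- rep(n * h / 2, 3L)
  th <- spec@thickness
  R <- spec@outerRadius
  rSkullOut <- R - th[["skin"]]
  rCsfOut <- rSkullOut - th[["skull"]]
  rGrayOut <- rCsfOut - th[["csf"]]
  rWhite <- rGrayOut - th[["gray"]]
  list(dims = dims, center = center,
       breaks = c(white = rWhite, gray = rGrayOut, csf = rCsfOut,
                  skull = rSkullOut, skin = R))
}

classifyShells <- function(r, breaks) {
  codes <- labelCodes()
  lut <- codes[c("white", "gray", "csf", "skull", "skin", "air")]
  idx <- findInterval(r, breaks)
  array(lut[idx + 1L], dim = dim(r))
}

#' Generate a gyrated sphere phantom
#'
#' As \code{\link{spherePhantom}}, but the gray/CSF interface radius is
#' modulated sinusoidally in the spherical angles,
#' r(theta, phi) = r0 + A sin(k theta) sin(k phi + phase), emulating
#' gyri/sulci: CSF fills the grooves and the gray sheet keeps its radial
#' thickness, which reproduces the mechanism behind sulcal field hotspots.
#' The modulated interface is clipped so folds never pierce the skull or
#' the white core. The phase derives deterministically from the integer
#' seed (golden-ratio map), so identical (spec, gyri) inputs give
#' bit-identical volumes.
#'
#' @param spec a \code{\link{sphereSpec}}
#' @param gyri a \code{\link{gyriSpec}}; amplitude must be smaller than the
#'   CSF + gray thickness
#' @return A \code{\linkS4class{LabelVolume}}.
#' @export
gyratedPhantom <- function(spec, gyri) {
  validObject(spec)
  validObject(gyri)
  th <- spec@thickness
  if (gyri@amplitude >= th[["csf"]] + th[["gray"]])
    stop("amplitude: fold amplitude must be < csf + gray thickness ",
         "(folds must not pierce skull or white core)")
  geom <- sphereGeometry(spec)
  h <- spec@voxelSize
  r <- radiusArray(geom$dims, h, geom$center)
  lab <- classifyShells(r, geom$breaks)

  if (gyri@amplitude > 0) {
    phase <- 2 * pi * ((gyri@seed * 0.6180339887498949) %% 1)
    rCsfOut <- geom$breaks[["csf"]]
    rGray0 <- geom$breaks[["gray"]]
    tGray <- th[["gray"]]
    # fold band: only voxels inside the CSF outer shell can change class
    sel <- which(r <= rCsfOut & r > 0)
    xyz <- voxelXYZ(sel, geom$dims, h, geom$center)
    rs <- r[sel]
    theta <- acos(clamp(xyz[, 3] / rs, -1, 1))
    phiAng <- atan2(xyz[, 2], xyz[, 1])
    k <- gyri@wavenumber
    rgc <- rGray0 + gyri@amplitude * sin(k * theta) * sin(k * phiAng + phase)
    # crowns keep a one-voxel CSF film below the skull (the CSF layer is
    # continuous in real heads); troughs must not reach the white core
    rgc <- clamp(rgc, tGray + h, rCsfOut - h)
    newLab <- ifelse(rs > rgc, labelCodes()[["csf"]],
                     ifelse(rs > rgc - tGray, labelCodes()[["gray"]],
                            labelCodes()[["white"]]))
    lab[sel] <- as.integer(newLab)
  }
  new("LabelVolume", labels = lab, voxelSize = h,
      labelCodes = labelCodes(), center = geom$center,
      provenance = list(type = "gyrated", spec = spec, gyri = gyri))
}

#' Generate a homogeneous slab phantom
#'
#' A box of a single tissue label surrounded by an air padding, used as a
#' closed-form test bed: with plate electrodes on opposite faces the
#' interior field is uniform with |E| = I / (A sigma).
#'
#' @param extent c(x, y, z) slab edge lengths (mm)
#' @param label tissue label name for the slab interior (default "gray")
#' @param voxelSize voxel edge length (mm)
#' @param paddingVoxels air padding on each side, in voxels (default 1;
#'   increase to leave room for plate electrodes)
#' @return A \code{\linkS4class{LabelVolume}}.
#' @export
slabPhantom <- function(extent, label = "gray", voxelSize = 1,
                        paddingVoxels = 1L) {
  if (any(extent <= 0)) stop("extent: all slab extents must be > 0")
  if (voxelSize <= 0) stop("voxelSize: must be > 0")
  codes <- labelCodes()
  if (!label %in% names(codes)) stop("unknown tissue label: ", label)
  nIn <- as.integer(round(extent / voxelSize))
  pad <- as.integer(paddingVoxels)
  dims <- nIn + 2L * pad
  lab <- array(codes[["air"]], dims)
  lab[pad + seq_len(nIn[1]), pad + seq_len(nIn[2]), pad + seq_len(nIn[3])] <-
    codes[[label]]
  new("LabelVolume", labels = lab, voxelSize = voxelSize,
      labelCodes = codes, center = dims * voxelSize / 2,
      provenance = list(type = "slab", extent = extent, label = label,
                        paddingVoxels = pad))
}

#' Subject phantom presets
#'
#' Illustrative per-"subject" sphere parameters (two male heads M1, M2 and
#' one female head F) emulating inter-individual anatomical variation:
#' about +/-10% in head radius and a 4-7 mm skull-thickness range, with the
#' smallest head (F) also carrying the thinnest skull and CSF. The presets
#' live in a configuration file (\code{inst/extdata/subjects.yaml}), not in
#' code, and can be overridden by supplying a different file.
#'
#' @param file optional YAML file with the same structure as the shipped
#'   default
#' @param voxelSize voxel size (mm) to build the specs with (default 1)
#' @return Named list of \code{\linkS4class{SphereSpec}}.
#' @export
#' @examples
#' names(subjectPresets())
subjectPresets <- function(file = NULL, voxelSize = 1) {
  if (is.null(file))
    file <- system.file("extdata", "subjects.yaml", package = "tdcssim")
  cfg <- yaml::read_yaml(file)
  lapply(cfg, function(s) {
    sphereSpec(s$outer_radius_mm,
               c(skin = s$skin_mm, skull = s$skull_mm,
                 csf = s$csf_mm, gray = s$gray_mm),
               voxelSize = voxelSize)
  })
}

#' Per-label voxel counts
#'
#' @param vol a \code{\linkS4class{LabelVolume}}
#' @return Named integer vector of voxel counts, one entry per label code
#'   (zero for absent labels).
#' @export
labelCounts <- function(vol) {
  tab <- tabulate(as.vector(vol@labels) + 1L,
                  nbins = max(vol@labelCodes) + 1L)
  out <- tab[vol@labelCodes + 1L]
  names(out) <- names(vol@labelCodes)
  out
}
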