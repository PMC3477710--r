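#' Montage position defaults
#'
#' Electrode-placement conventions used by the montage presets, read from
#' \code{inst/extdata/montage_defaults.yaml}: spherical angles (degrees)
#' approximating the left motor cortex (C3-like) anode position and the
#' contralateral supraorbital cathode position, the 4x1 ring geodesic
#' distance, and contact/conductor thicknesses. Coordinates: theta is the
#' colatitude from the vertex (+z), phi the azimuth from the anterior axis
#' (+x), +y pointing left.
#'
#' @param file optional alternative YAML file
#' @return Named list of defaults.
#' @export
montageDefaults <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "montage_defaults.yaml",
                        package = "tdcssim")
  yaml::read_yaml(file)
}

deg2rad <- function(x) x * pi / 180

#' Conventional pad montage (motor cortex - contralateral supraorbital)
#'
#' Two 5 cm x 5 cm sponge-pad electrodes: the anode centered over the
#' left-motor-cortex position and the cathode over the contralateral
#' supraorbital position, at 1 mA total current by default. Pad edges are
#' aligned with the local (theta, phi) tangent axes at the pad center.
#'
#' @param head a \code{\linkS4class{LabelVolume}} with a skin shell
#' @param current total injected current (A), default 1e-3
#' @param defaults placement defaults, see \code{\link{montageDefaults}}
#' @return A \code{\linkS4class{Montage}}.
#' @export
padMontageM1SO <- function(head, current = 1e-3,
                           defaults = montageDefaults()) {
  d <- defaults$pad_m1_so
  an <- electrode("anode", "pad", c(d$pad_mm, d$pad_mm),
                  list(theta = deg2rad(d$anode$theta_deg),
                       phi = deg2rad(d$anode$phi_deg)),
                  contactMedium = "sponge",
                  contactThickness = defaults$thickness$sponge_mm,
                  conductorThickness = defaults$thickness$conductor_mm)
  ca <- electrode("cathode", "pad", c(d$pad_mm, d$pad_mm),
                  list(theta = deg2rad(d$cathode$theta_deg),
                       phi = deg2rad(d$cathode$phi_deg)),
                  contactMedium = "sponge",
                  contactThickness = defaults$thickness$sponge_mm,
                  conductorThickness = defaults$thickness$conductor_mm)
  m <- new("Montage", electrodes = list(anode = an, cathode = ca),
           totalCurrent = current, name = "pad-m1-so")
  checkMontageFits(head, m)
  m
}

#' 4x1 high-definition ring montage
#'
#' One central anode disc (12 mm diameter) at the same angular position as
#' the pad-montage anode, surrounded by four cathode discs at 90-degree
#' azimuthal increments, each at the configured scalp-geodesic
#' center-to-center distance (60 mm by default) from the anode. Contact is
#' through gel. The 6 cm spacing is interpreted as geodesic distance along
#' the scalp.
#'
#' @param head a \code{\linkS4class{LabelVolume}}
#' @param current total injected current (A), default 1e-3
#' @param defaults placement defaults, see \code{\link{montageDefaults}}
#' @return A \code{\linkS4class{Montage}} with 1 anode + 4 cathodes.
#' @export
hdMontage4x1 <- function(head, current = 1e-3,
                         defaults = montageDefaults()) {
  d <- defaults$hd_4x1
  ctr <- c(theta = deg2rad(defaults$pad_m1_so$anode$theta_deg),
           phi = deg2rad(defaults$pad_m1_so$anode$phi_deg))
  Rs <- scalpRadius(head)
  ringAngle <- d$ring_distance_mm / Rs
  if (ctr[["theta"]] + ringAngle >= pi)
    stop("ring falls off the modeled scalp")
  mk <- function(role, theta, phi) {
    electrode(role, "disc", d$disc_diameter_mm,
              list(theta = theta, phi = phi), contactMedium = "gel",
              contactThickness = defaults$thickness$gel_mm,
              conductorThickness = defaults$thickness$conductor_mm)
  }
  u0 <- unitVec(ctr[["theta"]], ctr[["phi"]])
  fr <- tangentFrame(ctr[["theta"]], ctr[["phi"]])
  els <- list(anode = mk("anode", ctr[["theta"]], ctr[["phi"]]))
  for (i in 0:3) {
    az <- i * pi / 2
    # walk ringAngle along the great circle leaving the anode at azimuth az
    dir <- cos(az) * fr$e1 + sin(az) * fr$e2
    u <- cos(ringAngle) * u0 + sin(ringAngle) * dir
    th <- acos(clamp(u[3], -1, 1))
    ph <- atan2(u[2], u[1])
    els[[paste0("cathode", i + 1)]] <- mk("cathode", th, ph)
  }
  m <- new("Montage", electrodes = els, totalCurrent = current,
           name = "hd-4x1")
  checkMontageFits(head, m)
  m
}

#' Opposing plate montage for slab phantoms
#'
#' Pad electrodes covering opposite faces of a slab, used for the
#' closed-form Ohm's-law validation (uniform interior field
#' |E| = I / (A sigma)).
#'
#' @param head a slab \code{\linkS4class{LabelVolume}} (see
#'   \code{\link{slabPhantom}})
#' @param axis face axis, currently "z"
#' @param size plate edge lengths c(length, width) mm; default = full face
#' @param current total injected current (A)
#' @param contactThickness,conductorThickness layer thicknesses (mm);
#'   the slab's air padding must accommodate their sum
#' @return A \code{\linkS4class{Montage}}.
#' @export
slabPlateMontage <- function(head, axis = "z", size = NULL, current = 1e-3,
                             contactThickness = NULL,
                             conductorThickness = NULL) {
  stopifnot(axis == "z")
  prov <- head@provenance
  if (is.null(prov$type) || prov$type != "slab")
    stop("slabPlateMontage requires a slab phantom")
  if (is.null(size)) size <- prov$extent[1:2]
  h <- head@voxelSize
  pad <- prov$paddingVoxels * h
  if (is.null(contactThickness)) contactThickness <- max(h, pad / 2)
  if (is.null(conductorThickness)) conductorThickness <- max(h, pad - contactThickness)
  if (contactThickness + conductorThickness > pad + 1e-9)
    stop("slab air padding too thin for the requested electrode layers; ",
         "increase paddingVoxels in slabPhantom()")
  mk <- function(role, face) {
    electrode(role, "pad", size, list(face = face),
              contactMedium = "sponge", contactThickness = contactThickness,
              conductorThickness = conductorThickness)
  }
  new("Montage",
      electrodes = list(anode = mk("anode", "zmax"),
                        cathode = mk("cathode", "zmin")),
      totalCurrent = current, name = "slab-plates")
}

# outer scalp radius (mm): from generator provenance when available, else
# the largest non-air voxel-center radius
scalpRadius <- function(head) {
  prov <- head@provenance
  if (!is.null(prov$spec)) return(prov$spec@outerRadius)
  r <- radiusArray(dim(head@labels), head@voxelSize, head@center)
  max(r[head@labels != head@labelCodes[["air"]]])
}

# rough fit check: every electrode's angular footprint must stay on the
# sphere (full on-skin validation happens at rasterization)
checkMontageFits <- function(head, montage) {
  Rs <- scalpRadius(head)
  for (nm in names(montage@electrodes)) {
    e <- montage@electrodes[[nm]]
    if (is.null(e@position$theta)) next
    ext <- if (e@shape == "pad") sqrt(2) * max(e@size) / 2 else e@size[1] / 2
    halfAngle <- ext / Rs
    if (e@position$theta + halfAngle >= pi ||
        e@position$theta - halfAngle <= -pi)
      stop("electrode '", nm, "' footprint does not fit on the scalp")
  }
  invisible(TRUE)
}

#' Geodesic scalp distance between two electrodes
#'
#' Great-circle distance along the scalp sphere between electrode center
#' positions.
#'
#' @param head a \code{\linkS4class{LabelVolume}}
#' @param e1,e2 \code{Electrode}s with angular positions
#' @return Distance in mm.
#' @export
geodesicDistance <- function(head, e1, e2) {
  Rs <- scalpRadius(head)
  u1 <- unitVec(e1@position$theta, e1@position$phi)
  u2 <- unitVec(e2@position$theta, e2@position$phi)
  Rs * acos(clamp(sum(u1 * u2), -1, 1))
}

#' Serialize / deserialize a montage
#'
#' Round-trips roles, shapes, sizes, positions, media, thicknesses and the
#' total current through YAML.
#'
#' @param montage a \code{\linkS4class{Montage}}
#' @param file path to a .yaml file
#' @return \code{writeMontage}: \code{file} invisibly;
#'   \code{readMontage}: a \code{\linkS4class{Montage}}.
#' @export
writeMontage <- function(montage, file) {
  els <- lapply(montage@electrodes, function(e) {
    list(role = e@role, shape = e@shape, size_mm = as.list(e@size),
         position = e@position, contact_medium = e@contactMedium,
         contact_thickness_mm = e@contactThickness,
         conductor_thickness_mm = e@conductorThickness)
  })
  yaml::write_yaml(list(name = montage@name,
                        total_current_A = montage@totalCurrent,
                        electrodes = els), file, precision = 15L)
  invisible(file)
}

#' @rdname writeMontage
#' @export
readMontage <- function(file) {
  cfg <- yaml::read_yaml(file)
  els <- lapply(cfg$electrodes, function(e) {
    new("Electrode", role = e$role, shape = e$shape,
        size = as.numeric(unlist(e$size_mm)), position = e$position,
        contactMedium = e$contact_medium,
        contactThickness = e$contact_thickness_mm,
        conductorThickness = e$conductor_thickness_mm)
  })
  new("Montage", electrodes = els, totalCurrent = cfg$total_current_A,
      name = cfg$name)
}
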