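#' Peak cortical electric field
#'
#' Maximum and robust (99.9th percentile) field magnitude over the
#' cortical-surface locations, with the peak location. Ties are broken by
#' grid storage order (first occurrence).
#'
#' @param cmap a \code{\linkS4class{CorticalMap}}
#' @return List with \code{peak}, \code{robustPeak} (V/m), \code{location}
#'   (voxel indices) and \code{locationIndex} (linear index).
#' @export
peakCorticalEF <- function(cmap) {
  v <- cmap@efMagnitude
  if (!length(v)) stop("empty cortical map")
  ord <- order(cmap@surface@index)
  vOrd <- v[ord]
  iMax <- ord[which.max(vOrd)]
  list(peak = max(v),
       robustPeak = as.numeric(stats::quantile(v, 0.999, names = FALSE)),
       location = cmap@surface@coords[iMax, ],
       locationIndex = cmap@surface@index[iMax])
}

#' Fold-variation of peak fields across subjects
#'
#' max(peaks)/min(peaks): the spread in induced peak field across heads at
#' identical montage and current.
#'
#' @param peaks numeric vector (>= 2 positive values)
#' @return The ratio.
#' @export
#' @examples
#' foldVariation(c(0.27, 0.35, 0.40))   # ~1.5
#' foldVariation(c(0.14, 0.36, 0.42))   # 3.0
foldVariation <- function(peaks) {
  if (length(peaks) < 2) stop("need at least 2 peak values")
  if (any(!is.finite(peaks)) || any(peaks <= 0))
    stop("peaks must be positive")
  max(peaks) / min(peaks)
}

#' Containment of suprathreshold cortex inside a scalp region
#'
#' Fraction of cortical locations with |E| >= thresholdFrac x robust peak
#' whose radial scalp projection falls inside a geodesic disc (typically
#' the 4x1 ring's perimeter around the center anode). Operationalizes
#' "cortical activation circumscribed by the ring".
#'
#' @param cmap a \code{\linkS4class{CorticalMap}}
#' @param region list with \code{center} (unit 3-vector or
#'   \code{list(theta=, phi=)} scalp direction of the disc center),
#'   \code{radius} (geodesic radius, mm) and \code{scalpRadius} (mm); see
#'   \code{\link{ringRegion}}
#' @param thresholdFrac threshold as a fraction of the robust peak
#'   (default 0.5)
#' @return Fraction in [0, 1], or \code{NA} (with a warning) when no
#'   location is suprathreshold.
#' @export
containmentFraction <- function(cmap, region, thresholdFrac = 0.5) {
  u0 <- region$center
  if (is.list(u0)) u0 <- unitVec(u0$theta, u0$phi)
  u0 <- u0 / sqrt(sum(u0^2))
  thr <- thresholdFrac *
    as.numeric(stats::quantile(cmap@efMagnitude, 0.999, names = FALSE))
  supra <- cmap@efMagnitude >= thr
  if (!any(supra)) {
    warning("no suprathreshold cortical locations; containment undefined")
    return(NA_real_)
  }
  surf <- cmap@surface
  xyz <- sweep(surf@coords - 0.5, 2, surf@center / surf@voxelSize, "-") *
    surf@voxelSize
  r <- sqrt(rowSums(xyz^2))
  cosg <- clamp((xyz %*% u0) / r, -1, 1)
  geo <- region$scalpRadius * acos(cosg)
  mean(geo[supra] <= region$radius)
}

#' Scalp-projected ring region of an HD montage
#'
#' The geodesic disc on the scalp spanned by the 4x1 ring: centered on the
#' anode, radius equal to the anode-to-cathode geodesic distance.
#'
#' @param head the \code{\linkS4class{LabelVolume}}
#' @param montage an HD \code{\linkS4class{Montage}} (anode + ring
#'   cathodes); any montage with an angular anode position works, with
#'   \code{radius} overriding the measured ring distance
#' @param radius optional geodesic radius (mm); default: mean geodesic
#'   anode-cathode distance
#' @return Region list for \code{\link{containmentFraction}}.
#' @export
ringRegion <- function(head, montage, radius = NULL) {
  roles <- vapply(montage@electrodes, function(e) e@role, "")
  an <- montage@electrodes[[which(roles == "anode")]]
  if (is.null(radius)) {
    cat <- montage@electrodes[roles == "cathode"]
    radius <- mean(vapply(cat, function(e) geodesicDistance(head, an, e),
                          0))
  }
  list(center = list(theta = an@position$theta, phi = an@position$phi),
       radius = radius, scalpRadius = scalpRadius(head))
}

#' Focality volume
#'
#' Cortical volume (mm^3, counting surface voxels) with |E| above a
#' fraction of the robust peak.
#'
#' @param cmap a \code{\linkS4class{CorticalMap}}
#' @param thresholdFrac fraction of the robust peak (default 0.5)
#' @return Volume in mm^3.
#' @export
focalityVolume <- function(cmap, thresholdFrac = 0.5) {
  thr <- thresholdFrac *
    as.numeric(stats::quantile(cmap@efMagnitude, 0.999, names = FALSE))
  sum(cmap@efMagnitude >= thr) * cmap@surface@voxelSize^3
}

#' Normalize stimulation dose by current scaling
#'
#' Because the DC volume-conduction problem is linear in the injected
#' current, a subject can be brought to a reference head's peak cortical
#' field by scaling the base current by referencePeak / subjectPeak. A head
#' that concentrates x-fold more field than the reference thus gets its
#' current reduced by the factor x.
#'
#' @param subjectPeak subject's peak cortical field (V/m) at the base
#'   current
#' @param referencePeak reference head's peak cortical field (V/m)
#' @param baseCurrent base current (A), default 1e-3
#' @param referenceSubject optional reference label
#' @return A \code{\linkS4class{DoseNormalization}}.
#' @export
#' @examples
#' # 1 mA in a 0.27 V/m head scaled to match a 0.40 V/m head: ~1.5 mA
#' normalizeDose(0.27, 0.40)
normalizeDose <- function(subjectPeak, referencePeak, baseCurrent = 1e-3,
                          referenceSubject = "reference") {
  if (subjectPeak <= 0 || referencePeak <= 0)
    stop("peaks must be positive")
  sf <- referencePeak / subjectPeak
  new("DoseNormalization", scaleFactor = sf,
      normalizedCurrent = baseCurrent * sf,
      referenceSubject = referenceSubject)
}

#' Published reference peak cortical fields
#'
#' Representative peak cortical electric-field magnitudes (V/m) reported
#' for three healthy adult heads (two male, one female) under 1 mA
#' stimulation with the conventional 5x5 cm pad montage and the 4x1
#' high-definition ring montage. Used as inputs to the worked
#' fold-variation and dose-normalization examples.
#'
#' @return data.frame with columns subject, montage, peak_V_per_m.
#' @export
#' @examples
#' p <- referencePeaks()
#' foldVariation(p$peak_V_per_m[p$montage == "pad"])
referencePeaks <- function() {
  data.frame(
    subject = rep(c("M1", "M2", "F"), 2),
    montage = rep(c("pad", "hd"), each = 3),
    peak_V_per_m = c(0.27, 0.35, 0.40, 0.14, 0.36, 0.42),
    stringsAsFactors = FALSE)
}
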