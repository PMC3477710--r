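#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums
NULL

#' Canonical tissue/material label codes
#'
#' Integer codes used for the voxel label grids. The six tissue classes
#' (air, skin, skull, CSF, gray matter, white matter) plus the montage
#' materials (sponge, gel, electrode conductor).
#'
#' @return Named integer vector.
#' @export
#' @examples
#' labelCodes()
labelCodes <- function() {
  c(air = 0L, skin = 1L, skull = 2L, csf = 3L, gray = 4L, white = 5L,
    sponge = 6L, gel = 7L, electrode = 8L)
}

#' Specification of a layered-sphere head phantom
#'
#' Concentric shells (skin, skull, CSF, gray matter) around a white-matter
#' core, classified at voxel centers. All lengths in millimeters.
#'
#' @slot outerRadius outer scalp radius (mm)
#' @slot thickness named numeric, shell thicknesses for skin, skull, csf,
#'   gray (mm); white matter fills the remainder
#' @slot voxelSize isotropic voxel edge length (mm)
#' @slot margin air margin beyond the scalp on each side of the grid (mm);
#'   must leave room for electrode contact + conductor layers
#' @exportClass SphereSpec
setClass("SphereSpec", representation(
  outerRadius = "numeric", thickness = "numeric",
  voxelSize = "numeric", margin = "numeric"))

setValidity("SphereSpec", function(object) {
  th <- object@thickness
  need <- c("skin", "skull", "csf", "gray")
  if (!all(need %in% names(th)))
    return(paste0("thickness must name ", paste(need, collapse = ", ")))
  if (any(th[need] <= 0))
    return(paste0("thickness: all shell thicknesses must be > 0 (offending: ",
                  paste(need[th[need] <= 0], collapse = ", "), ")"))
  if (sum(th[need]) >= object@outerRadius)
    return("thickness: sum of shell thicknesses must be < outerRadius")
  if (object@voxelSize <= 0) return("voxelSize: must be > 0")
  if (object@outerRadius / object@voxelSize < 20)
    return("outerRadius/voxelSize: must be >= 20 voxels to resolve layers")
  if (object@margin < 0) return("margin: must be >= 0")
  TRUE
})

#' @rdname SphereSpec-class
#' @param outerRadius,thickness,voxelSize,margin see slots
#' @return A \code{SphereSpec}.
#' @export
#' @examples
#' sphereSpec(92, c(skin = 7, skull = 5, csf = 2, gray = 3), voxelSize = 1)
sphereSpec <- function(outerRadius,
                       thickness = c(skin = 7, skull = 5, csf = 2, gray = 3),
                       voxelSize = 1, margin = 10) {
  new("SphereSpec", outerRadius = as.numeric(outerRadius),
      thickness = thickness[c("skin", "skull", "csf", "gray")],
      voxelSize = as.numeric(voxelSize), margin = as.numeric(margin))
}

#' Sinusoidal gyral folding of the gray/CSF interface
#'
#' The gray/CSF interface radius of a layered sphere is modulated as
#' r(theta, phi) = r0 + A sin(k theta) sin(k phi + phase(seed)); cortical
#' (gray) thickness is preserved along the radial direction, so CSF fills
#' the grooves as in real sulci. The phase is derived from the integer seed
#' as phase = 2 pi frac(seed * (sqrt(5)-1)/2), which makes phantoms portable
#' across implementations.
#'
#' @slot amplitude fold amplitude A (mm); must be < csf + gray thickness
#' @slot wavenumber integer angular frequency k (>= 2)
#' @slot seed integer phase seed
#' @exportClass GyriSpec
setClass("GyriSpec", representation(
  amplitude = "numeric", wavenumber = "integer", seed = "integer"))

setValidity("GyriSpec", function(object) {
  if (object@amplitude < 0) return("amplitude: must be >= 0")
  if (object@wavenumber < 2L) return("wavenumber: must be an integer >= 2")
  TRUE
})

#' @rdname GyriSpec-class
#' @param amplitude,wavenumber,seed see slots
#' @return A \code{GyriSpec}.
#' @export
gyriSpec <- function(amplitude, wavenumber, seed = 1L) {
  new("GyriSpec", amplitude = as.numeric(amplitude),
      wavenumber = as.integer(wavenumber), seed = as.integer(seed))
}

#' Voxelized tissue-label volume
#'
#' The digital head: a 3-D integer grid of tissue/material labels with
#' isotropic voxel spacing. Voxel (i,j,k) has its center at physical
#' coordinates ((i-0.5)h, (j-0.5)h, (k-0.5)h) mm.
#'
#' @slot labels 3-D integer array of label codes
#' @slot voxelSize voxel edge length (mm)
#' @slot labelCodes named integer vector mapping label names to codes
#' @slot center physical coordinates (mm) of the head center
#' @slot provenance list of generator parameters (empty for imported data)
#' @exportClass LabelVolume
setClass("LabelVolume", representation(
  labels = "array", voxelSize = "numeric", labelCodes = "integer",
  center = "numeric", provenance = "list"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
  if (!is.integer(object@labels)) return("labels must be integer")
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  if (length(object@center) != 3L) return("center must have length 3")
  if (is.null(names(object@labelCodes))) return("labelCodes must be named")
  bad <- setdiff(unique(as.vector(object@labels)), object@labelCodes)
  if (length(bad))
    return(paste0("labels contain codes absent from labelCodes: ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Tissue conductivity table
#'
#' Maps tissue/material labels to isotropic conductivities in S/m.
#'
#' @slot sigma named numeric vector of conductivities (S/m), all > 0
#' @exportClass ConductivityTable
setClass("ConductivityTable", representation(sigma = "numeric"))

setValidity("ConductivityTable", function(object) {
  if (is.null(names(object@sigma))) return("sigma must be named")
  if (any(object@sigma <= 0))
    return(paste0("sigma: conductivities must be > 0 (offending: ",
                  paste(names(object@sigma)[object@sigma <= 0],
                        collapse = ", "), ")"))
  TRUE
})

#' A single stimulation electrode
#'
#' @slot role "anode" or "cathode"
#' @slot shape "pad" (rectangular sponge pad) or "disc"
#' @slot size numeric; c(length, width) mm for a pad, diameter mm for a disc
#' @slot position list: either spherical angles \code{list(theta=, phi=)}
#'   in radians (colatitude from +z, azimuth from +x) for sphere-like heads,
#'   or \code{list(face=)} naming a slab face ("zmin","zmax","xmin",...)
#' @slot contactMedium "sponge" or "gel"
#' @slot contactThickness contact layer thickness (mm)
#' @slot conductorThickness metal conductor thickness (mm)
#' @exportClass Electrode
setClass("Electrode", representation(
  role = "character", shape = "character", size = "numeric",
  position = "list", contactMedium = "character",
  contactThickness = "numeric", conductorThickness = "numeric"))

setValidity("Electrode", function(object) {
  if (!object@role %in% c("anode", "cathode")) return("role must be anode|cathode")
  if (!object@shape %in% c("pad", "disc")) return("shape must be pad|disc")
  if (object@shape == "pad" && length(object@size) != 2L)
    return("pad size must be c(length, width) in mm")
  if (object@shape == "disc" && length(object@size) != 1L)
    return("disc size must be a single diameter in mm")
  if (any(object@size <= 0)) return("size must be > 0")
  if (!object@contactMedium %in% c("sponge", "gel"))
    return("contactMedium must be sponge|gel")
  if (object@contactThickness <= 0) return("contactThickness must be > 0")
  if (object@conductorThickness <= 0) return("conductorThickness must be > 0")
  TRUE
})

#' @rdname Electrode-class
#' @param role,shape,size,position,contactMedium,contactThickness,conductorThickness
#'   see slots; thickness defaults: sponge 5 mm, gel 2 mm, conductor 1 mm
#' @return An \code{Electrode}.
#' @export
electrode <- function(role, shape, size, position,
                      contactMedium = if (shape == "pad") "sponge" else "gel",
                      contactThickness = if (contactMedium == "sponge") 5 else 2,
                      conductorThickness = 1) {
  new("Electrode", role = role, shape = shape, size = as.numeric(size),
      position = position, contactMedium = contactMedium,
      contactThickness = as.numeric(contactThickness),
      conductorThickness = as.numeric(conductorThickness))
}

#' An electrode montage
#'
#' An ordered set of electrodes plus the total injected current. The
#' default total current is 1 mA, applied at the anode with the cathode(s)
#' grounded.
#'
#' @slot electrodes list of \code{Electrode}
#' @slot totalCurrent total injected current (A); default 1e-3
#' @slot name montage name
#' @exportClass Montage
setClass("Montage", representation(
  electrodes = "list", totalCurrent = "numeric", name = "character"))

setValidity("Montage", function(object) {
  roles <- vapply(object@electrodes, function(e) e@role, "")
  if (sum(roles == "anode") != 1L)
    return("montage must have exactly one anode")
  if (sum(roles == "cathode") < 1L)
    return("montage must have at least one cathode")
  if (object@totalCurrent <= 0) return("totalCurrent must be > 0")
  TRUE
})

#' A head with a rasterized montage
#'
#' A \code{LabelVolume} onto which electrode contact (sponge/gel) and
#' conductor voxels have been overlaid, plus bookkeeping of which voxels
#' belong to which electrode and where the external current is applied.
#'
#' @slot labels,voxelSize,labelCodes,center,provenance as in LabelVolume
#' @slot montage the rasterized \code{Montage}
#' @slot electrodeVoxels per-electrode list with linear voxel indices of
#'   \code{conductor} and \code{contact} voxels and \code{exteriorFaces}
#'   (per conductor voxel, number of faces open to air/grid boundary)
#' @exportClass RasterizedHead
setClass("RasterizedHead", contains = "LabelVolume",
         representation(montage = "Montage", electrodeVoxels = "list"))

#' Solver configuration
#'
#' @slot tolerance relative-residual stopping bound for conjugate gradients
#'   (default 1e-6)
#' @slot maxIterations iteration cap
#' @slot electrodeMode "resistive" (anode current as uniform Neumann flux
#'   over exterior conductor faces) or "equipotential" (anode conductor
#'   voxels merged into one floating-potential node carrying the total
#'   current)
#' @slot preconditioner "diagonal" (Jacobi) or "none"
#' @exportClass SolverConfig
setClass("SolverConfig", representation(
  tolerance = "numeric", maxIterations = "integer",
  electrodeMode = "character", preconditioner = "character"))

setValidity("SolverConfig", function(object) {
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!object@electrodeMode %in% c("resistive", "equipotential"))
    return("electrodeMode must be resistive|equipotential")
  if (!object@preconditioner %in% c("diagonal", "none"))
    return("preconditioner must be diagonal|none")
  TRUE
})

#' @rdname SolverConfig-class
#' @param tolerance,maxIterations,electrodeMode,preconditioner see slots
#' @return A \code{SolverConfig}.
#' @export
solverConfig <- function(tolerance = 1e-6, maxIterations = 50000L,
                         electrodeMode = "resistive",
                         preconditioner = "diagonal") {
  new("SolverConfig", tolerance = as.numeric(tolerance),
      maxIterations = as.integer(maxIterations),
      electrodeMode = electrodeMode, preconditioner = preconditioner)
}

#' Solved electric potential on the voxel grid
#'
#' @slot V 3-D numeric array of potentials (volts)
#' @slot voxelSize voxel edge length (mm)
#' @slot center head center (mm)
#' @slot reference description of the ground constraint
#' @exportClass PotentialField
setClass("PotentialField", representation(
  V = "array", voxelSize = "numeric", center = "numeric",
  reference = "character"))

#' Solve diagnostics and current audit
#'
#' @slot iterations CG iterations used
#' @slot finalRelResidual final relative residual
#' @slot converged logical
#' @slot tolerance requested tolerance
#' @slot residualHistory per-iteration relative residuals
#' @slot perElectrodeCurrent named numeric, current injected into the head
#'   through each electrode (A); anodes positive, cathodes negative
#' @slot conservationError |sum of per-electrode currents| (A)
#' @exportClass SolveReport
setClass("SolveReport", representation(
  iterations = "integer", finalRelResidual = "numeric",
  converged = "logical", tolerance = "numeric",
  residualHistory = "numeric", perElectrodeCurrent = "numeric",
  conservationError = "numeric"))

#' Electric-field volume E = -grad V
#'
#' @slot E 4-D numeric array (nx, ny, nz, 3) of field components (V/m)
#' @slot magnitude 3-D numeric array of |E| (V/m)
#' @slot voxelSize voxel edge length (mm)
#' @slot center head center (mm)
#' @exportClass EFieldVolume
setClass("EFieldVolume", representation(
  E = "array", magnitude = "array", voxelSize = "numeric",
  center = "numeric"))

setValidity("EFieldVolume", function(object) {
  if (length(dim(object@E)) != 4L || dim(object@E)[4] != 3L)
    return("E must be (nx, ny, nz, 3)")
  if (any(object@magnitude < 0)) return("magnitude must be >= 0")
  TRUE
})

#' Cortical (gray/CSF) interface with outward normals
#'
#' @slot coords n x 3 matrix of voxel indices of surface gray voxels
#' @slot index linear voxel indices into the grid
#' @slot normals n x 3 matrix of outward unit normals
#' @slot voxelSize voxel edge length (mm)
#' @slot center head center (mm)
#' @slot dims grid dimensions
#' @exportClass CorticalSurface
setClass("CorticalSurface", representation(
  coords = "matrix", index = "integer", normals = "matrix",
  voxelSize = "numeric", center = "numeric", dims = "integer"))

#' Cortical field map
#'
#' Field sampled on the cortical surface: magnitude |E| and signed normal
#' component. Sign convention: \code{efNormal = -E . n_outward}, so positive
#' values mean inward current (anodal, depolarizing) and negative values
#' outward current (hyperpolarizing).
#'
#' @slot surface the \code{CorticalSurface}
#' @slot efMagnitude |E| at surface locations (V/m)
#' @slot efNormal signed normal component (V/m), positive = inward
#' @exportClass CorticalMap
setClass("CorticalMap", representation(
  surface = "CorticalSurface", efMagnitude = "numeric",
  efNormal = "numeric"))

setValidity("CorticalMap", function(object) {
  n <- nrow(object@surface@coords)
  if (length(object@efMagnitude) != n || length(object@efNormal) != n)
    return("efMagnitude/efNormal must match surface size")
  if (any(abs(object@efNormal) > object@efMagnitude * (1 + 1e-9) + 1e-15))
    return("|efNormal| must not exceed efMagnitude")
  TRUE
})

#' Multilayer concentric-sphere model for the analytic oracle
#'
#' @slot radii outer radii of the layers (mm), strictly decreasing,
#'   outermost (scalp) first; the innermost entry is the core-ball radius
#' @slot sigmas matching conductivities (S/m)
#' @slot electrodeAngles 2 x 2 matrix, rows = (theta, phi) radians of the
#'   current injection (+I) and return (-I) points on the outer surface
#' @slot current injected current I (A)
#' @slot nTerms Legendre series truncation order (default 120)
#' @exportClass SphereModel
setClass("SphereModel", representation(
  radii = "numeric", sigmas = "numeric", electrodeAngles = "matrix",
  current = "numeric", nTerms = "integer"))

setValidity("SphereModel", function(object) {
  r <- object@radii
  if (any(r <= 0) || any(diff(r) >= 0))
    return("radii must be positive and strictly decreasing (outermost first)")
  if (length(object@sigmas) != length(r)) return("sigmas must match radii")
  if (any(object@sigmas <= 0)) return("sigmas must be > 0")
  if (!all(dim(object@electrodeAngles) == c(2L, 2L)))
    return("electrodeAngles must be 2 x 2 (rows: source, sink)")
  if (object@nTerms < 8L) return("nTerms must be >= 8")
  TRUE
})

#' @rdname SphereModel-class
#' @param radii,sigmas,electrodeAngles,current,nTerms see slots
#' @return A \code{SphereModel}.
#' @export
sphereModel <- function(radii, sigmas, electrodeAngles, current = 1e-3,
                        nTerms = 120L) {
  new("SphereModel", radii = as.numeric(radii), sigmas = as.numeric(sigmas),
      electrodeAngles = electrodeAngles, current = as.numeric(current),
      nTerms = as.integer(nTerms))
}

#' Dose normalization by current scaling
#'
#' Exploits linearity of the DC volume-conduction problem: scaling the
#' injected current scales the field everywhere by the same factor, so a
#' subject can be brought to a reference subject's peak cortical field by
#' multiplying the base current by referencePeak/subjectPeak.
#'
#' @slot scaleFactor referencePeak / subjectPeak (dimensionless)
#' @slot normalizedCurrent base current x scaleFactor (A)
#' @slot referenceSubject label of the reference head
#' @exportClass DoseNormalization
setClass("DoseNormalization", representation(
  scaleFactor = "numeric", normalizedCurrent = "numeric",
  referenceSubject = "character"))
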