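# Shared fixtures, built lazily and cached for the test run. Solves use a
# reduced head (60 mm outer radius at 2.5 mm voxels) so each conjugate-
# gradient solve stays in the tens of seconds; the geometry keeps every
# tissue layer at least one voxel thick.

.fx <- new.env(parent = emptyenv())

fxGet <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

smallHeadSpec <- function(voxel = 2.5) {
  sphereSpec(60, c(skin = 5, skull = 5, csf = 3, gray = 5),
             voxelSize = voxel)
}

solveMontage <- function(head, montage, table = defaultConductivities(),
                         config = solverConfig()) {
  raster <- rasterizeMontage(head, montage)
  sigma <- conductivityVolume(raster, table)
  sys <- assembleSystem(sigma, raster,
                        electrodeMode = config@electrodeMode)
  sol <- solvePotential(sys, config)
  ef <- efieldFromPotential(sol$potential, raster)
  surf <- tryCatch(corticalSurface(head), error = function(e) NULL)
  cmap <- if (!is.null(surf)) normalComponentMap(ef, surf) else NULL
  list(head = head, montage = montage, raster = raster, sigma = sigma,
       potential = sol$potential, report = sol$report, ef = ef,
       surf = surf, cmap = cmap)
}

fxHdSolve <- function() fxGet("hd", function() {
  head <- spherePhantom(smallHeadSpec())
  solveMontage(head, hdMontage4x1(head))
})

fxPadSolve <- function() fxGet("pad", function() {
  head <- spherePhantom(smallHeadSpec())
  solveMontage(head, padMontageM1SO(head))
})

fxGyratedPair <- function() fxGet("gyr", function() {
  spec <- smallHeadSpec()
  smooth <- spherePhantom(spec)
  gyr <- gyratedPhantom(spec, gyriSpec(amplitude = 6, wavenumber = 6,
                                       seed = 7L))
  list(smooth = solveMontage(smooth, hdMontage4x1(smooth)),
       gyrated = solveMontage(gyr, hdMontage4x1(gyr)))
})

fxSlabSolve <- function(current = 1e-3) {
  key <- paste0("slab", current)
  fxGet(key, function() {
    slab <- slabPhantom(c(96, 96, 48), label = "gray", voxelSize = 2,
                        paddingVoxels = 4L)
    m <- slabPlateMontage(slab, current = current)
    solveMontage(slab, m, table = conductivityTable(gray = 1.0))
  })
}
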