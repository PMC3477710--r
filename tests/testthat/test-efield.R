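test_that("a linear potential yields a uniform field of the right magnitude", {
  slab <- slabPhantom(c(40, 40, 40), label = "gray", voxelSize = 2)
  d <- dim(labels3d(slab))
  z <- array(rep((seq_len(d[3]) - 0.5) * 2, each = d[1] * d[2]), d)
  # V drops 0.001 V per mm along +z  ->  E = (0, 0, 1) V/m
  pot <- new("PotentialField", V = -0.001 * z, voxelSize = 2,
             center = headCenter(slab), reference = "synthetic")
  ef <- efieldFromPotential(pot, slab)
  inner <- labels3d(slab) == labelCodes()[["gray"]]
  expect_lt(max(abs(ef@E[, , , 1][inner])), 1e-12)
  expect_lt(max(abs(ef@E[, , , 2][inner])), 1e-12)
  expect_equal(max(abs(ef@E[, , , 3][inner] - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ef@magnitude[inner] - 1)), 0, tolerance = 1e-9)
})

test_that("magnitude is the Euclidean norm of the components", {
  fx <- fxHdSolve()
  m2 <- sqrt(fx$ef@E[, , , 1]^2 + fx$ef@E[, , , 2]^2 + fx$ef@E[, , , 3]^2)
  expect_equal(fx$ef@magnitude, m2)
  expect_true(all(fx$ef@magnitude >= 0))
})

test_that("cortical surface voxels sit at the gray outer radius with radial normals", {
  spec <- sphereSpec(60, c(skin = 5, skull = 5, csf = 3, gray = 5),
                     voxelSize = 2)
  head <- spherePhantom(spec)
  surf <- corticalSurface(head)
  h <- voxelSize(head)
  xyz <- tdcssim:::voxelXYZ(surf@index, dim(labels3d(head)), h,
                            headCenter(head))
  r <- sqrt(rowSums(xyz^2))
  rGray <- 60 - 5 - 5 - 3
  # surface voxel centers within one voxel of the nominal interface
  expect_true(all(abs(r - rGray) <= h))
  expect_gt(median(abs(r - rGray) <= h / 2), 0.5)
  # unit normals, within 5 degrees of radial for 95% of locations
  expect_lt(max(abs(sqrt(rowSums(surf@normals^2)) - 1)), 1e-6)
  cosang <- rowSums(surf@normals * (xyz / r))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  expect_lt(as.numeric(stats::quantile(ang, 0.95)), 5)
})

test_that("gyrated surfaces reach down into the fold troughs", {
  spec <- sphereSpec(60, c(skin = 5, skull = 5, csf = 3, gray = 5),
                     voxelSize = 2)
  gyr <- gyratedPhantom(spec, gyriSpec(6, 6, seed = 7L))
  surf <- corticalSurface(gyr)
  xyz <- tdcssim:::voxelXYZ(surf@index, dim(labels3d(gyr)), 2,
                            headCenter(gyr))
  rGraySmooth <- 60 - 5 - 5 - 3
  expect_lt(min(sqrt(rowSums(xyz^2))), rGraySmooth - 3)
  # no gray/CSF adjacency -> error
  slab <- slabPhantom(c(20, 20, 10), label = "white", voxelSize = 2)
  expect_error(corticalSurface(slab), "gray")
})

test_that("normal-component maps follow the inward-positive convention", {
  spec <- sphereSpec(60, c(skin = 5, skull = 5, csf = 3, gray = 5),
                     voxelSize = 2)
  head <- spherePhantom(spec)
  surf <- corticalSurface(head)
  d <- dim(labels3d(head))
  xyz <- tdcssim:::voxelXYZ(seq_len(prod(d)), d, 2, headCenter(head))
  r <- pmax(sqrt(rowSums(xyz^2)), 1e-9)
  mkEF <- function(vec3) {
    E <- array(0, c(d, 3))
    for (ax in 1:3) E[, , , ax] <- array(vec3[, ax], d)
    new("EFieldVolume", E = E,
        magnitude = array(sqrt(rowSums(vec3^2)), d),
        voxelSize = 2, center = headCenter(head))
  }
  # purely radial inward field: E = -c * rhat  ->  efNormal = +magnitude
  cmapIn <- normalComponentMap(mkEF(-0.25 * xyz / r), surf)
  expect_equal(cmapIn@efNormal, cmapIn@efMagnitude, tolerance = 0.01)
  # purely tangential field -> efNormal ~ 0
  tang <- cbind(-xyz[, 2], xyz[, 1], 0) / r
  cmapT <- normalComponentMap(mkEF(0.3 * tang), surf)
  expect_lt(max(abs(cmapT@efNormal)) / 0.3, 0.12)
  expect_lt(stats::median(abs(cmapT@efNormal)) / 0.3, 0.05)
})

test_that("cortical maps from a solve satisfy the Cauchy-Schwarz bound", {
  fx <- fxHdSolve()
  expect_true(all(abs(fx$cmap@efNormal) <= fx$cmap@efMagnitude + 1e-15))
  # surface peak cannot exceed the gray-matter volume peak
  gray <- labels3d(fx$head) == labelCodes()[["gray"]]
  expect_lte(max(fx$cmap@efMagnitude), max(fx$ef@magnitude[gray]))
})

test_that("the HD anode drives net inward current under the disc", {
  fx <- fxHdSolve()
  an <- electrodes(fx$montage)$anode
  u0 <- tdcssim:::unitVec(an@position$theta, an@position$phi)
  surf <- fx$cmap@surface
  xyz <- tdcssim:::voxelXYZ(surf@index, surf@dims, surf@voxelSize,
                            surf@center)
  r <- sqrt(rowSums(xyz^2))
  under <- acos(pmin(1, (xyz %*% u0) / r)) * 60 <= 15  # ~15 mm geodesic
  expect_gt(mean(fx$cmap@efNormal[under]), 0)
})

test_that("cross-sections partition the volume and mirror the slab oracle", {
  fx <- fxSlabSolve()
  d <- dim(fx$ef@magnitude)
  sl <- crossSection(fx$ef, "z", d[3] %/% 2)
  expect_identical(dim(sl$values), d[1:2])
  inner <- sl$values[8:(d[1] - 8), 8:(d[2] - 8)]
  expected <- 1e-3 / 0.096^2
  expect_lt(max(abs(inner - expected)) / expected, 0.01)
  # restacking all z-slices rebuilds the volume
  stack <- simplify2array(lapply(seq_len(d[3]), function(k)
    crossSection(fx$ef, 3, k)$values))
  expect_identical(stack, fx$ef@magnitude)
  expect_error(crossSection(fx$ef, 3, d[3] + 1), "range")
})

test_that("sphere cross-sections show current channeled into the CSF ring", {
  # the conductivity contrast drives current into CSF: the annular CSF
  # ring carries far more current density J = sigma |E| than the skull,
  # while |E| itself is higher in the resistive skull (E = J / sigma)
  fx <- fxHdSolve()
  d <- dim(fx$ef@magnitude)
  k <- d[3] %/% 2
  sl <- crossSection(fx$ef, 3, k)
  lab <- labels3d(fx$raster)[, , k]
  codes <- labelCodes()
  jCsf <- 1.65 * stats::median(sl$values[lab == codes[["csf"]]])
  jSkull <- 0.01 * stats::median(sl$values[lab == codes[["skull"]]])
  expect_gt(jCsf, jSkull)
  expect_gt(stats::median(sl$values[lab == codes[["skull"]]]),
            stats::median(sl$values[lab == codes[["csf"]]]))
})

test_that("rotating the montage 90 degrees rotates the solution with it", {
  spec <- sphereSpec(50, c(skin = 4, skull = 4, csf = 3, gray = 5),
                     voxelSize = 2.5, margin = 7.5)
  head <- spherePhantom(spec)
  mk <- function(phi) {
    defaults <- montageDefaults()
    d <- defaults$hd_4x1
    e <- list(
      anode = electrode("anode", "disc", d$disc_diameter_mm,
                        list(theta = pi / 4, phi = phi)),
      cathode = electrode("cathode", "disc", d$disc_diameter_mm,
                          list(theta = 3 * pi / 4, phi = phi + pi)))
    new("Montage", electrodes = e, totalCurrent = 1e-3, name = "rot")
  }
  fx0 <- solveMontage(head, mk(0))
  fx90 <- solveMontage(head, mk(pi / 2))
  # rotate the phi = 0 solution by +90 degrees about z: (x,y) -> (-y,x)
  d <- dim(fx0$ef@magnitude)
  rot <- aperm(fx0$ef@magnitude, c(2, 1, 3))[d[2]:1, , ]
  tissue <- labels3d(head) != labelCodes()[["air"]]
  num <- sqrt(sum((fx90$ef@magnitude[tissue] - rot[tissue])^2))
  den <- sqrt(sum(rot[tissue]^2))
  expect_lt(num / den, 0.02)
})
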