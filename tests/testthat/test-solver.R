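test_that("face conductances use the harmonic mean of voxel conductivities", {
  # two-voxel check through the assembled operator: carve one skull voxel
  # into a CSF slab and inspect the coupling entry
  slab <- slabPhantom(c(20, 20, 12), label = "csf", voxelSize = 2,
                      paddingVoxels = 2L)
  lab <- labels3d(slab)
  codes <- labelCodes()
  d <- dim(lab)
  i0 <- c(d[1] %/% 2, d[2] %/% 2, d[3] %/% 2)
  lab[i0[1], i0[2], i0[3]] <- codes[["skull"]]
  vol <- new("LabelVolume", labels = lab, voxelSize = 2,
             labelCodes = codes, center = slab@center,
             provenance = slab@provenance)
  ras <- rasterizeMontage(vol, slabPlateMontage(vol))
  sig <- conductivityVolume(ras, defaultConductivities())
  sys <- assembleSystem(sig, ras)
  a <- i0[1] + (i0[2] - 1) * d[1] + (i0[3] - 1) * d[1] * d[2]
  b <- a + 1L  # csf neighbor in +x
  h <- 2e-3
  gExpect <- h * 2 / (1 / 0.01 + 1 / 1.65)   # = h * 0.019880...
  expect_equal(sys$A[sys$uid[a], sys$uid[b]], -gExpect, tolerance = 1e-12)
  expect_equal(2 / (1 / 0.01 + 1 / 1.65), 0.01988, tolerance = 1e-3)
  # equal conductivities reduce to the plain conductance sigma * h
  b2 <- a + as.integer(d[1] * d[2])          # csf-csf pair in +z
  a2 <- b2 + as.integer(d[1] * d[2])
  expect_equal(sys$A[sys$uid[a2], sys$uid[b2]], -h * 1.65,
               tolerance = 1e-12)
})

test_that("interior operator rows away from sources and ground sum to zero", {
  fx <- fxSlabSolve()
  sys <- assembleSystem(fx$sigma, fx$raster)
  rs <- Matrix::rowSums(sys$A)
  # rows coupled to a Dirichlet (cathode) voxel keep that conductance on
  # the diagonal; all other rows are exactly conservative
  cath <- fx$raster@electrodeVoxels$cathode$conductor
  nearDirichlet <- unique(unlist(lapply(
    c(-1L, 1L, -sys$dims[1], sys$dims[1],
      -sys$dims[1] * sys$dims[2], sys$dims[1] * sys$dims[2]),
    function(off) cath + off)))
  nearDirichlet <- nearDirichlet[nearDirichlet >= 1 &
                                   nearDirichlet <= prod(sys$dims)]
  freeRows <- setdiff(seq_len(sys$nUnknowns),
                      sys$uid[nearDirichlet[sys$uid[nearDirichlet] > 0]])
  relRs <- abs(rs) / Matrix::diag(sys$A)
  expect_lt(max(relRs[freeRows]), 1e-12)
})

test_that("homogeneous slab with plate electrodes reproduces Ohm's law", {
  fx <- fxSlabSolve()
  # |E| = I/(A sigma) = 1e-3 / (0.096^2 * 1) V/m, uniform mid-slab
  expected <- 1e-3 / (0.096^2 * 1.0)
  d <- dim(fx$ef@magnitude)
  mid <- fx$ef@magnitude[d[1] %/% 2, d[2] %/% 2, d[3] %/% 2]
  expect_lt(abs(mid - expected) / expected, 0.01)
  # and away from the edges across the whole mid-slice
  k <- d[3] %/% 2
  inner <- fx$ef@magnitude[8:(d[1] - 8), 8:(d[2] - 8), k]
  expect_lt(max(abs(inner - expected)) / expected, 0.01)
})

test_that("slab field error vs closed form is never worse on finer grids", {
  # grid-aligned layered media are reproduced exactly by the harmonic-mean
  # scheme, so the closed-form error sits at the solver-tolerance floor at
  # every resolution; it must stay there (non-increasing beyond round-off)
  err <- vapply(c(4, 2, 1), function(h) {
    slab <- slabPhantom(c(48, 48, 24), label = "gray", voxelSize = h,
                        paddingVoxels = max(2L, as.integer(8 / h)))
    m <- slabPlateMontage(slab, current = 1e-3,
                          contactThickness = 4, conductorThickness = 4)
    fx <- solveMontage(slab, m, table = conductivityTable(gray = 1.0))
    expected <- 1e-3 / (0.048^2)
    d <- dim(fx$ef@magnitude)
    mid <- fx$ef@magnitude[d[1] %/% 2, d[2] %/% 2, d[3] %/% 2]
    abs(mid - expected) / expected
  }, 0)
  expect_true(all(err < 1e-5))
  expect_true(all(diff(err) <= 1e-6))
})

test_that("doubling the injected current doubles the potential (linearity)", {
  fx1 <- fxSlabSolve()
  fx2 <- fxSlabSolve(current = 2e-3)
  tol <- fx1$report@tolerance
  scale <- max(abs(fx1$potential@V))
  expect_lt(max(abs(fx2$potential@V - 2 * fx1$potential@V)) / (2 * scale),
            10 * tol)
})

test_that("electrode current audit balances the 1 mA pad solve", {
  fx <- fxPadSolve()
  cur <- fx$report@perElectrodeCurrent
  expect_equal(unname(cur["anode"]), 1e-3, tolerance = 1e-3)
  expect_equal(unname(cur["cathode"]), -1e-3, tolerance = 1e-3)
  expect_lt(fx$report@conservationError, 1e-3 * 1e-3)
  expect_lte(fx$report@finalRelResidual, fx$report@tolerance)
})

test_that("symmetric HD ring splits the return current four ways", {
  fx <- fxHdSolve()
  cur <- fx$report@perElectrodeCurrent
  expect_equal(unname(cur["anode"]), 1e-3, tolerance = 1e-3)
  for (nm in paste0("cathode", 1:4))
    expect_equal(unname(cur[nm]), -0.25e-3, tolerance = 0.01)
  expect_lt(fx$report@conservationError, 1e-3 * 1e-3)
})

test_that("a cathode moved closer to the anode draws more than its share", {
  head <- spherePhantom(sphereSpec(50, c(skin = 4, skull = 4, csf = 3,
                                         gray = 5), voxelSize = 2.5,
                                   margin = 8))
  m <- hdMontage4x1(head)
  # pull cathode1 halfway in along its meridian
  an <- electrodes(m)$anode
  c1 <- electrodes(m)$cathode1
  u0 <- tdcssim:::unitVec(an@position$theta, an@position$phi)
  u1 <- tdcssim:::unitVec(c1@position$theta, c1@position$phi)
  gam <- acos(sum(u0 * u1)) / 2
  dir <- (u1 - sum(u0 * u1) * u0)
  dir <- dir / sqrt(sum(dir^2))
  uNew <- cos(gam) * u0 + sin(gam) * dir
  c1@position <- list(theta = acos(uNew[3]), phi = atan2(uNew[2], uNew[1]))
  m@electrodes$cathode1 <- c1
  fx <- solveMontage(head, m)
  cur <- fx$report@perElectrodeCurrent
  expect_gt(abs(cur[["cathode1"]]), 0.25e-3)
  expect_gt(abs(cur[["cathode1"]]), max(abs(cur[paste0("cathode", 2:4)])))
})

test_that("resistive and equipotential anode modes agree on tissue fields", {
  head <- spherePhantom(sphereSpec(50, c(skin = 4, skull = 4, csf = 3,
                                         gray = 5), voxelSize = 2.5,
                                   margin = 8))
  m <- hdMontage4x1(head)
  fxR <- solveMontage(head, m, config = solverConfig())
  fxE <- solveMontage(head, m,
                      config = solverConfig(electrodeMode = "equipotential"))
  gray <- labels3d(head) == labelCodes()[["gray"]]
  eR <- fxR$ef@magnitude[gray]
  eE <- fxE$ef@magnitude[gray]
  expect_lt(sqrt(sum((eR - eE)^2) / sum(eR^2)), 0.01)
})

test_that("potential extrema sit at the electrodes, not inside tissue", {
  fx <- fxHdSolve()
  lab <- labels3d(fx$raster)
  codes <- labelCodes()
  tissue <- lab %in% codes[c("skin", "skull", "csf", "gray", "white")]
  elec <- lab %in% codes[c("electrode", "sponge", "gel")]
  vmax <- max(fx$potential@V[elec])
  expect_lte(max(fx$potential@V[tissue]), vmax * (1 + 1e-6))
  # the ground (minimum) is on the cathode conductors by construction
  expect_gte(min(fx$potential@V[tissue]), min(fx$potential@V) - 1e-12)
})

test_that("non-convergence raises a structured error carrying the residuals", {
  fx <- fxSlabSolve()
  sys <- assembleSystem(fx$sigma, fx$raster)
  err <- tryCatch(solvePotential(sys, solverConfig(maxIterations = 5L)),
                  error = function(e) e)
  expect_s3_class(err, "tdcsConvergenceError")
  expect_length(err$residualHistory, 5L)
  expect_true(all(diff(err$residualHistory) < Inf))
})

test_that("solves are deterministic (bit-identical residual histories)", {
  fx <- fxSlabSolve()
  sys <- assembleSystem(fx$sigma, fx$raster)
  s1 <- solvePotential(sys)
  s2 <- solvePotential(sys)
  expect_identical(s1$report@residualHistory, s2$report@residualHistory)
  expect_identical(s1$potential@V, s2$potential@V)
})
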