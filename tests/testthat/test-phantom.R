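test_that("layered sphere shells classify correctly at center and beyond scalp", {
  spec <- sphereSpec(92, c(skin = 7, skull = 5, csf = 2, gray = 3),
                     voxelSize = 2)
  head <- spherePhantom(spec)
  codes <- labelCodes()
  d <- dim(labels3d(head))
  ctr <- round(d / 2)
  expect_identical(labels3d(head)[ctr[1], ctr[2], ctr[3]],
                   codes[["white"]])
  expect_identical(labels3d(head)[1, 1, 1], codes[["air"]])
  # every voxel farther than the outer radius is air (brute-force check)
  r <- sqrt(rowSums(sweep(
    tdcssim:::voxelXYZ(seq_len(prod(d)), d, 2, headCenter(head)),
    2, 0)^2))
  expect_true(all(labels3d(head)[r > 92] == codes[["air"]]))
})

test_that("skull shell voxel count matches brute-force distance classification", {
  spec <- sphereSpec(92, c(skin = 7, skull = 5, csf = 2, gray = 3),
                     voxelSize = 1)
  head <- spherePhantom(spec)
  # independent oracle: classify each voxel center by its distance
  d <- dim(labels3d(head))
  h <- voxelSize(head)
  ctr <- headCenter(head)
  cx <- (seq_len(d[1]) - 0.5) * h - ctr[1]
  r <- sqrt(outer(outer(cx^2, cx^2, "+"), cx^2, "+"))
  brute <- sum(r > 80 & r <= 85)
  expect_identical(unname(labelCounts(head)[["skull"]]), brute)
  # and the count is within 2% of the analytic shell volume
  analytic <- 4 / 3 * pi * (85^3 - 80^3)
  expect_lt(abs(brute - analytic) / analytic, 0.02)
})

test_that("per-label counts conserve the grid volume across generators", {
  spec <- sphereSpec(50, c(skin = 4, skull = 4, csf = 3, gray = 5),
                     voxelSize = 2)
  for (vol in list(spherePhantom(spec),
                   gyratedPhantom(spec, gyriSpec(5, 4, seed = 3L)),
                   slabPhantom(c(40, 40, 20), voxelSize = 2))) {
    expect_identical(sum(labelCounts(vol)), length(labels3d(vol)))
  }
})

test_that("shell volume error shrinks monotonically with voxel size", {
  err <- vapply(c(2, 1, 0.5), function(h) {
    spec <- sphereSpec(40, c(skin = 4, skull = 3, csf = 2, gray = 3),
                       voxelSize = h, margin = 5)
    cnt <- labelCounts(spherePhantom(spec))
    analytic <- 4 / 3 * pi * (36^3 - 33^3)        # skull shell
    abs(cnt[["skull"]] * h^3 - analytic) / analytic
  }, 0)
  expect_true(all(diff(err) <= 0))
})

test_that("generators are deterministic", {
  spec <- sphereSpec(45, c(skin = 4, skull = 4, csf = 3, gray = 4),
                     voxelSize = 2, margin = 6)
  expect_identical(labels3d(spherePhantom(spec)),
                   labels3d(spherePhantom(spec)))
  g <- gyriSpec(5, 5, seed = 11L)
  expect_identical(labels3d(gyratedPhantom(spec, g)),
                   labels3d(gyratedPhantom(spec, g)))
})

test_that("zero-amplitude gyration degenerates to the smooth sphere", {
  spec <- sphereSpec(45, c(skin = 4, skull = 4, csf = 3, gray = 4),
                     voxelSize = 2, margin = 6)
  expect_identical(labels3d(gyratedPhantom(spec, gyriSpec(0, 4))),
                   labels3d(spherePhantom(spec)))
})

test_that("gyration seeds change the folds but nearly preserve gray volume", {
  spec <- sphereSpec(55, c(skin = 4, skull = 4, csf = 4, gray = 6),
                     voxelSize = 2)
  v1 <- gyratedPhantom(spec, gyriSpec(6, 6, seed = 1L))
  v2 <- gyratedPhantom(spec, gyriSpec(6, 6, seed = 2L))
  expect_false(identical(labels3d(v1), labels3d(v2)))
  g1 <- labelCounts(v1)[["gray"]]
  g2 <- labelCounts(v2)[["gray"]]
  expect_lt(abs(g1 - g2) / g1, 0.05)
})

test_that("tissue shells stay radially nested", {
  spec <- sphereSpec(45, c(skin = 4, skull = 4, csf = 3, gray = 4),
                     voxelSize = 1, margin = 6)
  rank <- c(white = 1L, gray = 2L, csf = 3L, skull = 4L, skin = 5L,
            air = 6L)
  codes <- labelCodes()
  rankOf <- function(lab) {
    m <- match(lab, codes[names(rank)])
    rank[m]
  }
  head <- spherePhantom(spec)
  d <- dim(labels3d(head))
  ctr <- round(d / 2)
  # sample rays along axes and a diagonal: label rank never decreases
  rays <- list(cbind(ctr[1]:d[1], ctr[2], ctr[3]),
               cbind(ctr[1], ctr[2]:d[2], ctr[3]),
               cbind(ctr[1]:d[1], ctr[2]:d[2], ctr[3]:d[3]))
  for (ray in rays) {
    labs <- labels3d(head)[ray]
    expect_true(all(diff(rankOf(labs)) >= 0))
  }
  # gyrated: nesting may repeat gray/csf inside the fold band, but the
  # outer shells (skull outward) are untouched
  gyr <- gyratedPhantom(spec, gyriSpec(5, 5, seed = 2L))
  expect_identical(labels3d(gyr) >= codes[["skull"]] &
                     labels3d(gyr) != codes[["air"]],
                   labels3d(head) >= codes[["skull"]] &
                     labels3d(head) != codes[["air"]])
})

test_that("slab phantom is a homogeneous box with air padding", {
  slab <- slabPhantom(c(100, 100, 50), label = "gray", voxelSize = 2,
                      paddingVoxels = 1L)
  cnt <- labelCounts(slab)
  expect_identical(unname(cnt[["gray"]]),
                   as.integer(100 * 100 * 50 / 2^3))
  d <- dim(labels3d(slab))
  expect_true(all(labels3d(slab)[2:(d[1] - 1), 2:(d[2] - 1),
                                 2:(d[3] - 1)] == labelCodes()[["gray"]]))
  # conductivity lookup through a CSF slab is uniform 1.65 S/m inside
  csfSlab <- slabPhantom(c(20, 20, 10), label = "csf", voxelSize = 2)
  sig <- conductivityVolume(csfSlab, defaultConductivities())
  inside <- labels3d(csfSlab) == labelCodes()[["csf"]]
  expect_true(all(sig[inside] == 1.65))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(sphereSpec(92, c(skin = -1, skull = 5, csf = 2, gray = 3)),
               "thickness")
  expect_error(sphereSpec(10, c(skin = 4, skull = 4, csf = 1, gray = 0.5),
                          voxelSize = 1), "outerRadius")
  expect_error(sphereSpec(30, c(skin = 4, skull = 4, csf = 1, gray = 3),
                          voxelSize = 2), "voxelSize")
  spec <- sphereSpec(45, c(skin = 4, skull = 4, csf = 3, gray = 4),
                     voxelSize = 2, margin = 6)
  expect_error(gyratedPhantom(spec, gyriSpec(10, 4)), "amplitude")
  expect_error(gyriSpec(3, 1), "wavenumber")
  expect_error(slabPhantom(c(-10, 10, 10)), "extent")
})

test_that("subject presets emulate the intended anatomical spread", {
  subs <- subjectPresets(voxelSize = 2)
  expect_named(subs, c("M1", "M2", "F"))
  radii <- vapply(subs, function(s) s@outerRadius, 0)
  skulls <- vapply(subs, function(s) s@thickness[["skull"]], 0)
  expect_lt(diff(range(radii)) / max(radii), 0.15)
  expect_true(all(skulls >= 4 & skulls <= 7))
})
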