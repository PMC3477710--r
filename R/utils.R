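# Internal grid helpers. All physical lengths in mm unless noted; voxel
# (i,j,k) center sits at ((i-0.5)h, (j-0.5)h, (k-0.5)h).

voxelCenters1d <- function(n, h) (seq_len(n) - 0.5) * h

# squared distance from `center` at every voxel center
radius2Array <- function(dims, h, center) {
  dx2 <- (voxelCenters1d(dims[1], h) - center[1])^2
  dy2 <- (voxelCenters1d(dims[2], h) - center[2])^2
  dz2 <- (voxelCenters1d(dims[3], h) - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

radiusArray <- function(dims, h, center) sqrt(radius2Array(dims, h, center))

# physical coordinates (mm, relative to center) of linear voxel indices
voxelXYZ <- function(index, dims, h, center) {
  index <- index - 1L
  i <- index %% dims[1]
  j <- (index %/% dims[1]) %% dims[2]
  k <- index %/% (dims[1] * dims[2])
  cbind((i + 0.5) * h - center[1],
        (j + 0.5) * h - center[2],
        (k + 0.5) * h - center[3])
}

# unit direction on the sphere for colatitude theta (from +z), azimuth phi
unitVec <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# local tangent frame at (theta, phi): e1 along increasing theta, e2 along
# increasing phi
tangentFrame <- function(theta, phi) {
  list(e1 = c(cos(theta) * cos(phi), cos(theta) * sin(phi), -sin(theta)),
       e2 = c(-sin(phi), cos(phi), 0))
}

# zero-padded shift of a 3-D array by `by` voxels along `axis`
shift3d <- function(arr, axis, by) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- (by + 1L):n; src[[axis]] <- 1L:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1L:(n + by); src[[axis]] <- (1L - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# separable Gaussian smoothing (sigma in voxels), truncated at 3 sigma;
# renormalized at the array edges via smoothing of a ones-array
smooth3d <- function(arr, sigmaVox = 1.5) {
  r <- max(1L, ceiling(3 * sigmaVox))
  w <- exp(-((-r):r)^2 / (2 * sigmaVox^2))
  w <- w / sum(w)
  sm <- function(x) {
    for (axis in 1:3) {
      acc <- x * w[r + 1L]
      for (k in seq_len(r)) {
        acc <- acc + w[r + 1L + k] * (shift3d(x, axis, k) +
                                        shift3d(x, axis, -k))
      }
      x <- acc
    }
    x
  }
  sm(arr) / sm(array(1, dim(arr)))
}

# hash an R object (used for study caching); md5 of its serialization
hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
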