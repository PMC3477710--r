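# Legendre-series solution for an N-layer concentric sphere with two point
# current electrodes (+I, -I) on the outer surface. Within layer k (outer
# radius R_k) each harmonic degree l contributes
#   V_l(r) = A_kl (r/R_k)^l + B_kl (R_k/r)^(l+1),
# with A, B fixed per degree by continuity of V and sigma dV/dr across the
# interfaces, regularity at the origin, and the surface flux condition
#   sigma_1 dV/dr(R_1) = I (2l+1) / (4 pi R_1^2)
# (the Legendre expansion of a point current source; the l = 0 monopole
# cancels between the two electrodes). The radius-ratio parametrization
# keeps the per-degree 2x2 recursion numerically stable at high degree.

# per-degree coefficients, scaled for injected current I; returns K x L
# matrices cA, cB (SI units)
sphereLayerCoeffs <- function(radiiM, sigmas, current, L) {
  K <- length(radiiM)
  cA <- cB <- matrix(0, K, L)
  for (l in seq_len(L)) {
    A <- numeric(K); B <- numeric(K)
    A[K] <- 1
    if (K > 1) {
      for (k in (K - 1):1) {
        Vp <- A[k + 1] + B[k + 1]
        W <- (sigmas[k + 1] / sigmas[k]) *
          (l * A[k + 1] - (l + 1) * B[k + 1])
        P <- ((l + 1) * Vp + W) / (2 * l + 1)
        Q <- (l * Vp - W) / (2 * l + 1)
        rho <- radiiM[k + 1] / radiiM[k]
        A[k] <- P * rho^(-l)
        B[k] <- Q * rho^(l + 1)
      }
    }
    denom <- sigmas[1] * (l * A[1] - (l + 1) * B[1])
    cl <- current * (2 * l + 1) / (4 * pi * radiiM[1] * denom)
    if (!is.finite(cl))
      stop("non-finite series coefficient at degree ", l,
           "; model is ill-conditioned")
    cA[, l] <- cl * A
    cB[, l] <- cl * B
  }
  list(cA = cA, cB = cB)
}

sphereSeriesEval <- function(model, points, needE = FALSE,
                             seriesTol = 1e-5) {
  radiiM <- model@radii * 1e-3
  pts <- as.matrix(points) * 1e-3
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  r <- sqrt(rowSums(pts^2))
  if (any(r > radiiM[1] * (1 + 1e-9)))
    stop("query point(s) outside the outer radius")
  r <- pmin(r, radiiM[1])
  if (any(r == 0)) stop("query at the center is ambiguous; offset slightly")
  K <- length(radiiM)
  # layer index: largest k with r <= R_k
  layer <- vapply(r, function(ri) max(which(ri <= radiiM + 1e-12)), 1L)
  Rk <- radiiM[layer]
  rhat <- pts / r

  u1 <- unitVec(model@electrodeAngles[1, 1], model@electrodeAngles[1, 2])
  u2 <- unitVec(model@electrodeAngles[2, 1], model@electrodeAngles[2, 2])
  cos1 <- clamp(as.vector(rhat %*% u1), -1, 1)
  cos2 <- clamp(as.vector(rhat %*% u2), -1, 1)
  atEl <- (r > radiiM[1] * (1 - 1e-9)) & (pmax(cos1, cos2) > 1 - 1e-9)
  if (any(atEl))
    stop("query point coincides with an electrode point")

  L <- model@nTerms
  cf <- sphereLayerCoeffs(radiiM, model@sigmas, model@current, L)
  n <- length(r)
  xr <- r / Rk          # ratio for the growing radial term
  yr <- Rk / r          # ratio for the decaying radial term
  xp <- rep(1, n)       # (r/Rk)^l, updated multiplicatively
  yp <- yr              # (Rk/r)^(l+1)
  P1prev <- rep(1, n); P1cur <- cos1   # P_{l-1}, P_l, starting at l = 1
  P2prev <- rep(1, n); P2cur <- cos2
  V <- numeric(n)
  dVdr <- numeric(n)
  T1 <- T2 <- numeric(n)            # angular accumulators per electrode
  sin1 <- sqrt(pmax(0, 1 - cos1^2))
  sin2 <- sqrt(pmax(0, 1 - cos2^2))
  # the tail bound uses the last three degrees: a single term can dip
  # through a Legendre zero and fake convergence
  tailTerms <- numeric(3)

  for (l in seq_len(L)) {
    if (l > 1) {
      P1new <- ((2 * l - 1) * cos1 * P1cur - (l - 1) * P1prev) / l
      P2new <- ((2 * l - 1) * cos2 * P2cur - (l - 1) * P2prev) / l
      P1prev <- P1cur; P1cur <- P1new
      P2prev <- P2cur; P2cur <- P2new
    }
    xp <- xp * xr
    yp <- yp * yr
    a <- cf$cA[cbind(layer, l)]
    b <- cf$cB[cbind(layer, l)]
    # the decaying term vanishes in the core layer (B = 0) where
    # (Rk/r)^(l+1) can overflow; 0 * Inf must stay 0
    dec <- b * yp
    dec[b == 0] <- 0
    f <- a * xp + dec
    term <- f * (P1cur - P2cur)
    V <- V + term
    tailTerms[1 + (l %% 3)] <- max(abs(term))
    if (needE) {
      dVdr <- dVdr + (l * a * xp - (l + 1) * dec) / r *
        (P1cur - P2cur)
      # dP_l/dgamma = -sin(gamma) P_l'(cos gamma), with
      # (x^2 - 1) P_l' = l (x P_l - P_{l-1})
      dP1 <- dLegendreGamma(l, cos1, sin1, P1cur, P1prev)
      dP2 <- dLegendreGamma(l, cos2, sin2, P2cur, P2prev)
      T1 <- T1 + f * dP1
      T2 <- T2 + f * dP2
    }
  }
  # scale for the tail bound: the larger of the evaluated potentials and
  # the model's characteristic potential I/(4 pi sigma_1 R_1), so batches
  # of near-zero potentials (e.g. on a symmetry plane) are not penalized
  vScale <- max(max(abs(V)),
                model@current / (4 * pi * model@sigmas[1] * radiiM[1]))
  lastTerm <- max(tailTerms)
  if (lastTerm / vScale > seriesTol)
    stop(sprintf(paste0(
      "Legendre series not converged at n_terms = %d (last-term bound ",
      "%.2g of the solution); increase n_terms"), L, lastTerm / vScale))

  out <- list(V = V)
  if (needE) {
    g1 <- gammaHat(rhat, cos1, sin1, u1)
    g2 <- gammaHat(rhat, cos2, sin2, u2)
    E <- -(dVdr * rhat) - (T1 / r) * g1 + (T2 / r) * g2
    out$E <- E
  }
  out
}

# -sin(gamma) * P_l'(x): the gamma-derivative of P_l(cos gamma)
dLegendreGamma <- function(l, x, sing, Pl, Plm1) {
  denom <- x^2 - 1
  small <- abs(denom) < 1e-14
  dP <- numeric(length(x))
  dP[!small] <- -sing[!small] * l *
    (x[!small] * Pl[!small] - Plm1[!small]) / denom[!small]
  # at the poles sin(gamma) = 0 and the tangential derivative vanishes
  dP[small] <- 0
  dP
}

# unit vector of increasing gamma (away from the electrode axis u)
gammaHat <- function(rhat, cosg, sing, u) {
  g <- (cosg * rhat - matrix(u, nrow(rhat), 3, byrow = TRUE))
  g <- g / ifelse(sing > 1e-12, sing, 1)
  g[sing <= 1e-12, ] <- 0
  g
}

#' Analytic potential in a multilayer sphere
#'
#' Closed-form Legendre-series potential of an N-layer concentric-sphere
#' head with two point current electrodes (+I and -I) on the scalp. Serves
#' as the independent oracle for validating the voxel finite-volume solver.
#'
#' @param model a \code{\link{sphereModel}}
#' @param points n x 3 matrix of query coordinates (mm, relative to the
#'   sphere center); must lie inside the outer radius and away from the
#'   electrode points
#' @param seriesTol bound on the relative size of the last retained series
#'   term; exceeding it raises an error suggesting a larger \code{nTerms}
#' @return Numeric vector of potentials (V).
#' @export
spherePotential <- function(model, points, seriesTol = 1e-5) {
  validObject(model)
  sphereSeriesEval(model, points, needE = FALSE, seriesTol = seriesTol)$V
}

#' Analytic electric field in a multilayer sphere
#'
#' Term-by-term analytic gradient of \code{\link{spherePotential}}.
#'
#' @inheritParams spherePotential
#' @return n x 3 matrix of field vectors (V/m).
#' @export
sphereEField <- function(model, points, seriesTol = 1e-5) {
  validObject(model)
  sphereSeriesEval(model, points, needE = TRUE, seriesTol = seriesTol)$E
}

#' Compare the voxel solver against the sphere oracle
#'
#' Runs the oracle at the centers of selected voxels and reports the
#' relative L2 discrepancy of the (demeaned) potential and of |E| over
#' those voxels. The potential is compared after removing each field's
#' mean over the comparison set, since the numerical ground (cathode
#' V = 0) and the series reference differ by a constant. Voxels within an
#' exclusion radius of either electrode point are omitted: the rasterized
#' disc electrodes and the oracle's point electrodes legitimately differ
#' in the near field.
#'
#' @param potential solved \code{\linkS4class{PotentialField}}
#' @param ef matching \code{\linkS4class{EFieldVolume}}
#' @param head the phantom the solve ran on
#' @param model the \code{\link{sphereModel}} mirroring the phantom
#' @param voxelIndex linear indices of the comparison voxels (e.g. the
#'   gray shell)
#' @param excludeRadius exclusion radius around each electrode point (mm);
#'   default 2 electrode (12 mm) diameters
#' @return List with \code{relL2Potential}, \code{relL2Magnitude}, and the
#'   number of compared voxels \code{n}.
#' @export
compareWithOracle <- function(potential, ef, head, model, voxelIndex,
                              excludeRadius = 24) {
  dims <- dim(potential@V)
  h <- potential@voxelSize
  xyz <- voxelXYZ(voxelIndex, dims, h, potential@center)
  RsM <- model@radii[1]
  e1 <- RsM * unitVec(model@electrodeAngles[1, 1], model@electrodeAngles[1, 2])
  e2 <- RsM * unitVec(model@electrodeAngles[2, 1], model@electrodeAngles[2, 2])
  d1 <- sqrt(rowSums(sweep(xyz, 2, e1)^2))
  d2 <- sqrt(rowSums(sweep(xyz, 2, e2)^2))
  keep <- d1 > excludeRadius & d2 > excludeRadius
  xyz <- xyz[keep, , drop = FALSE]
  idx <- voxelIndex[keep]
  ana <- sphereSeriesEval(model, xyz, needE = TRUE)
  vNum <- potential@V[idx]
  vNum <- vNum - mean(vNum)
  vAna <- ana$V - mean(ana$V)
  magNum <- ef@magnitude[idx]
  magAna <- sqrt(rowSums(ana$E^2))
  list(relL2Potential = sqrt(sum((vNum - vAna)^2) / sum(vAna^2)),
       relL2Magnitude = sqrt(sum((magNum - magAna)^2) / sum(magAna^2)),
       n = length(idx))
}
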