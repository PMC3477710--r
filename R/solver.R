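#' Assemble the discrete volume-conduction system
#'
#' Seven-point finite-volume discretization of div(sigma grad V) = 0 on the
#' voxel grid. The conductance of the face between two adjacent voxels is
#' the harmonic mean of their conductivities times face area / spacing
#' (= sigma_face * h in SI units for cubic voxels). Exterior grid faces are
#' zero-flux (the surrounding air already makes the head boundary
#' effectively insulated). The anode carries the total current as a uniform
#' inward Neumann flux over the exterior faces of its conductor voxels
#' ("resistive" mode) or as a single floating-potential supernode with a
#' total-current constraint ("equipotential" mode); cathode conductor
#' voxels are grounded (Dirichlet V = 0). The resulting operator is
#' symmetric positive definite on the free voxels.
#'
#' @param sigmaVol 3-D conductivity array (S/m), see
#'   \code{\link{conductivityVolume}}
#' @param raster a \code{\linkS4class{RasterizedHead}}
#' @param electrodeMode "resistive" or "equipotential"
#' @return An object of class \code{tdcsSystem} (list with the sparse
#'   operator \code{A}, right-hand side \code{b}, voxel-to-unknown map and
#'   bookkeeping) for \code{\link{solvePotential}}.
#' @export
assembleSystem <- function(sigmaVol, raster,
                           electrodeMode = c("resistive", "equipotential")) {
  electrodeMode <- match.arg(electrodeMode)
  stopifnot(all(sigmaVol > 0))
  dims <- dim(raster@labels)
  stopifnot(all(dim(sigmaVol) == dims))
  N <- prod(dims)
  h <- raster@voxelSize * 1e-3       # SI from here on
  els <- raster@montage@electrodes
  roles <- vapply(els, function(e) e@role, "")
  anodeIdx <- which(roles == "anode")
  cathCond <- unlist(lapply(raster@electrodeVoxels[roles == "cathode"],
                            function(v) v$conductor), use.names = FALSE)
  anCond <- raster@electrodeVoxels[[anodeIdx]]$conductor
  anFaces <- raster@electrodeVoxels[[anodeIdx]]$exteriorFaces
  if (!length(anCond) || sum(anFaces) == 0L)
    stop("no anode exterior faces recorded; cannot apply the current")
  if (!length(cathCond))
    stop("no cathode conductor voxels recorded; system would be singular")

  keep <- rep(TRUE, N)
  keep[cathCond] <- FALSE
  group <- seq_len(N)
  if (electrodeMode == "equipotential") group[anCond] <- anCond[1]
  uid <- integer(N)
  isRep <- keep & (group == seq_len(N))
  uid[isRep] <- seq_len(sum(isRep))
  merged <- keep & !isRep
  uid[merged] <- uid[group[merged]]
  M <- sum(isRep)

  s <- as.vector(sigmaVol)
  allIdx <- seq_len(N)
  n1 <- dims[1]; n12 <- dims[1] * dims[2]
  i1 <- (allIdx - 1L) %% n1 + 1L
  j1 <- ((allIdx - 1L) %/% n1) %% dims[2] + 1L
  k1 <- (allIdx - 1L) %/% n12 + 1L
  pairList <- list(
    list(a = allIdx[i1 < dims[1]], off = 1L),
    list(a = allIdx[j1 < dims[2]], off = n1),
    list(a = allIdx[k1 < dims[3]], off = n12))
  rm(i1, j1, k1)

  # symmetric storage: upper-triangle off-diagonals; the diagonal is
  # recovered as the negated off-diagonal row sums plus the couplings to
  # grounded (Dirichlet) voxels
  I <- J <- X <- vector("list", 3L)
  dirIdx <- dirG <- vector("list", 3L)
  for (ax in 1:3) {
    a <- pairList[[ax]]$a
    b <- a + pairList[[ax]]$off
    g <- h * 2 * s[a] * s[b] / (s[a] + s[b])
    ua <- uid[a]; ub <- uid[b]
    off <- ua > 0L & ub > 0L & ua != ub
    I[[ax]] <- pmin(ua[off], ub[off])
    J[[ax]] <- pmax(ua[off], ub[off])
    X[[ax]] <- -g[off]
    toDir <- xor(ua > 0L, ub > 0L)
    dirIdx[[ax]] <- pmax(ua[toDir], ub[toDir])
    dirG[[ax]] <- g[toDir]
  }
  O <- sparseMatrix(i = unlist(I), j = unlist(J), x = unlist(X),
                    dims = c(M, M), symmetric = TRUE)
  rm(I, J, X, pairList)
  dvec <- -Matrix::rowSums(O)
  di <- unlist(dirIdx); dg <- unlist(dirG)
  if (length(di)) {
    acc <- rowsum(dg, di)
    dvec[as.integer(rownames(acc))] <-
      dvec[as.integer(rownames(acc))] + acc[, 1]
  }
  A <- O + Diagonal(M, dvec)

  bvec <- numeric(M)
  Itot <- raster@montage@totalCurrent
  if (electrodeMode == "resistive") {
    share <- Itot * anFaces / sum(anFaces)
    bi <- uid[anCond]
    bvec[bi] <- bvec[bi] + share
  } else {
    bvec[uid[anCond[1]]] <- Itot
  }
  structure(list(A = A, b = bvec, uid = uid, dims = dims, h = h,
                 sigma = sigmaVol, raster = raster,
                 electrodeMode = electrodeMode,
                 nUnknowns = M),
            class = "tdcsSystem")
}

#' @export
print.tdcsSystem <- function(x, ...) {
  cat(sprintf("tdcsSystem: %d unknowns on a %s grid (%s anode mode)\n",
              x$nUnknowns, paste(x$dims, collapse = " x "),
              x$electrodeMode))
  invisible(x)
}

# Jacobi-preconditioned conjugate gradients; zero start, fixed iteration
# order, so residual histories are reproducible bit-for-bit.
pcgSolve <- function(A, b, tol, maxit, precondition = TRUE) {
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(length(b)), iterations = 0L,
                              relres = 0, history = numeric(0),
                              converged = TRUE))
  Minv <- if (precondition) 1 / Matrix::diag(A) else rep(1, length(b))
  if (any(!is.finite(Minv)))
    stop("operator has zero diagonal entries; system is singular ",
         "(disconnected anode-to-cathode path?)")
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  hist <- numeric(maxit)
  it <- 0L
  relres <- 1
  while (it < maxit) {
    it <- it + 1L
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / bnorm
    hist[it] <- relres
    if (relres <= tol) break
    z <- Minv * r
    rzNew <- sum(r * z)
    beta <- rzNew / rz
    rz <- rzNew
    p <- z + beta * p
  }
  list(x = x, iterations = it, relres = relres, history = hist[seq_len(it)],
       converged = relres <= tol)
}

#' Solve for the electric potential
#'
#' Conjugate-gradient solve of the assembled system to the configured
#' relative residual (default 1e-6), starting from zero, followed by a
#' per-electrode current audit. Deterministic for fixed inputs.
#'
#' @param system a \code{tdcsSystem} from \code{\link{assembleSystem}}
#' @param config a \code{\link{solverConfig}}; its \code{electrodeMode} is
#'   only used at assembly, not here
#' @return List with \code{potential} (a
#'   \code{\linkS4class{PotentialField}}) and \code{report} (a
#'   \code{\linkS4class{SolveReport}}).
#' @export
solvePotential <- function(system, config = solverConfig()) {
  validObject(config)
  res <- pcgSolve(system$A, system$b, tol = config@tolerance,
                  maxit = config@maxIterations,
                  precondition = config@preconditioner == "diagonal")
  if (!res$converged) {
    cond <- structure(
      class = c("tdcsConvergenceError", "error", "condition"),
      list(message = sprintf(
        "conjugate gradients did not reach tolerance %g in %d iterations (residual %g)",
        config@tolerance, config@maxIterations, res$relres),
        call = sys.call(), residualHistory = res$history))
    stop(cond)
  }
  V <- numeric(prod(system$dims))
  freeVox <- system$uid > 0L
  V[freeVox] <- res$x[system$uid[freeVox]]
  V <- array(V, system$dims)
  raster <- system$raster
  pot <- new("PotentialField", V = V, voxelSize = raster@voxelSize,
             center = raster@center,
             reference = "V = 0 on cathode conductor voxels (ground)")
  audit <- electrodeCurrentAudit(pot, system$sigma, raster)
  report <- new("SolveReport", iterations = res$iterations,
                finalRelResidual = res$relres, converged = res$converged,
                tolerance = config@tolerance,
                residualHistory = res$history,
                perElectrodeCurrent = audit$perElectrodeCurrent,
                conservationError = audit$conservationError)
  list(potential = pot, report = report)
}

#' Audit electrode currents from a solved potential
#'
#' Integrates sigma grad V . n over each electrode's surface (all faces
#' from the electrode's conductor + contact voxels into the head) and
#' reports the per-electrode injected currents and the conservation error
#' |sum of currents|. Anodes come out positive, cathodes negative.
#'
#' @param potential a \code{\linkS4class{PotentialField}} (or 3-D array)
#' @param sigmaVol conductivity array used in the solve
#' @param raster the \code{\linkS4class{RasterizedHead}}
#' @return List with \code{perElectrodeCurrent} (named, A) and
#'   \code{conservationError} (A).
#' @export
electrodeCurrentAudit <- function(potential, sigmaVol, raster) {
  V <- if (is(potential, "PotentialField")) potential@V else potential
  dims <- dim(V)
  h <- raster@voxelSize * 1e-3
  n1 <- dims[1]; n12 <- dims[1] * dims[2]
  s <- as.vector(sigmaVol)
  v <- as.vector(V)
  offs <- c(-1L, 1L, -n1, n1, -n12, n12)
  currents <- numeric(length(raster@electrodeVoxels))
  names(currents) <- names(raster@electrodeVoxels)
  for (nm in names(raster@electrodeVoxels)) {
    reg <- c(raster@electrodeVoxels[[nm]]$conductor,
             raster@electrodeVoxels[[nm]]$contact)
    inReg <- logical(prod(dims))
    inReg[reg] <- TRUE
    ri <- (reg - 1L) %% n1 + 1L
    rj <- ((reg - 1L) %/% n1) %% dims[2] + 1L
    rk <- (reg - 1L) %/% n12 + 1L
    atEdge <- list(ri == 1L, ri == dims[1], rj == 1L, rj == dims[2],
                   rk == 1L, rk == dims[3])
    tot <- 0
    for (f in 1:6) {
      ok <- !atEdge[[f]]
      a <- reg[ok]
      b <- a + offs[f]
      sel <- !inReg[b]
      a <- a[sel]; b <- b[sel]
      g <- h * 2 * s[a] * s[b] / (s[a] + s[b])
      tot <- tot + sum(g * (v[a] - v[b]))
    }
    currents[nm] <- tot
  }
  list(perElectrodeCurrent = currents,
       conservationError = abs(sum(currents)))
}
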