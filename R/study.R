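#' Study configuration
#'
#' Bundles everything a multi-subject, multi-montage comparison needs:
#' named subject phantom specs, montage preset names, the conductivity
#' table, solver settings, voxel size, the dose-normalization reference
#' subject and a seed (used for gyrated subjects' fold phases).
#'
#' @param subjects named list of \code{\linkS4class{SphereSpec}} (or of
#'   \code{list(spec=, gyri=)} for gyrated subjects); default: the three
#'   shipped presets
#' @param montages character subset of c("pad", "hd")
#' @param conductivities a \code{\linkS4class{ConductivityTable}}
#' @param solver a \code{\link{solverConfig}}
#' @param voxelSize voxel size (mm) the phantoms are built at
#' @param reference reference subject name for dose normalization
#' @param seed integer seed
#' @param outputDir directory for cached per-cell results (created on
#'   demand); \code{NULL} for a session temporary directory
#' @return A \code{tdcsStudyConfig} list.
#' @export
studyConfig <- function(subjects = NULL, montages = c("pad", "hd"),
                        conductivities = defaultConductivities(),
                        solver = solverConfig(), voxelSize = 1,
                        reference = "F", seed = 1L, outputDir = NULL) {
  if (is.null(subjects)) subjects <- subjectPresets(voxelSize = voxelSize)
  stopifnot(all(montages %in% c("pad", "hd")), length(montages) >= 1)
  if (!reference %in% names(subjects))
    stop("reference subject '", reference, "' not among subjects")
  structure(list(subjects = subjects, montages = montages,
                 conductivities = conductivities, solver = solver,
                 voxelSize = voxelSize, reference = reference,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "tdcsStudyConfig")
}

buildSubjectPhantom <- function(sub, seed) {
  if (is(sub, "SphereSpec")) return(spherePhantom(sub))
  if (is.list(sub) && !is.null(sub$gyri)) {
    gy <- sub$gyri
    if (is.na(gy@seed)) gy@seed <- seed
    return(gyratedPhantom(sub$spec, gy))
  }
  stop("subject must be a SphereSpec or list(spec=, gyri=)")
}

# solve one (subject, montage) cell and compute its metrics
runStudyCell <- function(head, montageName, config) {
  montage <- switch(montageName,
                    pad = padMontageM1SO(head),
                    hd = hdMontage4x1(head))
  raster <- rasterizeMontage(head, montage)
  sigma <- conductivityVolume(raster, config$conductivities)
  sys <- assembleSystem(sigma, raster,
                        electrodeMode = config$solver@electrodeMode)
  sol <- solvePotential(sys, config$solver)
  ef <- efieldFromPotential(sol$potential, raster)
  surf <- corticalSurface(head)
  cmap <- normalComponentMap(ef, surf)
  pk <- peakCorticalEF(cmap)
  # containment is always judged against the HD ring's scalp disc so pad
  # and HD cells are comparable
  region <- ringRegion(head, hdMontage4x1(head))
  cont <- containmentFraction(cmap, region)
  list(peak = pk$peak, robustPeak = pk$robustPeak,
       peakLocation = pk$location, containment = cont,
       focalityVolume = focalityVolume(cmap),
       report = sol$report, cmap = cmap)
}

#' Run a subjects x montages comparison study
#'
#' For every (subject, montage) pair: build the phantom, rasterize the
#' montage, solve, derive cortical maps and metrics. Emits a cross-subject
#' table (peak, robust peak, containment), per-montage fold-variation, and
#' dose-normalization recommendations against the reference subject. A
#' failing cell is recorded in the table and the remaining cells continue.
#' Completed cells are cached on disk keyed by a hash of their inputs, so
#' re-running an unchanged configuration reuses them.
#'
#' @param config a \code{\link{studyConfig}}
#' @param cache reuse cached cells if present (default TRUE)
#' @param verbose log stage progress (default FALSE)
#' @return A \code{tdcsStudy} list: \code{table} (data.frame),
#'   \code{foldVariation} (named by montage), \code{dose} (data.frame of
#'   recommended currents), \code{reports}, \code{errors},
#'   \code{configHash}.
#' @export
runStudy <- function(config, cache = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "tdcsStudyConfig"))
  outDir <- config$outputDir
  if (is.null(outDir)) outDir <- file.path(tempdir(), "tdcssim-cache")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  rows <- list()
  reports <- list()
  errors <- list()
  cmaps <- list()
  for (sn in names(config$subjects)) {
    head <- buildSubjectPhantom(config$subjects[[sn]], config$seed)
    for (mn in config$montages) {
      key <- hashObject(list(subject = config$subjects[[sn]],
                             montage = mn, voxel = config$voxelSize,
                             sigma = config$conductivities@sigma,
                             solver = config$solver, seed = config$seed,
                             version = 1L))
      cacheFile <- file.path(outDir, paste0(key, ".rds"))
      cell <- NULL
      if (cache && file.exists(cacheFile)) {
        say("cell ", sn, "/", mn, ": cached")
        cell <- readRDS(cacheFile)
      } else {
        say("cell ", sn, "/", mn, ": solving")
        cell <- tryCatch(runStudyCell(head, mn, config),
                         error = function(e) e)
        if (!inherits(cell, "error")) saveRDS(cell, cacheFile)
      }
      if (inherits(cell, "error")) {
        errors[[paste(sn, mn, sep = ".")]] <- conditionMessage(cell)
        rows[[length(rows) + 1]] <- data.frame(
          subject = sn, montage = mn, peak_V_per_m = NA_real_,
          robust_peak_V_per_m = NA_real_, containment = NA_real_,
          focality_volume_mm3 = NA_real_, iterations = NA_integer_,
          status = "error", stringsAsFactors = FALSE)
      } else {
        reports[[paste(sn, mn, sep = ".")]] <- cell$report
        cmaps[[paste(sn, mn, sep = ".")]] <- cell$cmap
        rows[[length(rows) + 1]] <- data.frame(
          subject = sn, montage = mn, peak_V_per_m = cell$peak,
          robust_peak_V_per_m = cell$robustPeak,
          containment = cell$containment,
          focality_volume_mm3 = cell$focalityVolume,
          iterations = cell$report@iterations,
          status = "ok", stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  fold <- vapply(config$montages, function(mn) {
    p <- tab$peak_V_per_m[tab$montage == mn & tab$status == "ok"]
    if (length(p) >= 2) foldVariation(p) else NA_real_
  }, 0)
  dose <- do.call(rbind, lapply(config$montages, function(mn) {
    sel <- tab$montage == mn & tab$status == "ok"
    refPeak <- tab$peak_V_per_m[sel & tab$subject == config$reference]
    if (!length(refPeak)) return(NULL)
    do.call(rbind, lapply(tab$subject[sel], function(sn) {
      sp <- tab$peak_V_per_m[sel & tab$subject == sn]
      dn <- normalizeDose(sp, refPeak,
                          baseCurrent = 1e-3,
                          referenceSubject = config$reference)
      data.frame(subject = sn, montage = mn,
                 scale_factor = dn@scaleFactor,
                 normalized_current_mA = dn@normalizedCurrent * 1e3,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(table = tab, foldVariation = fold, dose = dose,
                 reports = reports, corticalMaps = cmaps, errors = errors,
                 config = config,
                 configHash = hashObject(config)),
            class = "tdcsStudy")
}

#' Write study outputs to a directory
#'
#' Emits the cross-subject metrics table and the dose recommendations as
#' CSV, the fold-variation summary as JSON, and one solve-report JSON per
#' completed cell (see \code{\link{writeSolveReport}}).
#'
#' @param study a \code{tdcsStudy} from \code{\link{runStudy}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly.
#' @export
writeStudyReport <- function(study, dir) {
  stopifnot(inherits(study, "tdcsStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$table, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(study$dose))
    utils::write.csv(study$dose, file.path(dir, "dose.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(fold_variation = as.list(study$foldVariation),
         config_hash = study$configHash,
         errors = study$errors),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(study$reports))
    writeSolveReport(study$reports[[nm]],
                     file.path(dir, paste0("solve-", nm, ".json")))
  invisible(dir)
}

#' @export
print.tdcsStudy <- function(x, ...) {
  cat("tdcsStudy:\n")
  print(x$table, row.names = FALSE)
  cat("fold variation by montage:\n")
  print(round(x$foldVariation, 3))
  if (length(x$errors))
    cat("failed cells:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
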