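#' Default tissue conductivity table
#'
#' Representative isotropic DC conductivities (S/m): skin 0.465, skull
#' 0.01, CSF 1.65, gray matter 0.276, white matter 0.126, air 1e-7,
#' electrode conductor 5.8e7, saline-soaked sponge 1.4, gel 0.3. Air keeps
#' a small positive value (never exactly zero) so the insulating external
#' boundary emerges physically from the conductivity contrast.
#'
#' @return A \code{\linkS4class{ConductivityTable}}.
#' @export
#' @examples
#' sigmaOf(defaultConductivities(), "skull")
defaultConductivities <- function() {
  new("ConductivityTable", sigma = c(
    air = 1e-7, skin = 0.465, skull = 0.01, csf = 1.65, gray = 0.276,
    white = 0.126, sponge = 1.4, gel = 0.3, electrode = 5.8e7))
}

#' Conductivity table with user overrides
#'
#' Merges overrides onto \code{\link{defaultConductivities}}. Keys absent
#' from the default table are rejected.
#'
#' @param ... named conductivity overrides in S/m, e.g. \code{skull = 0.02}
#' @param file optional YAML/JSON file of \code{label: S_per_m} overrides
#' @return A \code{\linkS4class{ConductivityTable}}.
#' @export
conductivityTable <- function(..., file = NULL) {
  base <- defaultConductivities()@sigma
  ov <- c(list(...),
          if (!is.null(file)) readConductivityFile(file) else list())
  if (length(ov)) {
    bad <- setdiff(names(ov), names(base))
    if (length(bad))
      stop("unknown conductivity label(s): ", paste(bad, collapse = ", "))
    base[names(ov)] <- as.numeric(unlist(ov))
  }
  new("ConductivityTable", sigma = base)
}

readConductivityFile <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
}

#' Serialize a conductivity table
#'
#' @param table a \code{\linkS4class{ConductivityTable}}
#' @param file output path; format chosen by extension (.json or .yaml)
#' @return \code{file}, invisibly.
#' @export
writeConductivityTable <- function(table, file) {
  vals <- as.list(table@sigma)
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::write_json(vals, file, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(vals, file, precision = 15L)
  invisible(file)
}

#' Map a label volume to a conductivity volume
#'
#' Elementwise lookup of each voxel's label in the conductivity table. The
#' output grid has the same shape and spacing as the input.
#'
#' @param vol a \code{\linkS4class{LabelVolume}} (possibly rasterized)
#' @param table a \code{\linkS4class{ConductivityTable}}
#' @return 3-D numeric array of conductivities (S/m).
#' @export
conductivityVolume <- function(vol, table) {
  present <- vol@labelCodes[vol@labelCodes %in% unique(as.vector(vol@labels))]
  miss <- setdiff(names(present), names(table@sigma))
  if (length(miss))
    stop("labels present in volume but unmapped in conductivity table: ",
         paste(miss, collapse = ", "))
  lut <- rep(NA_real_, max(vol@labelCodes) + 1L)
  lut[vol@labelCodes + 1L] <- table@sigma[names(vol@labelCodes)]
  array(lut[as.vector(vol@labels) + 1L], dim = dim(vol@labels))
}
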