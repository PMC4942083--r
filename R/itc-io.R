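## Reading and writing titration data (CSV + sidecar key-value config).

#' Read a titration from CSV plus a sidecar configuration
#'
#' The CSV must carry the header \code{injection,volume_uL,heat_ucal}.  The
#' sidecar config supplies the experiment metadata as key-value lines
#' (\code{key = value}) or as a flat JSON object; recognised keys are
#' \code{temperature_C}, \code{cell_conc_uM}, \code{syringe_conc_uM} and
#' \code{cell_volume_mL}.
#'
#' @param csv path to the injection table.
#' @param config path to the sidecar config.
#' @param label experiment label; defaults to the CSV file name.
#' @return A \linkS4class{TitrationExperiment}.
#' @export
readITC <- function(csv, config, label = basename(csv)) {
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("injection", "volume_uL", "heat_ucal")
  if (!identical(names(tab)[seq_along(need)], need))
    stop("ITC csv must have header 'injection,volume_uL,heat_ucal', got: ",
         paste(names(tab), collapse = ","))
  cfg <- readITCConfig(config)
  TitrationExperiment(
    injectionVolumes = tab$volume_uL * 1e-6,
    observedHeats    = tab$heat_ucal,
    cellConc         = cfg$cell_conc_uM * 1e-6,
    syringeConc      = cfg$syringe_conc_uM * 1e-6,
    temperature      = cfg$temperature_C + 273.15,
    cellVolume       = cfg$cell_volume_mL * 1e-3,
    label            = label)
}

#' Read an ITC sidecar configuration
#'
#' @param path key-value text file (\code{key = value} per line, '#'
#'   comments allowed) or a JSON file (extension .json).
#' @return Named list with temperature_C, cell_conc_uM, syringe_conc_uM and
#'   cell_volume_mL (the last defaulting to 1.4 mL when absent).
#' @export
readITCConfig <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*[=:]\\s*")
    bad <- lengths(kv) != 2
    if (any(bad))
      stop("malformed config line: '", lines[which(bad)[1]], "'")
    cfg <- stats::setNames(lapply(kv, function(x) as.numeric(x[2])),
                           vapply(kv, `[`, character(1), 1))
  }
  need <- c("temperature_C", "cell_conc_uM", "syringe_conc_uM")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("ITC config missing keys: ", paste(miss, collapse = ", "))
  if (is.null(cfg$cell_volume_mL)) cfg$cell_volume_mL <- 1.4
  for (k in c(need, "cell_volume_mL"))
    if (!is.finite(as.numeric(cfg[[k]])))
      stop("ITC config key '", k, "' is not numeric")
  cfg[c(need, "cell_volume_mL")]
}

#' Write a titration to CSV plus sidecar config
#'
#' Inverse of \code{\link{readITC}}; heats are written at full precision.
#'
#' @param exp \linkS4class{TitrationExperiment} with observed heats.
#' @param csv output CSV path.
#' @param config output key-value config path.
#' @return Invisibly, \code{exp}.
#' @export
writeITC <- function(exp, csv, config) {
  stopifnot(is(exp, "TitrationExperiment"))
  if (!length(exp@observedHeats))
    stop("experiment has no observed heats to write")
  tab <- data.frame(
    injection = seq_along(exp@injectionVolumes),
    volume_uL = exp@injectionVolumes * 1e6,
    heat_ucal = exp@observedHeats)
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("temperature_C = %.10g",   exp@temperature - 273.15),
    sprintf("cell_conc_uM = %.10g",    exp@cellConc * 1e6),
    sprintf("syringe_conc_uM = %.10g", exp@syringeConc * 1e6),
    sprintf("cell_volume_mL = %.10g",  exp@cellVolume * 1e3)), config)
  invisible(exp)
}
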