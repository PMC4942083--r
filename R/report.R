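## End-to-end report pipeline: validated configuration in, deterministic
## bundle of TSV/JSON outputs out.

.CONFIG_KEYS <- list(
  top = c("seed", "output_dir", "temperature_C", "itc", "coupling",
          "interface", "conformation"),
  itc = c("runs", "reference", "fix_n"),
  itc_run = c("label", "csv", "config"),
  coupling = c("single_a", "single_b", "double"),
  interface = c("pdb", "group_a", "group_b", "contact_cutoff", "probe",
                "n_points", "burial_threshold", "apo_pdb", "mapping_tsv"),
  conformation = c("ensemble_pdb", "atom_names", "components", "superpose"))

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

# "chain:C" / "range:10:20" group selector strings -> selector lists
.parseGroup <- function(selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  switch(parts[1],
    chain = list(chains = parts[-1]),
    range = list(residueRange = as.numeric(parts[2:3])),
    stop("group selector must be 'chain:<id...>' or 'range:<from>:<to>', got '",
         selector, "'"))
}

#' Validate a pipeline run configuration
#'
#' The configuration is a flat JSON object (or an equivalent named list)
#' with optional \code{itc}, \code{coupling}, \code{interface} and
#' \code{conformation} sections; unknown keys anywhere are rejected, and an
#' empty configuration (no stage requested) is an error.
#'
#' @param config named list or path to a JSON file.
#' @return The validated configuration list, invisibly usable downstream.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config) || is.null(names(config)) || !length(config))
    stop("config schema error: expected a non-empty named configuration")
  .checkKeys(config, .CONFIG_KEYS$top, "top level")
  stages <- intersect(names(config),
                      c("itc", "interface", "conformation"))
  if (!length(stages))
    stop("config schema error: no analysis stage ",
         "(itc / interface / conformation) requested")
  if (!is.null(config$itc)) {
    .checkKeys(config$itc, .CONFIG_KEYS$itc, "itc")
    if (is.null(config$itc$runs) || !length(config$itc$runs))
      stop("config schema error: itc.runs must list at least one run")
    if (is.data.frame(config$itc$runs))
      config$itc$runs <- split(config$itc$runs,
                               seq_len(nrow(config$itc$runs)))
    for (r in config$itc$runs) {
      .checkKeys(r, .CONFIG_KEYS$itc_run, "itc.runs entry")
      if (is.null(r$label) || is.null(r$csv) || is.null(r$config))
        stop("config schema error: each itc run needs label, csv, config")
    }
    if (is.null(config$itc$reference))
      stop("config schema error: itc.reference is required")
  }
  if (!is.null(config$coupling)) {
    .checkKeys(config$coupling, .CONFIG_KEYS$coupling, "coupling")
    if (is.null(config$itc))
      stop("config schema error: coupling requires the itc stage")
  }
  if (!is.null(config$interface)) {
    .checkKeys(config$interface, .CONFIG_KEYS$interface, "interface")
    for (k in c("pdb", "group_a", "group_b"))
      if (is.null(config$interface[[k]]))
        stop("config schema error: interface.", k, " is required")
  }
  if (!is.null(config$conformation)) {
    .checkKeys(config$conformation, .CONFIG_KEYS$conformation,
               "conformation")
    if (is.null(config$conformation$ensemble_pdb))
      stop("config schema error: conformation.ensemble_pdb is required")
  }
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.writeNum <- function(df, file, digits = 6) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full repressor-complex analysis report
#'
#' Wires the pipeline stages behind one validated configuration: fits every
#' configured titration and writes the thermodynamic table (with ddG
#' against the configured reference), evaluates an optional double-mutant
#' coupling cycle, an optional structural interface report, and optional
#' ensemble statistics (RMSF, PCA projections).  All outputs are plain TSV
#' or JSON with fixed decimal rounding, so a rerun with the same
#' configuration and seed is byte-identical; the resolved configuration is
#' written next to the outputs.  Progress goes to standard error via
#' \code{message()}.  A failing stage aborts with an error naming the
#' stage.
#'
#' @param config named list or path to a JSON configuration; see
#'   \code{\link{validateRunConfig}}.
#' @param outputDir overrides \code{config$output_dir}.
#' @return Invisibly, a list with the per-stage results (thermo table,
#'   coupling, interface report, pca) and the output paths.
#' @export
runRepressorReport <- function(config, outputDir = NULL) {
  config <- validateRunConfig(config)
  outDir <- outputDir %||% config$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  tempK <- (config$temperature_C %||% 25) + 273.15
  results <- list()
  paths <- character(0)

  if (!is.null(config$itc)) {
    results$thermo <- .stage("itc", {
      fits <- list()
      for (r in config$itc$runs) {
        message("[itc] fitting ", r$label)
        exp <- readITC(r$csv, r$config, label = r$label)
        fit <- fitOneSite(exp, fixN = isTRUE(config$itc$fix_n))
        if (!fit@converged)
          warning("fit for '", r$label, "' did not converge")
        fits[[r$label]] <- fit
      }
      tbl <- buildThermoTable(fits, reference = config$itc$reference,
                              temperature = tempK)
      f <- file.path(outDir, "thermo_table.tsv")
      writeThermoTable(tbl, f)
      paths <<- c(paths, f)
      tbl
    })
  }

  if (!is.null(config$coupling)) {
    results$coupling <- .stage("coupling", {
      tbl <- results$thermo
      pick <- function(lab) {
        i <- match(lab, tbl$syringe)
        if (is.na(i)) stop("coupling label '", lab, "' not in thermo table")
        tbl$ddG[i]
      }
      cp <- couplingEnergy(pick(config$coupling$single_a),
                           pick(config$coupling$single_b),
                           pick(config$coupling$double))
      f <- file.path(outDir, "coupling.json")
      jsonlite::write_json(lapply(cp, round, 6), f, auto_unbox = TRUE,
                           digits = NA)
      paths <<- c(paths, f)
      cp
    })
  }

  if (!is.null(config$interface)) {
    results$interface <- .stage("interface", {
      ic <- config$interface
      message("[interface] ", ic$pdb)
      model <- readPDB(ic$pdb)
      rset <- defaultRadii(probe = ic$probe %||% .PROBE_DEFAULT)
      rep_ <- buriedSurfaceArea(
        model, .parseGroup(ic$group_a), .parseGroup(ic$group_b),
        radii = rset, nPoints = ic$n_points %||% 960L,
        contactCutoff = ic$contact_cutoff %||% 4.5,
        labelA = ic$group_a, labelB = ic$group_b)
      .writeNum(rep_@perResidue, file.path(outDir, "interface_residues.tsv"))
      .writeNum(rep_@contacts, file.path(outDir, "interface_contacts.tsv"))
      jsonlite::write_json(
        list(bsa_total = round(rep_@bsaTotal, 3),
             n_contacts = nrow(rep_@contacts),
             parameters = rep_@parameters),
        file.path(outDir, "interface_summary.json"), auto_unbox = TRUE)
      paths <<- c(paths, file.path(outDir, c("interface_residues.tsv",
                  "interface_contacts.tsv", "interface_summary.json")))
      rep_
    })
  }

  if (!is.null(config$conformation)) {
    results$pca <- .stage("conformation", {
      cc <- config$conformation
      message("[conformation] ", cc$ensemble_pdb)
      ens <- asEnsemble(readPDB(cc$ensemble_pdb),
                        atomNames = cc$atom_names %||% "CA")
      sup <- cc$superpose %||% TRUE
      flucts <- rmsf(ens, superpose = sup)
      pca <- ensemblePca(ens, superpose = sup,
                         components = cc$components %||% 2L)
      .writeNum(data.frame(label = names(flucts), rmsf = unname(flucts)),
                file.path(outDir, "rmsf.tsv"))
      .writeNum(as.data.frame(pca@projections),
                file.path(outDir, "pca_projections.tsv"))
      .writeNum(data.frame(component = seq_along(pca@eigenvalues),
                           eigenvalue = pca@eigenvalues),
                file.path(outDir, "pca_eigenvalues.tsv"))
      paths <<- c(paths, file.path(outDir, c("rmsf.tsv",
                  "pca_projections.tsv", "pca_eigenvalues.tsv")))
      pca
    })
  }

  cfgPath <- file.path(outDir, "resolved_config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, cfgPath)
  message("report written to ", normalizePath(outDir))
  invisible(c(results, list(paths = paths)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
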