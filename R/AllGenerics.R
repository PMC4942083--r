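## Accessor generics and show methods.

#' Number of atoms in a structure or ensemble
#' @param x object.
#' @return Integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of coordinate models / frames
#' @param x object.
#' @return Integer model (frame) count.
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' Atom metadata table
#' @param x object.
#' @return data.frame of per-atom metadata.
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Coordinates of one model
#' @param x object.
#' @param model model index (1-based).
#' @return N x 3 numeric matrix, Angstrom.
#' @export
setGeneric("atomCoords", function(x, model = 1L) standardGeneric("atomCoords"))

#' Fitted parameters of a one-site fit
#' @param x a \linkS4class{OneSiteFit}.
#' @return \linkS4class{OneSiteParams}.
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @describeIn nAtoms atoms in a StructureModel.
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @describeIn nModels models in a StructureModel.
#' @export
setMethod("nModels", "StructureModel", function(x) length(x@coords))

#' @describeIn atomData atom table of a StructureModel.
#' @export
setMethod("atomData", "StructureModel", function(x) x@atoms)

#' @describeIn atomCoords coordinates of one model of a StructureModel.
#' @export
setMethod("atomCoords", "StructureModel", function(x, model = 1L) {
  model <- as.integer(model)
  if (model < 1L || model > length(x@coords))
    stop("model index ", model, " out of range (structure has ",
         length(x@coords), " model(s))")
  x@coords[[model]]
})

#' @describeIn nAtoms atoms in an Ensemble.
#' @export
setMethod("nAtoms", "Ensemble", function(x) dim(x@coords)[2])

#' @describeIn nModels frames in an Ensemble.
#' @export
setMethod("nModels", "Ensemble", function(x) dim(x@coords)[1])

#' @describeIn atomCoords one frame of an Ensemble.
#' @export
setMethod("atomCoords", "Ensemble", function(x, model = 1L) {
  model <- as.integer(model)
  if (model < 1L || model > dim(x@coords)[1])
    stop("frame index out of range")
  m <- x@coords[model, , , drop = FALSE]
  dim(m) <- dim(x@coords)[2:3]
  rownames(m) <- x@labels
  m
})

#' @describeIn fittedParams parameters of a OneSiteFit.
#' @export
setMethod("fittedParams", "OneSiteFit", function(x) x@params)

setMethod("show", "TitrationExperiment", function(object) {
  cat("TitrationExperiment", if (nzchar(object@label))
      paste0("'", object@label, "'") else "", "\n")
  cat(sprintf("  %d injections, cell %.3g uM / syringe %.3g uM, V0 %.3g mL, T %.2f K\n",
              length(object@injectionVolumes), object@cellConc * 1e6,
              object@syringeConc * 1e6, object@cellVolume * 1e3,
              object@temperature))
  if (length(object@observedHeats))
    cat(sprintf("  heats: [%.3g .. %.3g] ucal\n",
                min(object@observedHeats), max(object@observedHeats)))
  else cat("  design only (no heats)\n")
})

setMethod("show", "OneSiteParams", function(object) {
  cat(sprintf("OneSiteParams: n = %.4g, K = %.4g 1/M (Kd = %.4g uM), dH = %.4g kcal/mol\n",
              object@n, object@K, 1e6 / object@K, object@dH))
})

setMethod("show", "OneSiteFit", function(object) {
  cat("OneSiteFit (", if (object@converged) "converged" else "NOT converged",
      ", ", object@nIterations, " iterations)\n", sep = "")
  show(object@params)
  se <- object@stdErrors
  cat(sprintf("  std errors: n %.3g, K %.3g, dH %.3g\n",
              se[["n"]], se[["K"]], se[["dH"]]))
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel '%s': %d atoms, %d model(s), chains %s\n",
              object@source, nrow(a), length(object@coords),
              paste(sort(unique(a$chain)), collapse = " ")))
  cat(sprintf("  %d HETATM, altloc policy: %s\n",
              sum(a$het), object@altlocPolicy))
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf("SasaResult: %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
              length(object@atomArea), sum(object@atomArea),
              object@probe, object@nPoints))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("InterfaceReport %s | %s\n", object@labelA, object@labelB))
  cat(sprintf("  total BSA %.1f A^2 (two-sided), %d interface residues, %d contact pairs\n",
              object@bsaTotal, sum(object@perResidue$dsasa > 0),
              nrow(object@contacts)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms%s\n",
              object@rmsd, object@nAtoms,
              if (object@degenerate) " (degenerate point set)" else ""))
})

setMethod("show", "Ensemble", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Ensemble: %d frames x %d atoms", d[1], d[2]))
  if (length(object@states))
    cat(" | states:", paste(sprintf("%s (%d)", names(table(object@states)),
                                    table(object@states)), collapse = ", "))
  cat("\n")
})

setMethod("show", "PcaResult", function(object) {
  ev <- object@eigenvalues
  tot <- sum(ev)
  k <- min(3, length(ev))
  cat(sprintf("PcaResult: %d modes, total variance %.4g A^2\n",
              length(ev), tot))
  if (tot > 0)
    cat("  leading modes:",
        paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * ev[seq_len(k)] / tot),
              collapse = ", "), "\n")
})
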