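#' @import methods
NULL

## ---------------------------------------------------------------------------
## ITC classes
## ---------------------------------------------------------------------------

#' TitrationExperiment: one ITC run
#'
#' Holds the design of a titration (cell volume and concentrations, injection
#' volumes, temperature) together with the observed integrated heats.  A
#' design-only object (no heats yet, e.g. as input to a simulator) has an
#' empty \code{observedHeats} vector.
#'
#' Units follow calorimetric convention: concentrations in mol/L, volumes in
#' liters, temperature in kelvin, heats in microcalories per injection.
#'
#' @slot temperature kelvin.
#' @slot cellVolume active cell volume V0, liters.
#' @slot cellConc initial macromolecule concentration in the cell, mol/L.
#' @slot syringeConc titrant concentration in the syringe, mol/L.
#' @slot injectionVolumes per-injection volumes, liters.
#' @slot observedHeats integrated heats, microcalories; may be empty for a
#'   design-only object.
#' @slot label free-text experiment label.
#' @export
setClass("TitrationExperiment",
  representation(
    temperature      = "numeric",
    cellVolume       = "numeric",
    cellConc         = "numeric",
    syringeConc      = "numeric",
    injectionVolumes = "numeric",
    observedHeats    = "numeric",
    label            = "character"
  )
)

setValidity("TitrationExperiment", function(object) {
  msgs <- character(0)
  if (length(object@temperature) != 1 || !is.finite(object@temperature) ||
      object@temperature < 273 || object@temperature > 373)
    msgs <- c(msgs, "temperature must be a single value in [273, 373] K")
  for (sl in c("cellVolume", "cellConc", "syringeConc")) {
    v <- slot(object, sl)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("%s must be a single strictly positive value", sl))
  }
  if (length(object@injectionVolumes) < 5)
    msgs <- c(msgs, "at least 5 injections are required")
  if (any(!is.finite(object@injectionVolumes)) ||
      any(object@injectionVolumes <= 0))
    msgs <- c(msgs, "injection volumes must be strictly positive")
  nh <- length(object@observedHeats)
  if (nh > 0 && nh != length(object@injectionVolumes))
    msgs <- c(msgs,
      "observedHeats must be empty or match injectionVolumes in length")
  if (nh > 0 && any(!is.finite(object@observedHeats)))
    msgs <- c(msgs, "observed heats must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TitrationExperiment
#'
#' @param injectionVolumes per-injection volumes in liters.
#' @param observedHeats integrated heats in microcalories (empty for a
#'   design-only object).
#' @param cellConc macromolecule concentration in the cell, mol/L.
#' @param syringeConc titrant concentration in the syringe, mol/L.
#' @param temperature kelvin; defaults to 298.15 K.
#' @param cellVolume active cell volume in liters; defaults to 1.4e-3 L,
#'   typical for a VP-style perfusion calorimeter, and overridable per
#'   experiment.
#' @param label free-text label.
#' @return A \linkS4class{TitrationExperiment}.
#' @examples
#' TitrationExperiment(rep(7e-6, 40), cellConc = 5e-6, syringeConc = 50e-6)
#' @export
TitrationExperiment <- function(injectionVolumes, observedHeats = numeric(0),
                                cellConc, syringeConc,
                                temperature = .T_DEFAULT,
                                cellVolume = 1.4e-3, label = "") {
  new("TitrationExperiment",
      temperature = as.numeric(temperature),
      cellVolume = as.numeric(cellVolume),
      cellConc = as.numeric(cellConc),
      syringeConc = as.numeric(syringeConc),
      injectionVolumes = as.numeric(injectionVolumes),
      observedHeats = as.numeric(observedHeats),
      label = as.character(label))
}

#' OneSiteParams: parameters of the one-site binding isotherm
#'
#' @slot n binding stoichiometry (sites per macromolecule), dimensionless.
#' @slot K association constant, 1/M.
#' @slot dH molar injection enthalpy, kcal/mol.
#' @export
setClass("OneSiteParams",
  representation(n = "numeric", K = "numeric", dH = "numeric"))

setValidity("OneSiteParams", function(object) {
  msgs <- character(0)
  if (length(object@n) != 1 || !is.finite(object@n) || object@n <= 0)
    msgs <- c(msgs, "n must be a single positive value")
  if (length(object@K) != 1 || !is.finite(object@K) || object@K <= 0)
    msgs <- c(msgs, "K must be a single positive value")
  if (length(object@dH) != 1 || !is.finite(object@dH))
    msgs <- c(msgs, "dH must be a single finite value")
  if (length(msgs)) msgs else TRUE
})

#' Construct OneSiteParams
#'
#' @param n stoichiometry (default 1).
#' @param K association constant, 1/M.
#' @param dH enthalpy, kcal/mol.
#' @return A \linkS4class{OneSiteParams}.
#' @examples
#' OneSiteParams(K = 5.7e8, dH = -11.9)
#' @export
OneSiteParams <- function(n = 1, K, dH) {
  new("OneSiteParams", n = as.numeric(n), K = as.numeric(K),
      dH = as.numeric(dH))
}

#' OneSiteFit: result of fitting the one-site model
#'
#' @slot params fitted \linkS4class{OneSiteParams}.
#' @slot stdErrors named standard errors for n, K and dH (from the local
#'   curvature of the least-squares surface).
#' @slot residuals observed minus fitted heats, microcalories.
#' @slot converged logical convergence flag.
#' @slot nIterations optimizer iteration count.
#' @export
setClass("OneSiteFit",
  representation(
    params      = "OneSiteParams",
    stdErrors   = "numeric",
    residuals   = "numeric",
    converged   = "logical",
    nIterations = "integer"
  )
)

setValidity("OneSiteFit", function(object) {
  msgs <- character(0)
  if (any(object@stdErrors < 0, na.rm = TRUE))
    msgs <- c(msgs, "standard errors must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Structure classes
## ---------------------------------------------------------------------------

#' StructureModel: hierarchical coordinate model parsed from PDB
#'
#' Atom metadata live in a single data.frame (one row per atom, file order
#' preserved); coordinates live in a list of N x 3 matrices, one per MODEL of
#' a multi-MODEL file.  Residues are addressed by (chain, resseq, icode) in
#' author numbering.
#'
#' @slot atoms data.frame with columns serial, name, altloc, resname, chain,
#'   resseq, icode, occupancy, bfactor, element, het (logical HETATM flag).
#' @slot coords list of N x 3 coordinate matrices (Angstrom), one per model.
#' @slot altlocPolicy character description of the alternate-location policy
#'   applied at parse time.
#' @slot source free-text source label (usually the file name).
#' @export
setClass("StructureModel",
  representation(
    atoms        = "data.frame",
    coords       = "list",
    altlocPolicy = "character",
    source       = "character"
  )
)

setValidity("StructureModel", function(object) {
  msgs <- character(0)
  need <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "icode", "occupancy", "bfactor", "element", "het")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    msgs <- c(msgs, paste("atoms is missing columns:",
                          paste(miss, collapse = ", ")))
  if (nrow(object@atoms) == 0)
    msgs <- c(msgs, "structure contains zero atoms")
  if (!length(object@coords))
    msgs <- c(msgs, "at least one coordinate model is required")
  for (m in object@coords) {
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != nrow(object@atoms)) {
      msgs <- c(msgs, "every model must be an N x 3 matrix matching the atom table")
      break
    }
    if (any(!is.finite(m))) { msgs <- c(msgs, "coordinates must be finite"); break }
  }
  if (!length(msgs)) {
    key <- with(object@atoms,
                paste(chain, resseq, icode, name, altloc, sep = "\r"))
    if (anyDuplicated(key))
      msgs <- c(msgs, "(chain, resseq, icode, name, altloc) must be unique")
    if (any(!nzchar(object@atoms$element)))
      msgs <- c(msgs, "every atom must have a non-empty element")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Surface-area classes
## ---------------------------------------------------------------------------

#' RadiiSet: van der Waals radii and probe radius for SASA
#'
#' @slot radii named numeric vector, Angstrom, keyed by element symbol (and
#'   optionally synthetic element codes used by toy structures).
#' @slot probe probe radius, Angstrom.
#' @slot fallback radius assigned (with a warning) to elements absent from
#'   the table; \code{NA} makes unknown elements an error instead.
#' @export
setClass("RadiiSet",
  representation(radii = "numeric", probe = "numeric", fallback = "numeric"))

setValidity("RadiiSet", function(object) {
  msgs <- character(0)
  if (!length(object@radii) || is.null(names(object@radii)) ||
      any(!nzchar(names(object@radii))))
    msgs <- c(msgs, "radii must be a named numeric vector")
  if (any(object@radii <= 0.5 | object@radii >= 3.0))
    msgs <- c(msgs, "all radii must lie in (0.5, 3.0) Angstrom")
  if (length(object@probe) != 1 || object@probe < 0)
    msgs <- c(msgs, "probe must be a single nonnegative value")
  if (length(msgs)) msgs else TRUE
})

#' SasaResult: per-atom and per-residue solvent-accessible surface area
#'
#' @slot atomArea per-atom SASA, Angstrom^2, aligned with the atoms the
#'   computation used (heavy atoms by default).
#' @slot atomIndex row indices of those atoms in the source atom table.
#' @slot residueArea data.frame with chain, resseq, icode, resname, area and
#'   sideChainArea columns (Angstrom^2).
#' @slot probe probe radius used.
#' @slot nPoints sphere point count used.
#' @export
setClass("SasaResult",
  representation(
    atomArea    = "numeric",
    atomIndex   = "integer",
    residueArea = "data.frame",
    probe       = "numeric",
    nPoints     = "integer"
  )
)

setValidity("SasaResult", function(object) {
  msgs <- character(0)
  if (any(object@atomArea < 0))
    msgs <- c(msgs, "areas must be nonnegative")
  if (length(object@atomIndex) != length(object@atomArea))
    msgs <- c(msgs, "atomIndex must align with atomArea")
  if (length(msgs)) msgs else TRUE
})

#' InterfaceReport: buried surface area and contacts between two groups
#'
#' The buried-surface convention is two-sided:
#' \code{SASA(A alone) + SASA(B alone) - SASA(A and B together)}, with both
#' components kept in their complexed conformation.
#'
#' @slot labelA,labelB group labels.
#' @slot bsaTotal total buried surface area, Angstrom^2 (two-sided sum).
#' @slot perResidue data.frame: group, chain, resseq, icode, resname, dsasa,
#'   dsasaSideChain (Angstrom^2 lost on complexation).
#' @slot contacts data.frame of residue contact pairs with minimum
#'   heavy-atom distance (Angstrom).
#' @slot parameters list of probe, nPoints, contact cutoff.
#' @export
setClass("InterfaceReport",
  representation(
    labelA     = "character",
    labelB     = "character",
    bsaTotal   = "numeric",
    perResidue = "data.frame",
    contacts   = "data.frame",
    parameters = "list"
  )
)

## ---------------------------------------------------------------------------
## Conformational classes
## ---------------------------------------------------------------------------

#' SuperpositionResult: optimal rigid-body superposition
#'
#' The transform maps mobile coordinates x (rows) onto the target frame as
#' \code{x \%*\% rotation + translation} (row-vector convention).
#'
#' @slot rotation 3 x 3 proper rotation matrix (det +1).
#' @slot translation length-3 vector, Angstrom.
#' @slot rmsd coordinate RMSD after transformation, Angstrom.
#' @slot nAtoms number of atom pairs used.
#' @slot degenerate TRUE when the point set was (near-)collinear so the
#'   rotation about the common axis is not determined by the data.
#' @export
setClass("SuperpositionResult",
  representation(
    rotation    = "matrix",
    translation = "numeric",
    rmsd        = "numeric",
    nAtoms      = "integer",
    degenerate  = "logical"
  )
)

setValidity("SuperpositionResult", function(object) {
  msgs <- character(0)
  R <- object@rotation
  if (!all(dim(R) == c(3, 3)))
    msgs <- c(msgs, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msgs <- c(msgs, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      msgs <- c(msgs, "rotation must be proper (det +1)")
  }
  if (object@rmsd < 0) msgs <- c(msgs, "rmsd must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Ensemble: a set of frames over a fixed atom list
#'
#' @slot coords F x N x 3 array, Angstrom.
#' @slot labels length-N atom address labels (unique).
#' @slot states optional length-F frame state labels (empty when absent).
#' @export
setClass("Ensemble",
  representation(coords = "array", labels = "character",
                 states = "character"))

setValidity("Ensemble", function(object) {
  msgs <- character(0)
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    msgs <- c(msgs, "coords must be an F x N x 3 array")
  else {
    if (d[1] < 1) msgs <- c(msgs, "at least one frame required")
    if (length(object@labels) != d[2])
      msgs <- c(msgs, "labels must match the atom dimension")
    if (anyDuplicated(object@labels))
      msgs <- c(msgs, "labels must be unique")
    if (length(object@states) && length(object@states) != d[1])
      msgs <- c(msgs, "states must be empty or one per frame")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an Ensemble from an F x N x 3 array
#'
#' @param coords F x N x 3 array of coordinates (Angstrom).
#' @param labels length-N unique atom labels; defaults to "1".."N".
#' @param states optional per-frame state labels.
#' @return An \linkS4class{Ensemble}.
#' @export
Ensemble <- function(coords, labels = NULL, states = character(0)) {
  if (is.null(labels)) labels <- as.character(seq_len(dim(coords)[2]))
  new("Ensemble", coords = coords, labels = as.character(labels),
      states = as.character(states))
}

#' PcaResult: covariance principal components of an ensemble
#'
#' Eigendecomposition of the 3N x 3N covariance of coordinate fluctuations
#' about the ensemble mean (population normalisation, 1/F, so the eigenvalue
#' sum equals the summed squared RMSF exactly).
#'
#' @slot mean N x 3 mean structure, Angstrom.
#' @slot eigenvalues descending eigenvalues, Angstrom^2.
#' @slot eigenvectors 3N x k matrix of unit-norm eigenvectors; the sign of
#'   each is fixed so its largest-magnitude component is positive.
#' @slot projections F x k frame projections, Angstrom.
#' @slot labels atom labels of the ensemble.
#' @export
setClass("PcaResult",
  representation(
    mean         = "matrix",
    eigenvalues  = "numeric",
    eigenvectors = "matrix",
    projections  = "matrix",
    labels       = "character"
  )
)
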