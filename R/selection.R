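## Atom selection on StructureModel objects.

#' Select atoms from a structure
#'
#' Stable-ordered subsetting by chain, inclusive author-numbering residue
#' range, atom name, heaviness and side-chain membership.  Side-chain
#' selection excludes the backbone atoms N, CA, C, O and OXT, so glycine
#' contributes no side-chain atoms.  An empty selection is an error, never a
#' silent empty structure.
#'
#' @param model \linkS4class{StructureModel}.
#' @param chains character vector of chain identifiers, or NULL for all.
#' @param residueRange length-2 numeric (from, to), inclusive on author
#'   numbering, or NULL.
#' @param atomNames character vector of atom names (e.g. "CA"), or NULL.
#' @param heavyOnly drop hydrogens/deuteriums.
#' @param sideChainOnly drop backbone atoms.
#' @param includeHet keep HETATM records (default TRUE).
#' @return The selected \linkS4class{StructureModel} (all models subset
#'   consistently); use \code{\link{atomCoords}} for the coordinate matrix.
#' @examples
#' toy <- makeToyChain(10)
#' nAtoms(selectAtoms(toy, atomNames = "CA"))
#' @export
selectAtoms <- function(model, chains = NULL, residueRange = NULL,
                        atomNames = NULL, heavyOnly = FALSE,
                        sideChainOnly = FALSE, includeHet = TRUE) {
  idx <- selectionIndex(model, chains = chains, residueRange = residueRange,
                        atomNames = atomNames, heavyOnly = heavyOnly,
                        sideChainOnly = sideChainOnly,
                        includeHet = includeHet)
  subsetStructure(model, idx)
}

#' Atom row indices matching a selector
#'
#' Index-returning counterpart of \code{\link{selectAtoms}} (same
#' arguments); used where two groups of one structure must be addressed
#' without copying it.
#'
#' @inheritParams selectAtoms
#' @return Sorted integer vector of atom row indices.
#' @export
selectionIndex <- function(model, chains = NULL, residueRange = NULL,
                           atomNames = NULL, heavyOnly = FALSE,
                           sideChainOnly = FALSE, includeHet = TRUE) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(residueRange)) {
    if (length(residueRange) != 2) stop("residueRange must be (from, to)")
    keep <- keep & a$resseq >= residueRange[1] & a$resseq <= residueRange[2]
  }
  if (!is.null(atomNames)) keep <- keep & a$name %in% atomNames
  if (heavyOnly) keep <- keep & !(a$element %in% c("H", "D"))
  if (sideChainOnly) keep <- keep & !(a$name %in% .BACKBONE)
  if (!includeHet) keep <- keep & !a$het
  if (!any(keep))
    stop("empty selection: no atoms match the requested selector")
  which(keep)
}

#' Subset a structure by atom row indices
#'
#' @param model \linkS4class{StructureModel}.
#' @param idx integer atom row indices (in order).
#' @return \linkS4class{StructureModel} restricted to those atoms.
#' @export
subsetStructure <- function(model, idx) {
  if (!length(idx)) stop("empty selection")
  new("StructureModel",
      atoms = model@atoms[idx, , drop = FALSE],
      coords = lapply(model@coords, function(m) m[idx, , drop = FALSE]),
      altlocPolicy = model@altlocPolicy, source = model@source)
}

#' Residue address labels ("chain:resseq" with icode appended when present)
#'
#' @param atoms atom data.frame (or \linkS4class{StructureModel}).
#' @return Character vector of residue labels, one per atom row.
#' @export
residueLabels <- function(atoms) {
  if (is(atoms, "StructureModel")) atoms <- atoms@atoms
  paste0(atoms$chain, ":", atoms$resseq,
         ifelse(nzchar(atoms$icode), paste0(":", atoms$icode), ""))
}

#' C-alpha coordinates with residue labels
#'
#' @param model \linkS4class{StructureModel}.
#' @param modelIndex which model's coordinates (default 1).
#' @param chains optional chain filter.
#' @return N x 3 matrix with rownames "chain:resseq".
#' @export
caCoords <- function(model, modelIndex = 1L, chains = NULL) {
  sel <- selectAtoms(model, chains = chains, atomNames = "CA",
                     includeHet = FALSE)
  m <- atomCoords(sel, modelIndex)
  rownames(m) <- residueLabels(sel)
  m
}
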