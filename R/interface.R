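## Interface characterisation: buried surface area, contacts, burial filter.

.resolveGroup <- function(model, group, what) {
  if (is.numeric(group)) {
    idx <- as.integer(group)
    if (!length(idx) || any(idx < 1) || any(idx > nAtoms(model)))
      stop(what, ": atom indices out of range")
    return(sort(idx))
  }
  if (is.list(group)) return(do.call(selectionIndex, c(list(model), group)))
  stop(what, " must be an index vector or a selector list ",
       "(chains/residueRange/atomNames/...)")
}

#' Buried surface area between two atom groups
#'
#' Two-sided convention:
#' \code{BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)},
#' with each component extracted in its complexed conformation (no
#' re-minimisation).  Per-residue and side-chain-only dSASA are included;
#' by construction with a shared deterministic point lattice every per-atom
#' dSASA is nonnegative, and the per-residue values sum exactly to the
#' total.
#'
#' @param model \linkS4class{StructureModel} containing both groups.
#' @param groupA,groupB atom index vectors or selector lists (as in
#'   \code{\link{selectAtoms}}); must be disjoint and non-empty.
#' @param radii \linkS4class{RadiiSet}.
#' @param nPoints Shrake-Rupley lattice size.
#' @param contactCutoff heavy-atom contact distance, Angstrom.
#' @param modelIndex coordinate model.
#' @param labelA,labelB group labels for reporting.
#' @return An \linkS4class{InterfaceReport}.
#' @examples
#' toy <- makeToyChain(6)
#' buriedSurfaceArea(toy, list(residueRange = c(1, 3)),
#'                   list(residueRange = c(4, 6)))
#' @export
buriedSurfaceArea <- function(model, groupA, groupB, radii = defaultRadii(),
                              nPoints = 960L, contactCutoff = 4.5,
                              modelIndex = 1L,
                              labelA = "A", labelB = "B") {
  idxA <- .resolveGroup(model, groupA, "groupA")
  idxB <- .resolveGroup(model, groupB, "groupB")
  if (length(intersect(idxA, idxB)))
    stop("groups overlap: ", length(intersect(idxA, idxB)),
         " shared atom(s); BSA of a group with itself is undefined")

  subA  <- subsetStructure(model, idxA)
  subB  <- subsetStructure(model, idxB)
  subAB <- subsetStructure(model, sort(c(idxA, idxB)))

  sasaA  <- computeSasa(subA, radii, nPoints, modelIndex)
  sasaB  <- computeSasa(subB, radii, nPoints, modelIndex)
  sasaAB <- computeSasa(subAB, radii, nPoints, modelIndex)

  bsa <- sum(sasaA@atomArea) + sum(sasaB@atomArea) - sum(sasaAB@atomArea)

  perRes <- rbind(
    .residueDelta(sasaA, sasaAB, labelA),
    .residueDelta(sasaB, sasaAB, labelB))
  neg <- perRes$dsasa < 0
  if (any(neg)) {
    warning(sum(neg), " residue(s) with slightly negative dSASA clamped to 0")
    perRes$dsasa[neg] <- 0
  }
  perRes$dsasaSideChain[perRes$dsasaSideChain < 0] <- 0

  contacts <- contactResidues(model, idxA, idxB, cutoff = contactCutoff,
                              modelIndex = modelIndex)

  new("InterfaceReport", labelA = labelA, labelB = labelB,
      bsaTotal = bsa, perResidue = perRes, contacts = contacts,
      parameters = list(probe = radii@probe, nPoints = as.integer(nPoints),
                        contactCutoff = contactCutoff))
}

# per-residue SASA(alone) - SASA(in complex) for one group
.residueDelta <- function(alone, complexed, label) {
  key <- function(r) paste(r$chain, r$resseq, r$icode, sep = "\r")
  ra <- alone@residueArea
  rc <- complexed@residueArea
  m <- match(key(ra), key(rc))
  data.frame(group = label,
             chain = ra$chain, resseq = ra$resseq, icode = ra$icode,
             resname = ra$resname,
             dsasa = ra$area - rc$area[m],
             dsasaSideChain = ra$sideChainArea - rc$sideChainArea[m],
             stringsAsFactors = FALSE)
}

#' Residue contact pairs between two groups
#'
#' All residue pairs with any heavy-atom inter-group distance at or below
#' the cutoff, with the minimal distance, sorted by group-A residue number.
#'
#' @param model \linkS4class{StructureModel}.
#' @param groupA,groupB disjoint atom index vectors or selector lists.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.5; the
#'   notion of "contact" has no universal definition, so it is exposed).
#' @param modelIndex coordinate model.
#' @return data.frame: residueA, resnameA, residueB, resnameB, minDistance.
#' @export
contactResidues <- function(model, groupA, groupB, cutoff = 4.5,
                            modelIndex = 1L) {
  idxA <- .resolveGroup(model, groupA, "groupA")
  idxB <- .resolveGroup(model, groupB, "groupB")
  if (length(intersect(idxA, idxB))) stop("groups must be disjoint")
  a <- model@atoms
  heavy <- !(a$element %in% c("H", "D"))
  idxA <- idxA[heavy[idxA]]
  idxB <- idxB[heavy[idxB]]
  if (!length(idxA) || !length(idxB))
    stop("a contact group has no heavy atoms")
  xyz <- atomCoords(model, modelIndex)
  xa <- xyz[idxA, , drop = FALSE]
  xb <- xyz[idxB, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  labA <- residueLabels(a[idxA, , drop = FALSE])
  labB <- residueLabels(a[idxB, , drop = FALSE])
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(residueA = character(0), resnameA = character(0),
                      residueB = character(0), resnameB = character(0),
                      minDistance = numeric(0), stringsAsFactors = FALSE))
  pair <- paste(labA[hit[, 1]], labB[hit[, 2]], sep = "|")
  dmin <- tapply(sqrt(d2[hit]), pair, min)
  parts <- strsplit(names(dmin), "|", fixed = TRUE)
  out <- data.frame(
    residueA = vapply(parts, `[`, character(1), 1),
    residueB = vapply(parts, `[`, character(1), 2),
    minDistance = as.numeric(dmin), stringsAsFactors = FALSE)
  out$resnameA <- a$resname[idxA][match(out$residueA, labA)]
  out$resnameB <- a$resname[idxB][match(out$residueB, labB)]
  ord <- order(vapply(strsplit(out$residueA, ":"), function(p)
                 as.integer(p[2]), integer(1)),
               out$residueA, out$residueB)
  out <- out[ord, c("residueA", "resnameA", "residueB", "resnameB",
                    "minDistance")]
  rownames(out) <- NULL
  out
}

#' Filter residues by burial in an apo structure
#'
#' Returns the subset of query residues whose side-chain solvent-accessible
#' area in a reference (apo) structure is strictly below the threshold.
#' When the query and apo structures use different author numbering (e.g. a
#' fly protein filtered against a mouse ortholog structure), a two-column
#' mapping table translates query residue numbers to apo numbers; no
#' automatic alignment is attempted.
#'
#' @param apoSasa \linkS4class{SasaResult} computed on the apo structure.
#' @param residues character residue labels ("chain:resseq") in query
#'   numbering.
#' @param threshold Angstrom^2 (default 20); strictly-less-than comparison.
#' @param mapping optional data.frame with columns \code{from} and
#'   \code{to}: query resseq -> apo resseq.
#' @param apoChain chain of the apo structure to match against; defaults to
#'   the chain in each residue label (after mapping).
#' @return Character vector: the query labels that are buried in the apo
#'   structure, with the looked-up areas as the \code{area} attribute.
#' @examples
#' toy <- makeToyChain(5)
#' s <- computeSasa(toy)
#' apoBurialFilter(s, c("A:1", "A:2"), threshold = 1e6)
#' @export
apoBurialFilter <- function(apoSasa, residues, threshold = 20,
                            mapping = NULL, apoChain = NULL) {
  stopifnot(is(apoSasa, "SasaResult"))
  parts <- strsplit(residues, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, character(1), 1)
  resseq <- as.integer(vapply(parts, `[`, character(1), 2))
  if (any(is.na(resseq)))
    stop("residue labels must look like 'chain:resseq'")
  target <- resseq
  if (!is.null(mapping)) {
    if (!all(c("from", "to") %in% names(mapping)))
      stop("mapping must have 'from' and 'to' columns")
    m <- match(resseq, mapping$from)
    if (any(is.na(m)))
      stop("unmappable residue(s): ",
           paste(residues[is.na(m)], collapse = ", "))
    target <- mapping$to[m]
  }
  if (!is.null(apoChain)) chain <- rep_len(apoChain, length(target))
  ra <- apoSasa@residueArea
  m <- match(paste(chain, target), paste(ra$chain, ra$resseq))
  if (any(is.na(m)))
    stop("residue(s) not resolvable in the apo structure: ",
         paste(residues[is.na(m)], collapse = ", "))
  area <- ra$sideChainArea[m]
  hit <- area < threshold
  structure(residues[hit], area = area[hit])
}
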