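## Torsion angles; chi1 side-chain dihedral.

# gamma-position atom defining chi1 (N-CA-CB-<gamma>) per residue type
.CHI1_GAMMA <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1")

#' Signed torsion angle of four points
#'
#' IUPAC convention: looking along the p2->p3 bond, the angle is positive
#' when the far bond (p3->p4) is rotated clockwise from the near bond
#' (p2->p1); trans/anti is 180, returned in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(.cross3(b1, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Side-chain chi1 dihedral of a residue
#'
#' chi1 is defined over N-CA-CB-gamma, where the gamma atom depends on the
#' residue type (CG for most, CG1 for Ile/Val, OG for Ser, OG1 for Thr, SG
#' for Cys).  Glycine and alanine have no chi1.  For a multi-model
#' structure all models are evaluated, giving a per-frame series.
#'
#' @param model \linkS4class{StructureModel}.
#' @param chain chain identifier.
#' @param resseq residue number (author numbering).
#' @param icode insertion code (default "").
#' @param modelIndex model index/indices; default all models.
#' @return Numeric vector of chi1 angles in degrees, one per model.
#' @examples
#' fix <- makeTorsionFixture(60)
#' chi1Dihedral(fix, "A", 1)
#' @export
chi1Dihedral <- function(model, chain, resseq, icode = "",
                         modelIndex = NULL) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  inRes <- a$chain == chain & a$resseq == resseq & a$icode == icode
  if (!any(inRes))
    stop("residue ", chain, ":", resseq, " not found")
  resname <- a$resname[inRes][1]
  if (resname %in% c("GLY", "ALA"))
    stop(resname, " has no chi1 dihedral")
  gamma <- .CHI1_GAMMA[[resname]]
  if (is.null(gamma)) gamma <- "CG"
  needed <- c("N", "CA", "CB", gamma)
  rows <- vapply(needed, function(nm) {
    i <- which(inRes & a$name == nm)
    if (!length(i)) NA_integer_ else i[1]
  }, integer(1))
  if (any(is.na(rows)))
    stop("missing chi1 atom(s) for ", resname, " ", chain, ":", resseq,
         ": ", paste(needed[is.na(rows)], collapse = ", "))
  if (is.null(modelIndex)) modelIndex <- seq_along(model@coords)
  vapply(modelIndex, function(m) {
    xyz <- atomCoords(model, m)
    torsionAngle(xyz[rows[1], ], xyz[rows[2], ], xyz[rows[3], ],
                 xyz[rows[4], ])
  }, numeric(1))
}
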