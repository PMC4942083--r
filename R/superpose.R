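## Kabsch superposition and per-residue displacement.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation + translation mapping \code{mobile} onto
#' \code{target}, via SVD of the cross-covariance of the centred sets; an
#' improper (reflection) solution is corrected by flipping the sign of the
#' smallest singular direction.  When both inputs carry rownames they must
#' match pairwise (matched label order is the caller's contract).
#'
#' @param mobile,target N x 3 coordinate matrices, N >= 3.
#' @return A \linkS4class{SuperpositionResult}; coordinates transform as
#'   \code{mobile \%*\% rotation + translation} (see
#'   \code{\link{applySuperposition}}).  Near-collinear point sets are
#'   flagged \code{degenerate}.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' kabschSuperpose(x, x)@rmsd   # 0
#' @export
kabschSuperpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("mobile and target must have identical dimensions")
  if (ncol(mobile) != 3) stop("coordinates must be N x 3")
  if (nrow(mobile) < 3) stop("at least 3 atoms are required")
  if (!is.null(rownames(mobile)) && !is.null(rownames(target)) &&
      !identical(rownames(mobile), rownames(target))) {
    off <- rownames(mobile)[rownames(mobile) != rownames(target)]
    stop("label mismatch between coordinate sets: ",
         paste(utils::head(off, 5), collapse = ", "))
  }
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$u, s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  # collinear sets leave rotation about the common axis undetermined
  degenerate <- s$d[2] <= 1e-8 * max(s$d[1], 1e-300)
  transformed <- P %*% R
  rmsd <- sqrt(mean(rowSums((transformed - Q)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(ct - cm %*% R),
      rmsd = rmsd, nAtoms = nrow(mobile), degenerate = degenerate)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords N x 3 matrix.
#' @param sup \linkS4class{SuperpositionResult}.
#' @return Transformed N x 3 matrix.
#' @export
applySuperposition <- function(coords, sup) {
  stopifnot(is(sup, "SuperpositionResult"))
  sweep(as.matrix(coords) %*% sup@rotation, 2, sup@translation, "+")
}

#' Per-atom displacement between two labelled coordinate sets
#'
#' Euclidean distance per atom, optionally after superposing \code{b} onto
#' \code{a}.  The superposition fit may be restricted to a subset of labels
#' (e.g. a rigid core) while displacements are reported for all atoms --
#' the natural way to measure a loop excursion against a fixed core.
#'
#' @param a,b N x 3 matrices with matching rownames (labels).
#' @param presuperpose superpose b onto a first (default FALSE).
#' @param fitLabels labels used for the superposition fit; default all.
#' @return data.frame with columns label, chain, resseq, displacement
#'   (Angstrom); chain/resseq are parsed from "chain:resseq" labels where
#'   possible.
#' @examples
#' x <- caCoords(makeToyChain(5))
#' perResidueDisplacement(x, x + 3)$displacement  # all sqrt(27)
#' @export
perResidueDisplacement <- function(a, b, presuperpose = FALSE,
                                   fitLabels = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  la <- rownames(a); lb <- rownames(b)
  if (is.null(la) || is.null(lb))
    stop("both coordinate sets must carry rownames (labels)")
  if (!identical(la, lb)) {
    off <- union(setdiff(la, lb), setdiff(lb, la))
    if (!length(off)) off <- la[la != lb]
    stop("label mismatch: ", paste(utils::head(off, 5), collapse = ", "))
  }
  if (presuperpose) {
    fit <- if (is.null(fitLabels)) la else fitLabels
    miss <- setdiff(fit, la)
    if (length(miss))
      stop("fitLabels not present: ", paste(utils::head(miss, 5), collapse = ", "))
    sup <- kabschSuperpose(b[la %in% fit, , drop = FALSE],
                           a[la %in% fit, , drop = FALSE])
    b <- applySuperposition(b, sup)
  }
  disp <- sqrt(rowSums((a - b)^2))
  parts <- strsplit(la, ":", fixed = TRUE)
  data.frame(
    label = la,
    chain = vapply(parts, `[`, character(1), 1),
    resseq = suppressWarnings(
      as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                        character(1)))),
    displacement = unname(disp),
    stringsAsFactors = FALSE)
}

#' Maximum displacement within a residue window
#'
#' Operationalises "translation of a loop" as the maximum per-atom
#' displacement over an inclusive residue range.
#'
#' @param displacements data.frame from
#'   \code{\link{perResidueDisplacement}}.
#' @param from,to inclusive residue numbers.
#' @param chain optional chain restriction.
#' @return Maximum displacement in the window, Angstrom.
#' @export
segmentMax <- function(displacements, from, to, chain = NULL) {
  d <- displacements
  keep <- !is.na(d$resseq) & d$resseq >= from & d$resseq <= to
  if (!is.null(chain)) keep <- keep & d$chain %in% chain
  if (!any(keep))
    stop("no residues in window [", from, ", ", to, "]")
  max(d$displacement[keep])
}
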