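## Ensemble statistics: iterative superposition, RMSF, covariance PCA,
## state separation.

#' Build an Ensemble from a multi-model structure
#'
#' @param model \linkS4class{StructureModel} with one or more models.
#' @param atomNames atom-name filter (default "CA"); NULL keeps all atoms.
#' @param chains optional chain filter.
#' @param states optional per-frame state labels.
#' @return An \linkS4class{Ensemble} labelled by residue
#'   ("chain:resseq[:icode]") when one atom per residue is selected, else
#'   by "chain:resseq:name".
#' @export
asEnsemble <- function(model, atomNames = "CA", chains = NULL,
                       states = character(0)) {
  sel <- if (is.null(atomNames) && is.null(chains)) model
         else selectAtoms(model, chains = chains, atomNames = atomNames)
  labs <- residueLabels(sel)
  if (anyDuplicated(labs))
    labs <- paste0(labs, ":", sel@atoms$name)
  F <- length(sel@coords)
  N <- nAtoms(sel)
  arr <- array(NA_real_, c(F, N, 3))
  for (f in seq_len(F)) arr[f, , ] <- sel@coords[[f]]
  Ensemble(arr, labels = labs, states = states)
}

#' Iteratively superpose every frame onto the ensemble mean
#'
#' Each frame is Kabsch-superposed onto the current mean structure, the
#' mean is recomputed, and the cycle repeats until the mean moves less than
#' \code{tol} (RMS over atoms) or \code{maxIter} is reached.
#'
#' @param ens \linkS4class{Ensemble}.
#' @param tol convergence tolerance on the mean shift, Angstrom.
#' @param maxIter iteration cap.
#' @return The superposed \linkS4class{Ensemble}.
#' @export
iterativeSuperpose <- function(ens, tol = 1e-6, maxIter = 20L) {
  stopifnot(is(ens, "Ensemble"))
  arr <- ens@coords
  F <- dim(arr)[1]
  meanXYZ <- apply(arr, c(2, 3), mean)
  for (it in seq_len(maxIter)) {
    for (f in seq_len(F)) {
      sup <- kabschSuperpose(arr[f, , ], meanXYZ)
      arr[f, , ] <- applySuperposition(arr[f, , ], sup)
    }
    newMean <- apply(arr, c(2, 3), mean)
    shift <- sqrt(mean(rowSums((newMean - meanXYZ)^2)))
    meanXYZ <- newMean
    if (shift < tol) break
  }
  Ensemble(arr, labels = ens@labels, states = ens@states)
}

#' Per-atom root-mean-square fluctuation
#'
#' \eqn{RMSF_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle_f}},
#' optionally after iterative superposition to the ensemble mean.
#'
#' @param ens \linkS4class{Ensemble} with at least 2 frames.
#' @param superpose iteratively superpose first (default TRUE).
#' @return Named numeric vector of per-atom RMSF, Angstrom.
#' @export
rmsf <- function(ens, superpose = TRUE) {
  stopifnot(is(ens, "Ensemble"))
  if (dim(ens@coords)[1] < 2)
    stop("at least 2 frames are required for fluctuation statistics")
  if (superpose) ens <- iterativeSuperpose(ens)
  arr <- ens@coords
  meanXYZ <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), meanXYZ)^2
  out <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames AND xyz, times 3
  names(out) <- ens@labels
  out
}

#' Covariance principal-component analysis of an ensemble
#'
#' Builds the 3N x 3N covariance matrix of coordinate fluctuations about
#' the ensemble mean (mass-unweighted; population normalisation 1/F so that
#' the eigenvalue sum equals the summed squared RMSF exactly) and
#' diagonalises it.  Eigenvalues descend; each eigenvector's sign is fixed
#' by making its largest-magnitude component positive, so projections are
#' reproducible.  Frames are projected onto the leading components.
#'
#' @param ens \linkS4class{Ensemble}, F > 1 frames, N >= 2 atoms.
#' @param superpose iteratively superpose first (default TRUE).
#' @param components number of projection columns to keep (default 2).
#' @return A \linkS4class{PcaResult}.
#' @export
ensemblePca <- function(ens, superpose = TRUE, components = 2L) {
  stopifnot(is(ens, "Ensemble"))
  d <- dim(ens@coords)
  if (d[1] < 2) stop("at least 2 frames are required")
  if (d[2] < 2) stop("at least 2 atoms are required")
  if (superpose) ens <- iterativeSuperpose(ens)
  arr <- ens@coords
  F <- d[1]; N <- d[2]
  meanXYZ <- apply(arr, c(2, 3), mean)
  # fluctuation matrix, columns ordered (x1, y1, z1, x2, ...)
  X <- matrix(NA_real_, F, 3 * N)
  for (f in seq_len(F))
    X[f, ] <- as.numeric(t(arr[f, , ] - meanXYZ))
  C <- crossprod(X) / F
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  k <- min(components, ncol(vecs))
  proj <- X %*% vecs[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  new("PcaResult", mean = meanXYZ, eigenvalues = vals,
      eigenvectors = vecs, projections = proj, labels = ens@labels)
}

#' Separation of labelled states in a projection space
#'
#' For two frame groups, the per-component standardised mean difference
#' \eqn{|m_1 - m_2| / s_{pooled}}; a score above 2 on the leading component
#' flags the groups as occupying distinct regions.
#'
#' @param projections F x k matrix (e.g. the \code{projections} slot of a
#'   \linkS4class{PcaResult}).
#' @param states length-F labels with exactly two distinct non-empty
#'   groups.
#' @return list with \code{score} (per component), \code{component1} (the
#'   PC1 score) and \code{distinct} (PC1 score > 2).
#' @export
stateSeparation <- function(projections, states) {
  projections <- as.matrix(projections)
  states <- as.character(states)
  if (length(states) != nrow(projections))
    stop("one state label per frame is required")
  groups <- unique(states)
  if (length(groups) != 2)
    stop("exactly two state groups are required, got ", length(groups))
  i1 <- states == groups[1]; i2 <- states == groups[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2)
    stop("each state group needs at least 2 frames")
  score <- vapply(seq_len(ncol(projections)), function(j) {
    x1 <- projections[i1, j]; x2 <- projections[i2, j]
    sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
               (n1 + n2 - 2))
    if (sp == 0) return(if (mean(x1) == mean(x2)) 0 else Inf)
    abs(mean(x1) - mean(x2)) / sp
  }, numeric(1))
  names(score) <- colnames(projections)
  list(score = score, component1 = score[[1]], distinct = score[[1]] > 2)
}
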