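## Seeded synthetic-data generators.  Each generator is a pure function of
## its arguments (seed included): identical calls give bit-identical output,
## and ground truth is returned alongside the data.

#' Simulate a titration thermogram
#'
#' Per-injection heats from \code{\link{injectionSeries}} plus iid Gaussian
#' noise.  Noise is specified either as an absolute standard deviation in
#' microcalories (\code{noise}) or relative to the largest absolute
#' injection heat (\code{noiseRelative}); the relative form at 1\% is the
#' default.
#'
#' @param params generating \linkS4class{OneSiteParams} (the ground truth).
#' @param design design-only \linkS4class{TitrationExperiment}; defaults to
#'   \code{\link{defaultITCDesign}()} (40 x 7 uL, 5/50 uM, 25 C, 1.4 mL).
#' @param noise absolute Gaussian sd, microcalories; overrides
#'   \code{noiseRelative} when given.
#' @param noiseRelative sd as a fraction of max |heat| (default 0.01).
#' @param seed integer RNG seed; NULL leaves the RNG state alone.
#' @param label experiment label.
#' @return \linkS4class{TitrationExperiment} with simulated heats.
#' @examples
#' exp <- simulateThermogram(OneSiteParams(K = 1.9e7, dH = -23.8), seed = 7)
#' @export
simulateThermogram <- function(params, design = defaultITCDesign(),
                               noise = NULL, noiseRelative = 0.01,
                               seed = NULL, label = "simulated") {
  stopifnot(is(params, "OneSiteParams"), is(design, "TitrationExperiment"))
  mu <- injectionSeries(params, design)
  sd <- if (!is.null(noise)) noise else noiseRelative * max(abs(mu))
  if (sd < 0) stop("noise sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  heats <- if (sd > 0) mu + stats::rnorm(length(mu), 0, sd) else mu
  TitrationExperiment(design@injectionVolumes, heats,
                      cellConc = design@cellConc,
                      syringeConc = design@syringeConc,
                      temperature = design@temperature,
                      cellVolume = design@cellVolume, label = label)
}

#' Toy sphere cluster with prescribed radii
#'
#' Pseudo-atoms whose radii are carried by synthetic element codes, for
#' analytic SASA/BSA oracles.  Each atom is its own residue, so per-residue
#' and per-atom areas coincide.
#'
#' @param centers k x 3 matrix of centres, Angstrom.
#' @param radii length-k (or scalar) van der Waals radii in (0.5, 3.0).
#' @param probe probe radius for the accompanying radii set.
#' @param chain chain identifier.
#' @return list with \code{model} (\linkS4class{StructureModel}),
#'   \code{radii} (\linkS4class{RadiiSet} mapping the synthetic elements,
#'   unknowns an error) and \code{truth} (centres and radii as supplied).
#' @examples
#' makeSphereCluster(rbind(c(0, 0, 0), c(2, 0, 0)), 1.7)
#' @export
makeSphereCluster <- function(centers, radii, probe = .PROBE_DEFAULT,
                              chain = "A") {
  centers <- matrix(as.numeric(centers), ncol = 3)
  k <- nrow(centers)
  radii <- rep_len(radii, k)
  uniq <- unique(radii)
  elem <- paste0("Q", match(radii, uniq))
  atoms <- data.frame(
    name = "XS", resname = "SPH", chain = chain, resseq = seq_len(k),
    element = elem, stringsAsFactors = FALSE)
  model <- structureModel(atoms, centers, source = "sphere-cluster")
  rset <- radiiSet(stats::setNames(uniq, paste0("Q", seq_along(uniq))),
                   probe = probe, fallback = NA_real_)
  list(model = model, radii = rset,
       truth = list(centers = centers, radii = radii))
}

#' Deterministic toy peptide chain
#'
#' A flat synthetic backbone (N, CA, C, O and, except for glycine, CB) laid
#' along x with 3.8 Angstrom calpha spacing.  Geometry is schematic -- it
#' exercises selection, superposition and displacement code, not chemistry.
#'
#' @param nRes number of residues.
#' @param chain chain identifier.
#' @param startRes first author residue number.
#' @param resnames residue names, recycled (default "ALA").
#' @return A \linkS4class{StructureModel}.
#' @export
makeToyChain <- function(nRes, chain = "A", startRes = 1L,
                         resnames = "ALA") {
  resnames <- rep_len(resnames, nRes)
  rows <- list(); coords <- list()
  for (i in seq_len(nRes)) {
    ca <- c(3.8 * (i - 1), 0, 0)
    names_i <- c("N", "CA", "C", "O")
    offs <- rbind(c(-1.2, 0.9, 0.3), c(0, 0, 0), c(1.2, 0.9, -0.3),
                  c(1.4, 2.0, -0.3))
    if (resnames[i] != "GLY") {
      names_i <- c(names_i, "CB")
      offs <- rbind(offs, c(0, -1.5, 0.4))
    }
    rows[[i]] <- data.frame(
      name = names_i, resname = resnames[i], chain = chain,
      resseq = startRes + i - 1L, stringsAsFactors = FALSE)
    coords[[i]] <- sweep(offs, 2, ca, "+")
  }
  structureModel(do.call(rbind, rows), do.call(rbind, coords),
                 source = "toy-chain")
}

#' Random proper rotation matrix
#'
#' @param seed integer seed; NULL uses the current RNG state.
#' @return 3 x 3 rotation matrix (det +1).
#' @export
randomRotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Rigid-transformed copy of a structure with a known loop excursion
#'
#' The copy is \code{x \%*\% rotation + translation}; calpha atoms of the
#' loop window are then displaced by exactly \code{loopExcursion} Angstrom
#' along a recorded unit direction.  The returned truth table gives the
#' exact per-atom displacement that a superposition fitted on the rigid
#' part must recover.
#'
#' @param model \linkS4class{StructureModel}.
#' @param rotation 3 x 3 rotation (default identity).
#' @param translation length-3 vector (default zero).
#' @param loopWindow inclusive residue range (from, to) receiving the
#'   excursion, or NULL.
#' @param loopExcursion excursion magnitude, Angstrom.
#' @param direction unit 3-vector for the excursion; default (0, 1, 0)
#'   (applied after the rigid transform).
#' @param seed optional seed; when given and \code{rotation} is NULL, a
#'   random rotation/translation is drawn.
#' @return list with \code{model}, \code{transformed}, and \code{truth}
#'   (data.frame label/displacement; excursion on loop calphas, 0
#'   elsewhere).
#' @export
makeTransformedPair <- function(model, rotation = NULL,
                                translation = c(0, 0, 0),
                                loopWindow = NULL, loopExcursion = 0,
                                direction = c(0, 1, 0), seed = NULL) {
  stopifnot(is(model, "StructureModel"))
  if (!is.null(seed)) {
    set.seed(seed)
    if (is.null(rotation)) {
      rotation <- randomRotation()
      translation <- stats::rnorm(3, 0, 10)
    }
  }
  if (is.null(rotation)) rotation <- diag(3)
  a <- model@atoms
  xyz <- atomCoords(model, 1L)
  moved <- sweep(xyz %*% rotation, 2, translation, "+")
  disp <- numeric(nrow(a))
  if (!is.null(loopWindow) && loopExcursion != 0) {
    dirU <- direction / sqrt(sum(direction^2))
    hit <- a$name == "CA" & a$resseq >= loopWindow[1] &
           a$resseq <= loopWindow[2]
    moved[hit, ] <- sweep(moved[hit, , drop = FALSE], 2,
                          loopExcursion * dirU, "+")
    disp[hit] <- loopExcursion
  }
  transformed <- structureModel(a, moved, source = "transformed-copy")
  list(model = model, transformed = transformed,
       truth = data.frame(label = residueLabels(a), name = a$name,
                          displacement = disp, stringsAsFactors = FALSE))
}

#' Two-state Gaussian coordinate ensemble with known eigenstructure
#'
#' Frames are one of two reference structures plus isotropic Gaussian
#' jitter of standard deviation \code{sigma} per axis.  When the
#' inter-state displacement is much larger than sigma, the leading
#' principal component converges on the normalised displacement vector and
#' the expected PC1 state separation is |refB - refA| (as a 3N vector)
#' divided by sigma.
#'
#' @param refA,refB N x 3 reference structures with matching rownames.
#' @param nA,nB frames per state.
#' @param sigma jitter sd per axis, Angstrom.
#' @param seed integer seed.
#' @return list with \code{ensemble} (states "A"/"B") and \code{truth}
#'   (displacement unit 3N-vector, its magnitude, and the expected
#'   separation |d|/sigma).
#' @export
makeTwoStateEnsemble <- function(refA, refB, nA, nB, sigma, seed = NULL) {
  refA <- as.matrix(refA); refB <- as.matrix(refB)
  if (!all(dim(refA) == dim(refB)))
    stop("reference structures must have identical dimensions")
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(refA); F <- nA + nB
  arr <- array(NA_real_, c(F, N, 3))
  for (f in seq_len(nA))
    arr[f, , ] <- refA + matrix(stats::rnorm(3 * N, 0, sigma), N, 3)
  for (f in seq_len(nB))
    arr[nA + f, , ] <- refB + matrix(stats::rnorm(3 * N, 0, sigma), N, 3)
  labels <- rownames(refA)
  if (is.null(labels)) labels <- as.character(seq_len(N))
  d <- as.numeric(t(refB - refA))
  mag <- sqrt(sum(d^2))
  list(ensemble = Ensemble(arr, labels = labels,
                           states = rep(c("A", "B"), c(nA, nB))),
       truth = list(direction = if (mag > 0) d / mag else d,
                    magnitude = mag,
                    expectedSeparation = mag / sigma))
}

#' Four-atom fixture with an exact chi1 torsion
#'
#' Builds N, CA, CB and CG (plus decoy C and O) so that the N-CA-CB-CG
#' torsion equals \code{chi1Degrees} exactly: CG is placed by rotating
#' about the CA-CB axis from the cis (eclipsing-N) reference position.
#' With a seed, a random rigid transform is applied to the whole residue
#' (torsions are invariant under it).
#'
#' @param chi1Degrees requested torsion, degrees.
#' @param resname residue type (must have a CG-type gamma atom; default
#'   "PHE").
#' @param seed optional seed for the rigid scrambling transform.
#' @return A \linkS4class{StructureModel} of one residue, with the
#'   requested angle as the \code{chi1} attribute.
#' @export
makeTorsionFixture <- function(chi1Degrees, resname = "PHE", seed = NULL) {
  phi <- chi1Degrees * pi / 180
  CA <- c(0, 0, 0)
  axis <- c(0, 0, 1)
  CB <- 1.53 * axis
  N <- c(1.37, 0, -0.48)
  u <- c(1, 0, 0)                     # unit projection of N-CA off the axis
  v <- .cross3(axis, u)
  CG <- CB - 0.51 * axis + 1.40 * (u * cos(phi) + v * sin(phi))
  C <- c(-1.2, 0.9, -0.3); O <- c(-1.4, 2.0, -0.3)
  coords <- rbind(N = N, CA = CA, C = C, O = O, CB = CB, CG = CG)
  if (!is.null(seed)) {
    set.seed(seed)
    R <- randomRotation()
    coords <- sweep(coords %*% R, 2, stats::rnorm(3, 0, 5), "+")
  }
  atoms <- data.frame(name = c("N", "CA", "C", "O", "CB", "CG"),
                      resname = resname, chain = "A", resseq = 1L,
                      stringsAsFactors = FALSE)
  out <- structureModel(atoms, coords, source = "torsion-fixture")
  attr(out, "chi1") <- chi1Degrees
  out
}
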