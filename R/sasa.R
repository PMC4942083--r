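## Shrake-Rupley solvent-accessible surface area with a deterministic
## generalized-spiral point lattice.

#' Construct a radii set for SASA calculations
#'
#' @param radii named numeric vector of van der Waals radii (Angstrom) keyed
#'   by element symbol; synthetic element codes from toy generators are
#'   allowed.
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @param fallback radius used (with one warning per call) for elements
#'   missing from the table; set \code{NA} to make unknown elements an
#'   error.
#' @return A \linkS4class{RadiiSet}.
#' @export
radiiSet <- function(radii, probe = .PROBE_DEFAULT, fallback = 1.70) {
  new("RadiiSet", radii = radii, probe = as.numeric(probe),
      fallback = as.numeric(fallback))
}

#' Default van der Waals radii
#'
#' A fixed published table: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Angstrom,
#' with a 1.70 Angstrom fallback for anything else.
#'
#' @param probe probe radius, Angstrom.
#' @return A \linkS4class{RadiiSet}.
#' @export
defaultRadii <- function(probe = .PROBE_DEFAULT) {
  radiiSet(c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80),
           probe = probe, fallback = 1.70)
}

#' Deterministic generalized-spiral points on the unit sphere
#'
#' Golden-angle spiral: points are evenly spread, and the construction is a
#' pure function of \code{n}, so repeated SASA runs are bit-identical.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
spiralPoints <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n)
  h <- -1 + 2 * (k - 1) / (n - 1)
  theta <- acos(pmin(pmax(h, -1), 1))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = sin(theta) * cos(phi),
        y = sin(theta) * sin(phi),
        z = cos(theta))
}

.atomRadii <- function(elements, radii) {
  r <- radii@radii[elements]
  unknown <- is.na(r)
  if (any(unknown)) {
    if (is.na(radii@fallback))
      stop("no van der Waals radius for element(s): ",
           paste(unique(elements[unknown]), collapse = ", "))
    warning("no van der Waals radius for element(s) ",
            paste(unique(elements[unknown]), collapse = ", "),
            "; using fallback ", radii@fallback, " Angstrom")
    r[unknown] <- radii@fallback
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic Shrake-Rupley: each atom's solvent sphere (vdW radius +
#' probe) is sampled with a fixed spiral lattice of \code{nPoints} points,
#' and its area is \eqn{4\pi (r_i + p)^2} times the fraction of lattice
#' points not inside any neighbouring solvent sphere.  Hydrogens are
#' excluded from the calculation by default (they neither gain area nor
#' occlude).
#'
#' @param model \linkS4class{StructureModel}.
#' @param radii \linkS4class{RadiiSet}.
#' @param nPoints lattice points per atom (default 960).
#' @param modelIndex coordinate model to use.
#' @param ignoreHydrogens drop H/D before computing (default TRUE).
#' @return A \linkS4class{SasaResult} with per-atom areas and per-residue
#'   total and side-chain areas.
#' @examples
#' one <- makeSphereCluster(matrix(0, 1, 3), 1.7)
#' sum(computeSasa(one$model, one$radii)@atomArea)  # ~ 4*pi*3.1^2
#' @export
computeSasa <- function(model, radii = defaultRadii(), nPoints = 960L,
                        modelIndex = 1L, ignoreHydrogens = TRUE) {
  stopifnot(is(model, "StructureModel"), is(radii, "RadiiSet"))
  a <- model@atoms
  idx <- seq_len(nrow(a))
  if (ignoreHydrogens) idx <- idx[!(a$element[idx] %in% c("H", "D"))]
  if (!length(idx)) stop("no heavy atoms present")
  xyz <- atomCoords(model, modelIndex)[idx, , drop = FALSE]
  r <- .atomRadii(a$element[idx], radii) + radii@probe
  n <- length(idx)

  pts <- spiralPoints(nPoints)
  area <- numeric(n)
  # neighbour lists from the pairwise distance matrix; a pair can occlude
  # only when centres are closer than the sum of solvent radii
  d2 <- as.matrix(stats::dist(xyz))^2
  rsum2 <- outer(r, r, "+")^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ] & seq_len(n) != i)
    if (!length(nb)) { area[i] <- 4 * pi * r[i]^2; next }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")       # lattice on atom i
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
            (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj > r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / nPoints
  }

  sub <- a[idx, , drop = FALSE]
  resKey <- paste(sub$chain, sub$resseq, sub$icode, sep = "\r")
  firstOfRes <- !duplicated(resKey)
  sideChain <- !(sub$name %in% .BACKBONE)
  residueArea <- data.frame(
    chain   = sub$chain[firstOfRes],
    resseq  = sub$resseq[firstOfRes],
    icode   = sub$icode[firstOfRes],
    resname = sub$resname[firstOfRes],
    area    = as.numeric(tapply(area, factor(resKey, levels = resKey[firstOfRes]), sum)),
    sideChainArea = as.numeric(tapply(area * sideChain,
                      factor(resKey, levels = resKey[firstOfRes]), sum)),
    stringsAsFactors = FALSE)
  rownames(residueArea) <- NULL

  new("SasaResult", atomArea = area, atomIndex = as.integer(idx),
      residueArea = residueArea, probe = radii@probe,
      nPoints = as.integer(nPoints))
}
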