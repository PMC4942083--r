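## One-site (Wiseman) binding isotherm and per-injection heat bookkeeping.

#' Total heat content of the cell under the one-site binding model
#'
#' Closed-form total heat for a macromolecule M at total concentration
#' \code{Mt} with \code{n} equivalent sites of association constant K,
#' titrant at total concentration \code{Xt}, in an active volume V0:
#' \deqn{Q = \frac{n M_t \Delta H V_0}{2}\left[b - \sqrt{b^2 - 4 X_t/(n M_t)}\right],
#'   \quad b = 1 + \frac{X_t}{n M_t} + \frac{1}{n K M_t}}
#' The negative root is the physical one: it keeps the bound fraction within
#' \code{[0, min(1, Xt/(n Mt))]}.
#'
#' @param params \linkS4class{OneSiteParams}.
#' @param Mt macromolecule total concentration, mol/L (vectorized).
#' @param Xt titrant total concentration, mol/L (vectorized, >= 0).
#' @param V0 active cell volume, liters.
#' @return Total heat in kilocalories (same length as Mt/Xt).
#' @examples
#' p <- OneSiteParams(K = 1e7, dH = -10)
#' oneSiteTotalHeat(p, Mt = 5e-6, Xt = 2.5e-6, V0 = 1.4e-3)
#' @export
oneSiteTotalHeat <- function(params, Mt, Xt, V0) {
  stopifnot(is(params, "OneSiteParams"))
  if (any(Mt <= 0)) stop("Mt must be strictly positive")
  if (any(Xt < 0)) stop("Xt must be nonnegative")
  if (V0 <= 0) stop("V0 must be strictly positive")
  n <- params@n; K <- params@K; dH <- params@dH
  b <- 1 + Xt / (n * Mt) + 1 / (n * K * Mt)
  disc <- b^2 - 4 * Xt / (n * Mt)
  bad <- disc < 0
  if (any(bad)) {
    # roundoff can push the discriminant an epsilon below zero near saturation
    tiny <- abs(disc) <= 1e-12 * b^2
    disc[bad & tiny] <- 0
    if (any(bad & !tiny))
      stop(sprintf(
        "negative discriminant in one-site heat (n=%g, K=%g, Mt=%g, Xt=%g)",
        n, K, Mt[which(bad & !tiny)[1]], Xt[which(bad & !tiny)[1]]))
  }
  (n * Mt * dH * V0 / 2) * (b - sqrt(disc))
}

#' Cell concentrations after cumulative injection (perfusion approximation)
#'
#' For a perfusion cell of volume V0 that has received a cumulative injected
#' volume v, the standard displaced-volume approximation gives
#' \deqn{M_t = M_{t0}\frac{1 - v/2V_0}{1 + v/2V_0}, \qquad
#'       X_t = X_{t0}\frac{v/V_0}{1 + v/2V_0}.}
#' This is a bookkeeping convention, not a physical model of mixing.
#'
#' @param cellConc initial macromolecule concentration, mol/L.
#' @param syringeConc syringe titrant concentration, mol/L.
#' @param cumVolume cumulative injected volume(s), liters (vectorized).
#' @param V0 cell volume, liters.
#' @return list with components \code{Mt} and \code{Xt} (mol/L).
#' @export
dilutedConcentrations <- function(cellConc, syringeConc, cumVolume, V0) {
  f <- cumVolume / (2 * V0)
  list(Mt = cellConc * (1 - f) / (1 + f),
       Xt = syringeConc * (cumVolume / V0) / (1 + f))
}

#' Per-injection heats for a titration design
#'
#' Differences the total-heat curve across injections with the displaced-
#' volume correction used by perfusion instruments:
#' \deqn{\Delta Q_i = Q_i + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2} - Q_{i-1}}
#' with \eqn{Q_0 = 0} and cell concentrations updated per
#' \code{\link{dilutedConcentrations}} after each injection.
#'
#' @param params \linkS4class{OneSiteParams}.
#' @param exp \linkS4class{TitrationExperiment} (heats, if present, ignored).
#' @return Numeric vector of per-injection heats in microcalories.
#' @examples
#' d <- defaultITCDesign()
#' head(injectionSeries(OneSiteParams(K = 1.9e7, dH = -23.8), d))
#' @export
injectionSeries <- function(params, exp) {
  stopifnot(is(params, "OneSiteParams"), is(exp, "TitrationExperiment"))
  validObject(exp)
  dv <- exp@injectionVolumes
  V0 <- exp@cellVolume
  v <- cumsum(dv)
  conc <- dilutedConcentrations(exp@cellConc, exp@syringeConc, v, V0)
  Q <- oneSiteTotalHeat(params, conc$Mt, conc$Xt, V0)   # kcal
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q + (dv / V0) * (Q + Qprev) / 2 - Qprev
  dQ * .UCAL_PER_KCAL
}

#' Default titration design
#'
#' The package-wide reference design: 40 injections of 7 uL into a 1.4 mL
#' cell holding 5 uM macromolecule, titrated from a 50 uM syringe at 25 C.
#'
#' @param nInjections number of injections.
#' @param injectionVolume per-injection volume, liters.
#' @param cellConc cell concentration, mol/L.
#' @param syringeConc syringe concentration, mol/L.
#' @param temperature kelvin.
#' @param cellVolume liters.
#' @param label experiment label.
#' @return Design-only \linkS4class{TitrationExperiment}.
#' @export
defaultITCDesign <- function(nInjections = 40, injectionVolume = 7e-6,
                             cellConc = 5e-6, syringeConc = 50e-6,
                             temperature = .T_DEFAULT, cellVolume = 1.4e-3,
                             label = "design") {
  TitrationExperiment(rep(injectionVolume, nInjections),
                      cellConc = cellConc, syringeConc = syringeConc,
                      temperature = temperature, cellVolume = cellVolume,
                      label = label)
}

#' Molar ratio (titrant over macromolecule) after each injection
#'
#' @param exp \linkS4class{TitrationExperiment}.
#' @return Numeric vector Xt/Mt after each injection.
#' @export
molarRatio <- function(exp) {
  v <- cumsum(exp@injectionVolumes)
  conc <- dilutedConcentrations(exp@cellConc, exp@syringeConc, v,
                                exp@cellVolume)
  conc$Xt / conc$Mt
}
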