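## Nonlinear least-squares fitting of the one-site isotherm.

#' Fit the one-site binding model to a titration
#'
#' Levenberg-Marquardt least squares (via \code{minpack.lm::nls.lm}) of the
#' observed per-injection heats against \code{\link{injectionSeries}}, over
#' (n, K, dH).  K is fitted on a log10 scale for conditioning, with box
#' constraints K in [1, 1e15] 1/M and n in [0.1, 10].  Standard errors come
#' from the local curvature (Jacobian) at the optimum; the error for K is
#' propagated from the log-scale error by the delta method.
#'
#' Default initialisation: n = 1; dH from the first two injection heats
#' normalised by the moles injected; K = 10 / cellConc (i.e. Kd one tenth of
#' the cell concentration).
#'
#' @param exp \linkS4class{TitrationExperiment} with at least 5 observed
#'   heats, not all zero.
#' @param init optional \linkS4class{OneSiteParams} starting values.
#' @param fixN fit with the stoichiometry frozen at its starting value
#'   (useful for low-c titrations where n is not identifiable).
#' @param maxIterations optimizer cap.
#' @return A \linkS4class{OneSiteFit}.  Non-convergence is flagged in the
#'   \code{converged} slot, never silent.
#' @examples
#' truth <- OneSiteParams(K = 1.9e7, dH = -23.8)
#' exp <- simulateThermogram(truth, noise = 0)
#' fittedParams(fitOneSite(exp))
#' @export
fitOneSite <- function(exp, init = NULL, fixN = FALSE, maxIterations = 200) {
  stopifnot(is(exp, "TitrationExperiment"))
  validObject(exp)
  y <- exp@observedHeats
  if (length(y) < 5)
    stop("at least 5 observed injections are required to fit")
  if (all(y == 0))
    stop("all observed heats are zero; nothing to fit")

  if (is.null(init)) {
    dv <- exp@injectionVolumes
    molesFirst2 <- exp@syringeConc * sum(dv[1:2])
    dH0 <- sum(y[1:2]) / .UCAL_PER_KCAL / molesFirst2
    if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
    init <- OneSiteParams(n = 1, K = 10 / exp@cellConc, dH = dH0)
  }
  stopifnot(is(init, "OneSiteParams"))

  lowerK <- 0; upperK <- 15                      # log10 K bounds
  if (fixN) {
    par0  <- c(logK = log10(init@K), dH = init@dH)
    lower <- c(lowerK, -Inf); upper <- c(upperK, Inf)
    unpack <- function(p) OneSiteParams(init@n, 10^p[[1]], p[[2]])
  } else {
    par0  <- c(n = init@n, logK = log10(init@K), dH = init@dH)
    lower <- c(0.1, lowerK, -Inf); upper <- c(10, upperK, Inf)
    unpack <- function(p) OneSiteParams(p[[1]], 10^p[[2]], p[[3]])
  }
  par0 <- pmin(pmax(par0, lower), upper)

  residFun <- function(p) y - injectionSeries(unpack(p), exp)
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = residFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxIterations, maxfev = 10000))

  params <- unpack(fit$par)
  converged <- fit$info %in% 1:4

  # curvature-based standard errors; delta method for K from log10 K
  se <- c(n = NA_real_, K = NA_real_, dH = NA_real_)
  dof <- length(y) - length(fit$par)
  if (dof > 0) {
    s2 <- fit$deviance / dof
    covp <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
    if (!is.null(covp)) {
      d <- sqrt(pmax(diag(covp), 0))
      if (fixN) {
        se["K"]  <- params@K * log(10) * d[[1]]
        se["dH"] <- d[[2]]
        se["n"]  <- 0
      } else {
        se["n"]  <- d[[1]]
        se["K"]  <- params@K * log(10) * d[[2]]
        se["dH"] <- d[[3]]
      }
    }
  }

  new("OneSiteFit", params = params, stdErrors = se,
      residuals = as.numeric(fit$fvec), converged = converged,
      nIterations = as.integer(fit$niter))
}
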