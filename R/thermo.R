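## Derived binding thermodynamics: dG, -TdS, ddG, fold changes, coupling.

#' Standard binding free energy from an association constant
#'
#' \eqn{\Delta G^\circ = -RT\ln K}, R = 1.987204e-3 kcal/(mol K).
#'
#' @param K association constant, 1/M (vectorized, > 0).
#' @param temperature kelvin (> 0), default 298.15.
#' @return kcal/mol.
#' @examples
#' freeEnergy(5.7e8)   # -11.9 kcal/mol at 25 C
#' @export
freeEnergy <- function(K, temperature = .T_DEFAULT) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("association constant K must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  -.R_KCAL * temperature * log(K)
}

#' Entropic term -TdS from free energy and enthalpy
#'
#' \eqn{-T\Delta S^\circ = \Delta G^\circ - \Delta H^\circ}.
#'
#' @param dG kcal/mol.
#' @param dH kcal/mol.
#' @return kcal/mol.
#' @examples
#' entropyTerm(-9.9, -23.8)  # 13.9: entropically opposed binding
#' @export
entropyTerm <- function(dG, dH) {
  if (any(!is.finite(dG)) || any(!is.finite(dH)))
    stop("dG and dH must be finite")
  dG - dH
}

#' Mutant binding penalty ddG from association constants
#'
#' \eqn{\Delta\Delta G^\circ = RT \ln(K_{ref}/K_{mut})}; positive when the
#' mutant binds more weakly than the reference.  Computed from K, never from
#' rounded Kd values.
#'
#' @param Kref reference association constant, 1/M.
#' @param Kmut mutant association constant, 1/M.
#' @param temperature kelvin.
#' @return kcal/mol (vectorized over Kmut).
#' @examples
#' ddGFromK(5.7e8, 4.3e6)  # ~2.9 kcal/mol penalty
#' @export
ddGFromK <- function(Kref, Kmut, temperature = .T_DEFAULT) {
  if (any(Kref <= 0) || any(Kmut <= 0))
    stop("association constants must be positive")
  .R_KCAL * temperature * log(Kref / Kmut)
}

#' Fold change in affinity between dissociation constants
#'
#' Returns the raw ratio Kd_mut / Kd_ref; \code{\link{roundHalfUp}} is the
#' reporting convention for in-text integer fold changes.
#'
#' @param KdMut mutant dissociation constant (any unit, both alike).
#' @param KdRef reference dissociation constant.
#' @return Dimensionless ratio.
#' @examples
#' foldChange(0.279, 0.002)               # 139.5
#' roundHalfUp(foldChange(0.279, 0.002))  # reported as 140-fold
#' @export
foldChange <- function(KdMut, KdRef) {
  if (any(KdMut <= 0) || any(KdRef <= 0))
    stop("dissociation constants must be positive")
  KdMut / KdRef
}

#' Round half away from zero to the nearest integer
#'
#' Reporting convention for fold changes (64.5 reports as 65), unlike base
#' R's banker's rounding.
#'
#' @param x numeric.
#' @return numeric integer values.
#' @export
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Double-mutant-cycle coupling energy
#'
#' For single mutants A and B and the double mutant AB,
#' \eqn{\Delta\Delta G_{int} = \Delta\Delta G_{AB} - \Delta\Delta G_{A} -
#' \Delta\Delta G_{B}}.  A positive interaction energy means the double
#' mutant is worse than additive, i.e. the two residues are energetically
#' coupled.
#'
#' @param ddG_A,ddG_B single-mutant penalties, kcal/mol.
#' @param ddG_AB double-mutant penalty, kcal/mol.
#' @return list with ddG_A, ddG_B, ddG_AB and ddG_interaction (kcal/mol).
#' @examples
#' couplingEnergy(1.2, 0.7, 2.4)$ddG_interaction  # 0.5: nonadditive
#' @export
couplingEnergy <- function(ddG_A, ddG_B, ddG_AB) {
  if (any(!is.finite(c(ddG_A, ddG_B, ddG_AB))))
    stop("coupling inputs must be finite")
  list(ddG_A = ddG_A, ddG_B = ddG_B, ddG_AB = ddG_AB,
       ddG_interaction = ddG_AB - ddG_A - ddG_B)
}

#' Build a thermodynamic summary table from fitted parameters
#'
#' One row per complex with all derived columns (Kd, dG, dH, -TdS and ddG
#' against a designated reference row).  Stored values are never rounded;
#' \code{\link{writeThermoTable}} applies display rounding.
#'
#' @param fits named list of \linkS4class{OneSiteParams} or
#'   \linkS4class{OneSiteFit}; names are the syringe/complex labels.
#' @param reference name of the reference entry for the ddG column.
#' @param temperature kelvin.
#' @param cell cell-side label(s), recycled across rows.
#' @return data.frame with columns cell, syringe, K_per_M, Kd_uM, dG, dH,
#'   mTdS, ddG (reference row ddG is NA).
#' @examples
#' fits <- list(`Hairless` = OneSiteParams(K = 5.7e8, dH = -11.9),
#'              `H-L235A`  = OneSiteParams(K = 1.7e7, dH = -9.6))
#' buildThermoTable(fits, reference = "Hairless", cell = "Su(H)")
#' @export
buildThermoTable <- function(fits, reference, temperature = .T_DEFAULT,
                             cell = "") {
  if (!length(fits) || is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("fits must be a non-empty named list")
  if (!reference %in% names(fits))
    stop("reference label '", reference, "' not found among fits")
  params <- lapply(fits, function(f) {
    if (is(f, "OneSiteFit")) f@params
    else if (is(f, "OneSiteParams")) f
    else stop("fits must contain OneSiteParams or OneSiteFit objects")
  })
  K  <- vapply(params, slot, numeric(1), "K")
  dH <- vapply(params, slot, numeric(1), "dH")
  dG <- freeEnergy(K, temperature)
  tbl <- data.frame(
    cell     = rep_len(cell, length(K)),
    syringe  = names(fits),
    K_per_M  = unname(K),
    Kd_uM    = unname(1e6 / K),
    dG       = unname(dG),
    dH       = unname(dH),
    mTdS     = unname(entropyTerm(dG, dH)),
    ddG      = unname(ddGFromK(K[[reference]], K, temperature)),
    stringsAsFactors = FALSE
  )
  tbl$ddG[tbl$syringe == reference] <- NA_real_
  rownames(tbl) <- NULL
  tbl
}

#' Write a thermodynamic table as TSV with display rounding
#'
#' Energies are rounded to one decimal for display; K keeps full precision
#' in scientific notation and Kd is printed to three decimals (uM).
#'
#' @param tbl data.frame from \code{\link{buildThermoTable}}.
#' @param file output path or connection.
#' @return Invisibly, the formatted data.frame that was written.
#' @export
writeThermoTable <- function(tbl, file) {
  out <- data.frame(
    cell     = tbl$cell,
    syringe  = tbl$syringe,
    K_per_M  = sprintf("%.4g", tbl$K_per_M),
    Kd_uM    = sprintf("%.3f", tbl$Kd_uM),
    dG       = sprintf("%.1f", tbl$dG),
    dH       = sprintf("%.1f", tbl$dH),
    mTdS     = sprintf("%.1f", tbl$mTdS),
    ddG      = ifelse(is.na(tbl$ddG), "n/a", sprintf("%.1f", tbl$ddG)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
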