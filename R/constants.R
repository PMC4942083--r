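#' Physical constants and unit conversions used throughout the package
#'
#' A single authoritative record of the constants the thermodynamic layer
#' relies on. Heats are stored in microcalories at the experiment boundary
#' while the binding model works in kilocalories internally; the conversion
#' factor is 1 kcal = 1e3 cal = 1e9 ucal.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{R_kcal}{gas constant, 1.987204e-3 kcal mol^-1 K^-1}
#'     \item{T_default}{default analysis temperature, 298.15 K (25 C)}
#'     \item{ucal_per_kcal}{1e9, microcalories per kilocalorie}
#'     \item{probe_default}{1.4 Angstrom water-probe radius}
#'   }
#' @examples
#' thermoConstants()$R_kcal
#' @export
thermoConstants <- function() {
  list(
    R_kcal        = 1.987204e-3,
    T_default     = 298.15,
    ucal_per_kcal = 1e9,
    probe_default = 1.4
  )
}

.R_KCAL        <- 1.987204e-3
.T_DEFAULT     <- 298.15
.UCAL_PER_KCAL <- 1e9
.PROBE_DEFAULT <- 1.4

# backbone atom names excluded from side-chain selections
.BACKBONE <- c("N", "CA", "C", "O", "OXT")
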