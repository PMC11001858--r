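# Unit conversions. External interfaces use clinical units (mmHg, mL/min);
# everything inside the solver and the lumped elements is SI (Pa, m^3/s).

#' Unit conversion constants and helpers
#'
#' The package accepts clinical units at every user-facing interface
#' (pressures in mmHg, volumetric flows in mL/min) and converts to coherent SI
#' units (Pa, m\eqn{^3}/s) internally. 1 mmHg = 133.322 Pa and
#' 1 mL/min = 1/6e7 m\eqn{^3}/s.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
NULL

MMHG_PER_PA <- 1 / 133.322
PA_PER_MMHG <- 133.322
M3S_PER_MLMIN <- 1 / 6e7
MLMIN_PER_M3S <- 6e7

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * PA_PER_MMHG

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x * MMHG_PER_PA

#' @rdname units
#' @export
mlmin_to_m3s <- function(x) x * M3S_PER_MLMIN

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x * MLMIN_PER_M3S

#' Canonical vessel labels of the Circle-of-Willis recording layout
#'
#' Four feeding vessels (internal carotid and vertebral arteries) and six
#' outflow vessels (anterior, middle and posterior cerebral arteries, left and
#' right each).
#'
#' @return A list with character vectors `inlets` and `outlets`.
#' @export
#' @examples
#' cow_vessels()
cow_vessels <- function() {
  list(
    inlets = c("LICA", "RICA", "LVA", "RVA"),
    outlets = c("LACA", "RACA", "LMCA", "RMCA", "LPCA", "RPCA")
  )
}

# left/right members -> vessel class, used for side-averaged parameters
cow_outlet_class <- function(outlet) {
  map <- c(
    LACA = "ACA", RACA = "ACA",
    LMCA = "MCA", RMCA = "MCA",
    LPCA = "PCA", RPCA = "PCA"
  )
  unname(map[outlet])
}

#' Working-fluid properties
#'
#' Defaults match a water–glycerol blood analogue: dynamic viscosity
#' 4.01 mPa s, density 1.137 g/mL.
#'
#' @param rho density in kg/m^3.
#' @param mu dynamic viscosity in Pa s.
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(rho = 1137, mu = 4.01e-3) {
  stopifnot(is.numeric(rho), is.numeric(mu), rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_props")
}
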