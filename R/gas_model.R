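#' @useDynLib gasphantom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Unit constants. All internal pressure arithmetic is in mmHg absolute;
# psi is accepted at the interface only.
MMHG_PER_ATM <- 760
MMHG_PER_PSI <- 51.7149
PSI_PER_ATM <- MMHG_PER_ATM / MMHG_PER_PSI  # ~14.696, kept exactly consistent

#' Atmospheric pressure in mmHg
#'
#' Absolute ambient pressure at 1 atm, the reference for non-dimensional
#' tension maps and the floor for chamber pressure schedules.
#' @return 760 (mmHg)
#' @export
atm_mmHg <- function() MMHG_PER_ATM

#' Define a gas species
#'
#' Bundles the physical constants of one dissolved gas: the Henry solubility
#' constant relating dissolved concentration to partial pressure, the bulk
#' diffusion coefficient in the hydrogel, and the species' mole fraction in
#' the chamber gas.
#'
#' @param name Species label, e.g. `"O2"`.
#' @param k_h Henry solubility constant, mol m^-3 mmHg^-1. Must be > 0.
#' @param D Diffusion coefficient, m^2 s^-1. Must be > 0.
#' @param mole_fraction Fraction of the chamber gas, in \[0, 1\].
#' @return A `gas_species` object (named list).
#' @examples
#' gas_species("O2", k_h = 1.3e-3, D = 2.5e-9, mole_fraction = 0.21)
#' @export
gas_species <- function(name, k_h, D, mole_fraction) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(k_h) || length(k_h) != 1 || !is.finite(k_h) || k_h <= 0)
    stop("k_h must be a single positive number (mol m^-3 mmHg^-1)")
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D <= 0)
    stop("D must be a single positive number (m^2 s^-1)")
  if (!is.numeric(mole_fraction) || length(mole_fraction) != 1 ||
      !is.finite(mole_fraction) || mole_fraction < 0 || mole_fraction > 1)
    stop("mole_fraction must lie in [0, 1]")
  structure(list(name = name, k_h = k_h, D = D, mole_fraction = mole_fraction),
            class = "gas_species")
}

#' Default chamber gas: dry air as O2 + N2
#'
#' The chamber gas is modelled as dry air partitioned into oxygen (0.21) and
#' nitrogen (0.79); water vapour and CO2 are ignored. Henry constants default
#' to aqueous solubilities at 37 C (the hydrogel is >95% water); the oxygen
#' diffusion coefficient defaults to 2.5e-9 m^2 s^-1. CO2, though roughly
#' 20-fold more soluble than O2 (the physiological "oxygen window"), is not
#' transported. All constants are overridable.
#'
#' @param k_h_O2,k_h_N2 Henry constants, mol m^-3 mmHg^-1.
#' @param D_O2,D_N2 Diffusion coefficients, m^2 s^-1.
#' @return A named list of two `gas_species` (`O2`, `N2`) whose mole
#'   fractions sum to 1.
#' @export
default_species <- function(k_h_O2 = 1.3e-3, k_h_N2 = 7.2e-4,
                            D_O2 = 2.5e-9, D_N2 = 2.0e-9) {
  list(
    O2 = gas_species("O2", k_h = k_h_O2, D = D_O2, mole_fraction = 0.21),
    N2 = gas_species("N2", k_h = k_h_N2, D = D_N2, mole_fraction = 0.79)
  )
}

#' Validate a species set
#'
#' Checks that each element is a `gas_species` and that mole fractions sum
#' to 1 within 1e-9 (Dalton closure of the chamber gas).
#' @param species Named list of `gas_species`.
#' @return The species list, invisibly.
#' @export
validate_species <- function(species) {
  stopifnot(is.list(species), length(species) >= 1)
  ok <- vapply(species, inherits, logical(1), what = "gas_species")
  if (!all(ok)) stop("all elements must be gas_species objects")
  total <- sum(vapply(species, `[[`, numeric(1), "mole_fraction"))
  if (abs(total - 1) > 1e-9)
    stop(sprintf("species mole fractions sum to %.12f, not 1", total))
  invisible(species)
}

#' Michaelis-Menten consumption parameters
#'
#' The saturable cellular oxygen consumption model: `V_max` is the maximum
#' per-cell consumption rate and `K_m` the partial pressure at which
#' consumption is half-maximal.
#'
#' @param V_max Maximum consumption rate, mol cell^-1 s^-1 (>= 0).
#' @param K_m Half-maximal partial pressure, mmHg (> 0).
#' @return An `mm_params` object.
#' @export
mm_params <- function(V_max = 3e-17, K_m = 5.6) {
  if (!is.numeric(V_max) || length(V_max) != 1 || !is.finite(V_max) || V_max < 0)
    stop("V_max must be a single non-negative number")
  if (!is.numeric(K_m) || length(K_m) != 1 || !is.finite(K_m) || K_m <= 0)
    stop("K_m must be a single positive number (mmHg)")
  structure(list(V_max = V_max, K_m = K_m), class = "mm_params")
}

#' Cell density
#'
#' Cell seeding density, stated in cells/ml as in culture practice; internal
#' rate arithmetic converts to cells m^-3 (x 1e6).
#' @param cells_per_ml Cells per millilitre (>= 0).
#' @return A `cell_density` object with fields `cells_per_ml`, `cells_per_m3`.
#' @export
cell_density <- function(cells_per_ml) {
  if (!is.numeric(cells_per_ml) || length(cells_per_ml) != 1 ||
      !is.finite(cells_per_ml) || cells_per_ml < 0)
    stop("cells_per_ml must be a single non-negative number")
  structure(list(cells_per_ml = cells_per_ml,
                 cells_per_m3 = cells_per_ml * 1e6),
            class = "cell_density")
}

#' Henry's-law dissolved concentration
#'
#' Dissolved gas concentration at equilibrium with a partial pressure:
#' `C = k_h * pp`.
#'
#' @param k_h Henry constant, mol m^-3 mmHg^-1 (> 0).
#' @param pp Partial pressure, mmHg (>= 0). Vectorised.
#' @return Concentration, mol m^-3.
#' @examples
#' henry_concentration(1.3e-3, 160)
#' @export
henry_concentration <- function(k_h, pp) {
  if (!is.numeric(k_h) || any(k_h <= 0)) stop("k_h must be positive")
  if (!is.numeric(pp) || any(pp < 0)) stop("pp must be non-negative (mmHg)")
  k_h * pp
}

#' Michaelis-Menten oxygen sink rate
#'
#' Rate at which cellular metabolism removes dissolved oxygen, expressed as a
#' partial-pressure sink: `V_max * pp / (pp + K_m) * sigma / k_h`, with sigma
#' in cells m^-3. Saturates at `V_max * sigma / k_h` for pp >> K_m.
#'
#' @param pp Oxygen partial pressure, mmHg (>= 0). Vectorised.
#' @param mm An [mm_params()] object.
#' @param sigma A [cell_density()] object.
#' @param k_h Oxygen Henry constant, mol m^-3 mmHg^-1 (> 0).
#' @return Sink rate, mmHg s^-1 (same shape as `pp`).
#' @export
mm_consumption_rate <- function(pp, mm, sigma, k_h) {
  stopifnot(inherits(mm, "mm_params"), inherits(sigma, "cell_density"))
  if (!is.numeric(k_h) || length(k_h) != 1 || k_h <= 0)
    stop("k_h must be a single positive number")
  if (any(pp < 0)) stop("pp must be non-negative (mmHg)")
  mm$V_max * pp / (pp + mm$K_m) * sigma$cells_per_m3 / k_h
}

#' Pressure unit conversions
#'
#' `psi_to_mmHg()` and `mmHg_to_psi()` convert between psi and mmHg using
#' 1 psi = 51.7149 mmHg (1 atm = 14.696 psi = 760 mmHg).
#'
#' @param p Pressure (vectorised, >= 0).
#' @return Converted pressure.
#' @export
psi_to_mmHg <- function(p) {
  if (any(p < 0)) stop("pressure must be non-negative")
  p * MMHG_PER_PSI
}

#' @rdname psi_to_mmHg
#' @export
mmHg_to_psi <- function(p) {
  if (any(p < 0)) stop("pressure must be non-negative")
  p / MMHG_PER_PSI
}

#' Ambient partial pressure of one species
#'
#' Dalton partition: partial pressure = mole fraction x total absolute
#' pressure.
#'
#' @param total_pressure Total absolute pressure, mmHg (vectorised, >= 0).
#' @param species A [gas_species()].
#' @return Partial pressure, mmHg.
#' @export
ambient_pp <- function(total_pressure, species) {
  stopifnot(inherits(species, "gas_species"))
  if (any(total_pressure < 0)) stop("total_pressure must be non-negative")
  species$mole_fraction * total_pressure
}

#' Non-dimensionalise partial pressures
#'
#' Divides values in mmHg by atmospheric pressure (760 mmHg), the
#' normalisation used for tension maps.
#' @param x Values in mmHg (any shape).
#' @return `x / 760`, dimensionless.
#' @export
nondimensionalise <- function(x) x / MMHG_PER_ATM
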