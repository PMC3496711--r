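#' Construct a Forster system
#'
#' Bundles the photophysical parameters of a donor-acceptor FRET pair:
#' the donor excited-state lifetime in the absence of acceptor, the Forster
#' distance, the refractive index of the medium, the donor quantum yield,
#' and the orientational averaging regime.
#'
#' @param tau0D Donor excited-state (fluorescence) lifetime in the absence of
#'   acceptor, in ns. Must be positive.
#' @param R0 Forster distance in nm: the separation at which half of donor
#'   excitations are transferred. Must be non-negative. The conventional
#'   isotropic dynamic average orientation factor (kappa^2 = 2/3) is assumed
#'   to be embedded in this value.
#' @param refractive_index Refractive index of the medium (>= 1).
#' @param QD Donor fluorescence quantum yield in the absence of acceptor,
#'   in `[0, 1]`, or `NA` if unknown (not needed for rate/efficiency work).
#' @param regime Orientational averaging regime: `"dynamic"` (dipoles
#'   reorient fast relative to transfer, kappa^2 averages to 2/3) or
#'   `"static"` (each pair keeps a fixed kappa^2 during the excited state).
#'
#' @return An object of class `forster_system`.
#' @examples
#' cerulean_venus <- forster_system(tau0D = 3, R0 = 5.4)
#' efficiency_from_distance(5.4, cerulean_venus)
#' @export
forster_system <- function(tau0D, R0, refractive_index = 1.33, QD = NA_real_,
                           regime = c("dynamic", "static")) {
  regime <- match.arg(regime)
  if (!is.numeric(tau0D) || length(tau0D) != 1L || !is.finite(tau0D) || tau0D <= 0)
    stop("`tau0D` must be a single positive number (ns)")
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 < 0)
    stop("`R0` must be a single non-negative number (nm)")
  if (!is.finite(refractive_index) || refractive_index < 1)
    stop("`refractive_index` must be >= 1")
  if (!is.na(QD) && (QD < 0 || QD > 1))
    stop("`QD` must lie in [0, 1]")
  structure(
    list(tau0D = as.numeric(tau0D), R0 = as.numeric(R0),
         refractive_index = as.numeric(refractive_index),
         QD = as.numeric(QD), regime = regime),
    class = "forster_system"
  )
}

#' @export
print.forster_system <- function(x, ...) {
  cat("Forster system\n")
  cat(sprintf("  tau0D: %g ns   R0: %g nm   n: %g   QD: %s   regime: %s\n",
              x$tau0D, x$R0, x$refractive_index,
              ifelse(is.na(x$QD), "NA", format(x$QD)), x$regime))
  invisible(x)
}

as_forster_system <- function(system) {
  if (!inherits(system, "forster_system"))
    stop("`system` must be a `forster_system` object; see forster_system()")
  system
}

#' FRET efficiency of a fixed pair at a given separation
#'
#' Computes `E = 1 / (1 + (R_DA / R0)^6)`, the transfer efficiency of a
#' single donor-acceptor pair at separation `R_DA` given the system's
#' Forster distance. Strictly decreasing in `R_DA` with `E(R0) = 0.5`.
#'
#' @param R_DA Donor-acceptor separation(s) in nm; positive.
#' @param system A [forster_system()] with `R0 > 0`.
#' @return Efficiency value(s) in (0, 1).
#' @export
efficiency_from_distance <- function(R_DA, system) {
  system <- as_forster_system(system)
  if (system$R0 <= 0) stop("`system$R0` must be positive")
  if (any(!is.finite(R_DA)) || any(R_DA <= 0))
    stop("`R_DA` must be positive and finite")
  1 / (1 + (R_DA / system$R0)^6)
}

#' FRET transfer rate constant at a given separation
#'
#' Computes `k_T = (1 / tau0D) * (R0 / R_DA)^6`, the rate of donor-to-
#' acceptor energy transfer for a fixed pair in the dynamic averaging
#' regime (kappa^2 = 2/3 embedded in `R0`).
#'
#' @inheritParams efficiency_from_distance
#' @return Transfer rate(s) in ns^-1.
#' @seealso [static_transfer_rate()] for the static-regime per-pair rate.
#' @export
transfer_rate <- function(R_DA, system) {
  system <- as_forster_system(system)
  if (any(!is.finite(R_DA)) || any(R_DA <= 0))
    stop("`R_DA` must be positive and finite")
  (1 / system$tau0D) * (system$R0 / R_DA)^6
}

#' FRET efficiency from a transfer rate constant
#'
#' `E = k_T / (k_T + 1/tau0D)`: the fraction of donor de-excitation events
#' that proceed through energy transfer.
#'
#' @param k_T Transfer rate constant(s), ns^-1, non-negative.
#' @param tau0D Donor lifetime in the absence of acceptor, ns.
#' @return Efficiency value(s) in `[0, 1)`.
#' @export
efficiency_from_rate <- function(k_T, tau0D) {
  if (!is.finite(tau0D) || tau0D <= 0) stop("`tau0D` must be positive")
  if (any(!is.finite(k_T)) || any(k_T < 0))
    stop("`k_T` must be non-negative and finite")
  k_T / (k_T + 1 / tau0D)
}

#' Forster distance from photophysical parameters
#'
#' `R0 = (0.02108 * kappa2 * QD * n^-4 * J)^(1/6)` in nm, with the overlap
#' integral `J` in nm^4 cm^2 / mmole. Returns 0 whenever `J`, `kappa2` or
#' `QD` is 0 (no overlap, perpendicular dipoles, or a dark donor all
#' abolish transfer).
#'
#' @param QD Donor quantum yield in the absence of acceptor.
#' @param J Spectral overlap integral, nm^4 cm^2 / mmole.
#' @param n Refractive index of the medium (>= 1).
#' @param kappa2 Dipole orientation factor, in `[0, 4]`; 2/3 for the dynamic
#'   random isotropic average.
#' @return Forster distance in nm.
#' @export
forster_radius <- function(QD, J, n = 1.33, kappa2 = 2 / 3) {
  if (any(c(QD, J, kappa2) < 0)) stop("`QD`, `J` and `kappa2` must be >= 0")
  if (any(n < 1)) stop("`n` must be >= 1")
  (0.02108 * kappa2 * QD * n^-4 * J)^(1 / 6)
}

#' Construct an emission or extinction spectrum
#'
#' A minimal container for a one-dimensional spectrum: donor fluorescence
#' emission intensity per unit wavelength, or acceptor molar extinction
#' coefficient, tabulated on a strictly increasing wavelength grid.
#'
#' @param wavelengths Wavelengths in nm, strictly increasing, length >= 2.
#' @param values Non-negative spectral values at those wavelengths.
#' @return An object of class `fret_spectrum` (a data.frame with columns
#'   `wavelength_nm` and `value`).
#' @export
fret_spectrum <- function(wavelengths, values) {
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least 2 points")
  if (length(wavelengths) != length(values))
    stop("`wavelengths` and `values` must have equal length")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be finite and strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectral `values` must be finite and non-negative")
  structure(
    data.frame(wavelength_nm = as.numeric(wavelengths),
               value = as.numeric(values)),
    class = c("fret_spectrum", "data.frame")
  )
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects a header line and columns `wavelength_nm,value` (comma
#' separated, UTF-8).
#'
#' @param path Path to the CSV file.
#' @return A [fret_spectrum()] object.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum CSV must have columns `wavelength_nm,value`: ", path)
  fret_spectrum(df$wavelength_nm, df$value)
}

#' Spectral overlap integral
#'
#' Computes `J = integral f_D(lambda) eps_A(lambda) lambda^4 dlambda /
#' integral f_D(lambda) dlambda` by trapezoidal quadrature on the union of
#' both wavelength grids restricted to the common range, with linear
#' interpolation between tabulated points. The normalisation by the donor
#' emission area makes `J` invariant under rescaling of the donor spectrum.
#' Returns 0 when the spectra do not overlap in wavelength.
#'
#' @param donor_emission Donor emission spectrum ([fret_spectrum()]);
#'   arbitrary intensity units.
#' @param acceptor_extinction Acceptor molar extinction spectrum in
#'   cm^-1 / mmole-consistent units.
#' @return Overlap integral in nm^4 cm^2 / mmole (given the unit
#'   conventions above).
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  for (s in list(donor_emission, acceptor_extinction))
    if (!inherits(s, "fret_spectrum"))
      stop("spectra must be `fret_spectrum` objects; see fret_spectrum()")
  lo <- max(min(donor_emission$wavelength_nm), min(acceptor_extinction$wavelength_nm))
  hi <- min(max(donor_emission$wavelength_nm), max(acceptor_extinction$wavelength_nm))
  if (lo >= hi) return(0)
  grid <- sort(unique(c(
    donor_emission$wavelength_nm, acceptor_extinction$wavelength_nm, lo, hi
  )))
  grid <- grid[grid >= lo & grid <= hi]
  fD <- stats::approx(donor_emission$wavelength_nm, donor_emission$value,
                      xout = grid, rule = 1)$y
  eA <- stats::approx(acceptor_extinction$wavelength_nm, acceptor_extinction$value,
                      xout = grid, rule = 1)$y
  # denominator uses the full donor emission band, not just the overlap range
  fD_full <- donor_emission$value
  wl_full <- donor_emission$wavelength_nm
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  denom <- trapz(wl_full, fD_full)
  if (denom <= 0) return(0)
  trapz(grid, fD * eA * grid^4) / denom
}

#' Dipole-dipole orientation factor kappa^2
#'
#' `kappa^2 = cos^2(omega) * (1 + 3 cos^2(theta))`, where `theta` is the
#' angle between the donor emission dipole and the donor-acceptor
#' separation vector, and `omega` the angle between the donor electric
#' field at the acceptor and the acceptor absorption dipole. Bounded in
#' `[0, 4]`; zero whenever the acceptor dipole is perpendicular to the
#' donor field (`omega = pi/2`).
#'
#' @param theta,omega Angles in radians (vectorised; recycled).
#' @return kappa^2 value(s) in `[0, 4]`.
#' @export
kappa_squared <- function(theta, omega) {
  cos(omega)^2 * (1 + 3 * cos(theta)^2)
}

#' Mean FRET efficiency under acceptor blinking
#'
#' With a fraction `f_dark_acceptor` of acceptors in a long-lived,
#' non-absorbing dark state, those pairs transfer nothing and the ensemble
#' mean efficiency is attenuated proportionally to the bright fraction:
#' `<E_B> = (1 - f_dark_acceptor) * <E>`.
#'
#' @param E_mean Mean efficiency without blinking, in `[0, 1]`.
#' @param f_dark_acceptor Fraction of acceptors in the dark state, `[0, 1]`.
#' @return Attenuated mean efficiency.
#' @export
blinking_mean_efficiency <- function(E_mean, f_dark_acceptor) {
  if (any(E_mean < 0 | E_mean > 1)) stop("`E_mean` must lie in [0, 1]")
  if (any(f_dark_acceptor < 0 | f_dark_acceptor > 1))
    stop("`f_dark_acceptor` must lie in [0, 1]")
  (1 - f_dark_acceptor) * E_mean
}

#' Apparent Forster-distance attenuation from dark-state fractions
#'
#' Donor dark states reduce the measured quantum yield and acceptor dark
#' states reduce the measured extinction coefficient (hence the overlap
#' integral). Since R0 depends on the sixth root of the product QD * J,
#' scaling each by its bright fraction multiplies the apparent R0 by
#' `[(1 - f_dark_donor) * (1 - f_dark_acceptor)]^(1/6)`.
#'
#' This closed form is inferred from the R0 expression under bright-
#' fraction scaling; it is monotone decreasing in both fractions and equals
#' 1 when neither population blinks.
#'
#' @param f_dark_donor Fraction of donors in the dark state, `[0, 1]`.
#' @param f_dark_acceptor Fraction of acceptors in the dark state, `[0, 1]`.
#' @return Multiplicative attenuation factor on the apparent R0, in `[0, 1]`.
#' @export
r0_attenuation <- function(f_dark_donor, f_dark_acceptor) {
  if (any(f_dark_donor < 0 | f_dark_donor > 1) ||
      any(f_dark_acceptor < 0 | f_dark_acceptor > 1))
    stop("dark-state fractions must lie in [0, 1]")
  ((1 - f_dark_donor) * (1 - f_dark_acceptor))^(1 / 6)
}
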