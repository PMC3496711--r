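# ln(2 + sqrt(3)) recurs throughout the closed-form kappa^2 distribution
.kappa2_logconst <- log(2 + sqrt(3))

#' Sample dipole orientations for an isotropic population
#'
#' Draws `n` independent orientation pairs as in the pseudo-isotropic
#' recipe: `x = cos(theta)` and `y = cos(omega)` each uniform on `[0, 1]`
#' (hemispherical sampling), then `kappa^2 = y^2 (1 + 3 x^2)`. By the
#' cos^2 symmetry of the orientation factor this is distributionally
#' identical to sampling the cosines on `[-1, 1]` (full sphere), which can
#' be requested with `full_sphere = TRUE`.
#'
#' The resulting kappa^2 population has mean 2/3 — the value conventionally
#' embedded in R0 for the dynamic averaging regime — with mode at 0 and
#' maximum 4.
#'
#' @param n Number of orientation pairs (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param full_sphere If `TRUE`, sample cosines on `[-1, 1]` instead of
#'   `[0, 1]`; the kappa^2 distribution is unchanged.
#' @return A data.frame with columns `theta`, `omega` (radians), `x`, `y`
#'   (their cosines) and `kappa2`.
#' @examples
#' s <- sample_isotropic_angles(1000, seed = 42)
#' mean(s$kappa2)  # close to 2/3
#' @export
sample_isotropic_angles <- function(n, seed = NULL, full_sphere = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  lo <- if (full_sphere) -1 else 0
  x <- stats::runif(n, lo, 1)
  y <- stats::runif(n, lo, 1)
  data.frame(
    theta = acos(x), omega = acos(y),
    x = x, y = y,
    kappa2 = y^2 * (1 + 3 * x^2)
  )
}

#' Cumulative distribution function of isotropic kappa^2
#'
#' Closed-form CDF `A(k)` of the orientation factor when donor and
#' acceptor dipoles are independently isotropically oriented
#' (`K = y^2 (1 + 3 x^2)` with `x`, `y` uniform cosines):
#' \itemize{
#'   \item `0 <= k <= 1`: `A(k) = sqrt(k/3) * ln(2 + sqrt(3))`
#'   \item `1 < k <= 4`: `A(k) = sqrt((k-1)/3) + sqrt(k/3) *
#'     (ln(2 + sqrt(3)) - ln(sqrt(k-1) + sqrt(k)))`
#' }
#' with `A(0) = 0` and `A(4) = 1`. Validated against the empirical CDF of
#' [sample_isotropic_angles()] in the package tests.
#'
#' @param k kappa^2 value(s) in `[0, 4]`.
#' @return Cumulative probability value(s).
#' @export
kappa2_cdf <- function(k) {
  if (any(!is.finite(k)) || any(k < 0 | k > 4))
    stop("`k` must lie in [0, 4]")
  out <- numeric(length(k))
  lowr <- k <= 1
  out[lowr] <- sqrt(k[lowr] / 3) * .kappa2_logconst
  kk <- k[!lowr]
  out[!lowr] <- sqrt((kk - 1) / 3) +
    sqrt(kk / 3) * (.kappa2_logconst - log(sqrt(kk - 1) + sqrt(kk)))
  out
}

#' Probability density of isotropic kappa^2
#'
#' Derivative of [kappa2_cdf()]. Diverges as `k^(-1/2)` at `k = 0`
#' (an integrable singularity: near-perpendicular acceptor orientations
#' dominate an isotropic population) and reaches 0 at `k = 4`.
#'
#' @param k kappa^2 value(s) in (0, 4].
#' @return Density value(s).
#' @export
kappa2_density <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0 | k > 4))
    stop("`k` must lie in (0, 4]")
  out <- numeric(length(k))
  lowr <- k <= 1
  out[lowr] <- .kappa2_logconst / (2 * sqrt(3 * k[lowr]))
  kk <- k[!lowr]
  out[!lowr] <- (.kappa2_logconst - log(sqrt(kk - 1) + sqrt(kk))) /
    (2 * sqrt(3 * kk))
  out
}

#' Forster factor and static-regime phase boundaries
#'
#' The static random isotropic regime is governed by the dimensionless
#' Forster factor `F = (3/2) (R0 / R_DA)^6`. The efficiency density in that
#' regime has three phases delimited by `E_lower = F/(1+F)` (location of
#' the interior peak/inflection) and `E_upper = 4F/(1+4F)` (maximum
#' attainable efficiency, where the density vanishes). At `R_DA = R0`,
#' `F = 1.5`, `E_lower = 0.6` and `E_upper = 6/7` (0.86 to two decimals).
#'
#' @param R_DA Donor-acceptor separation, nm, positive.
#' @param R0 Forster distance, nm, positive.
#' @return An object of class `static_regime_params`: list with `F`,
#'   `E_lower`, `E_upper`.
#' @export
static_factor <- function(R_DA, R0) {
  if (any(!is.finite(R_DA)) || any(R_DA <= 0) ||
      any(!is.finite(R0)) || any(R0 <= 0))
    stop("`R_DA` and `R0` must be positive")
  F <- (3 / 2) * (R0 / R_DA)^6
  structure(
    list(F = F, E_lower = F / (1 + F), E_upper = 4 * F / (1 + 4 * F)),
    class = "static_regime_params"
  )
}

#' @export
print.static_regime_params <- function(x, ...) {
  cat(sprintf("Static-regime parameters: F = %g, phases (0, %g), (%g, %g), zero beyond\n",
              x$F, x$E_lower, x$E_lower, x$E_upper))
  invisible(x)
}

#' Static-regime per-pair transfer rate
#'
#' In the static regime each pair keeps a fixed kappa^2 during the donor
#' excited state, so the rate carries the pair's own orientation factor:
#' `k_T = (3/2) kappa^2 (1/tau0D) (R0/R_DA)^6`. The 3/2 prefactor removes
#' the 2/3 dynamic-average kappa^2 embedded in `R0`; setting
#' `kappa2 = 2/3` recovers [transfer_rate()] exactly.
#'
#' @inheritParams transfer_rate
#' @param kappa2 Per-pair orientation factor(s) in `[0, 4]`.
#' @return Transfer rate(s) in ns^-1.
#' @export
static_transfer_rate <- function(R_DA, system, kappa2) {
  system <- as_forster_system(system)
  if (any(!is.finite(R_DA)) || any(R_DA <= 0))
    stop("`R_DA` must be positive and finite")
  if (any(!is.finite(kappa2)) || any(kappa2 < 0 | kappa2 > 4))
    stop("`kappa2` must lie in [0, 4]")
  (3 / 2) * kappa2 * (1 / system$tau0D) * (system$R0 / R_DA)^6
}
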