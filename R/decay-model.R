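#' Synthesize an ensemble donor fluorescence decay
#'
#' Builds the ensemble donor decay implied by a binned efficiency
#' distribution: each bin contributes a mono-exponential component with
#' lifetime `tau_n = tau0D * (1 - E_n)` (E_n the bin centre) and amplitude
#' equal to the bin's normalized probability,
#' `I(t) = sum_n w_n exp(-t / tau_n)`. A bin centred exactly at E = 1 would
#' have zero lifetime (an infinitely fast component); such bins are
#' excluded from the sum, their weight recorded in attribute
#' `"excluded_weight"`, and the remaining amplitudes renormalized so that
#' `I(0) = 1`. (With the default 0.01 bin width, centres never reach 1.)
#'
#' @param dist An [efficiency_distribution()].
#' @param tau0D Donor lifetime in the absence of acceptor, ns.
#' @param t_max End of the time grid, ns; default `4 * tau0D` covers > 98%
#'   of the intensity decay of the slowest component.
#' @param n_points Number of uniformly spaced time points from 0; default
#'   1024.
#' @return An object of class `decay_curve`: data.frame with columns
#'   `time_ns` and `intensity`, normalized to `I(0) = 1`.
#' @export
synthesize_decay <- function(dist, tau0D, t_max = 4 * tau0D, n_points = 1024) {
  if (!inherits(dist, "efficiency_distribution"))
    stop("`dist` must be an `efficiency_distribution`")
  if (!is.finite(tau0D) || tau0D <= 0) stop("`tau0D` must be positive")
  w <- dist$density * diff(dist$bin_edges)
  En <- dist$bin_centers
  occupied <- w > 0
  if (!any(occupied)) stop("empty efficiency distribution")
  w <- w[occupied]; En <- En[occupied]
  unity <- En >= 1
  excluded <- sum(w[unity])
  w <- w[!unity]; En <- En[!unity]
  if (length(w) == 0L)
    stop("all probability mass at E = 1: decay is instantaneous")
  w <- w / sum(w)
  tau_n <- tau0D * (1 - En)
  times <- seq(0, t_max, length.out = n_points)
  intensity <- colSums(w * exp(-outer(1 / tau_n, times)))
  structure(
    data.frame(time_ns = times, intensity = intensity),
    excluded_weight = excluded,
    tau0D = tau0D,
    class = c("decay_curve", "data.frame")
  )
}

#' Construct a decay curve from time and intensity vectors
#'
#' @param time_ns Time points, ns, non-negative and strictly increasing.
#' @param intensity Intensities, positive, with `I(0)` used to normalize.
#' @return A `decay_curve` object normalized to `I(0) = 1`.
#' @export
decay_curve <- function(time_ns, intensity) {
  if (length(time_ns) != length(intensity) || length(time_ns) < 2L)
    stop("`time_ns` and `intensity` must be equal-length vectors (>= 2 points)")
  if (any(diff(time_ns) <= 0)) stop("`time_ns` must be strictly increasing")
  if (any(intensity <= 0)) stop("intensities must be positive")
  structure(
    data.frame(time_ns = time_ns, intensity = intensity / intensity[1]),
    class = c("decay_curve", "data.frame")
  )
}

# model intensity for ordered parameters: amplitudes sum to 1
.exp_mixture <- function(t, amplitudes, lifetimes) {
  colSums(amplitudes * exp(-outer(1 / lifetimes, t)))
}

#' Fit a single- or double-exponential model to a decay curve
#'
#' Nonlinear least squares of `I(t) = sum_i a_i exp(-t / tau_i)` with
#' `a_i >= 0` and `sum a_i = 1`, via an unconstrained reparameterisation
#' (log lifetimes, logit amplitude share) minimised with `optim`. For two
#' components the returned lifetimes are ordered `tau_1 < tau_2`.
#' Non-convergence is reported through the `converged` flag rather than an
#' error, with the optimiser diagnostics attached.
#'
#' @param curve A `decay_curve` (>= 10 time points).
#' @param n_components 1 or 2.
#' @param weights `"uniform"` (default, appropriate for noiseless model
#'   curves) or `"poisson"` (weights `1/sqrt(I)`, for photon-counting
#'   noise).
#' @return An object of class `expfit_result`: list with `n_components`,
#'   `amplitudes`, `lifetimes` (ns), `amplitude_weighted_lifetime`,
#'   `weighted_residuals`, `chi2_reduced`, `converged`, `message`.
#' @export
fit_exponentials <- function(curve, n_components = 1,
                             weights = c("uniform", "poisson")) {
  if (!inherits(curve, "decay_curve"))
    stop("`curve` must be a `decay_curve`")
  weights <- match.arg(weights)
  if (nrow(curve) < 10L) stop("need at least 10 time points to fit")
  if (!n_components %in% c(1L, 2L)) stop("`n_components` must be 1 or 2")
  t <- curve$time_ns
  I <- curve$intensity
  wt <- if (weights == "poisson") 1 / sqrt(pmax(I, .Machine$double.eps)) else
    rep(1, length(I))

  # crude initial lifetimes from early and late log-slopes
  slope_tau <- function(idx) {
    fitc <- stats::coef(stats::lm(log(pmax(I[idx], 1e-300)) ~ t[idx]))
    tau <- -1 / fitc[[2]]
    if (!is.finite(tau) || tau <= 0) tau <- diff(range(t)) / 4
    tau
  }
  n_pt <- length(t)
  tau_early <- slope_tau(seq_len(max(10L, n_pt %/% 8L)))
  tau_late <- slope_tau(seq(max(1L, n_pt - n_pt %/% 4L), n_pt))

  # variable projection: for fixed lifetimes the constrained amplitude
  # (a, 1 - a) is a clipped linear least-squares solution, leaving only the
  # log-lifetimes to the nonlinear optimiser
  best_share <- function(e1, e2) {
    d <- e1 - e2
    denom <- sum((wt * d)^2)
    if (denom == 0) return(0.5)
    min(max(sum(wt^2 * (I - e2) * d) / denom, 0), 1)
  }
  ssr <- function(par) {
    if (n_components == 1L) {
      model <- exp(-t / exp(par[1]))
    } else {
      e1 <- exp(-t / exp(par[1])); e2 <- exp(-t / exp(par[2]))
      a <- best_share(e1, e2)
      model <- a * e1 + (1 - a) * e2
    }
    sum((wt * (I - model))^2)
  }
  if (n_components == 1L) {
    opt <- stats::optim(log(tau_early), ssr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-15))
    amplitudes <- 1
    lifetimes <- exp(opt$par[1])
  } else {
    taus <- sort(c(tau_early, tau_late))
    starts <- list(log(c(taus[1] * 0.8, taus[2] * 1.2)),
                   log(c(taus[1] * 0.5, taus[2])),
                   log(c(mean(taus), 2 * taus[2])))
    opts <- lapply(starts, function(p0) {
      o <- stats::optim(p0, ssr, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-15))
      stats::optim(o$par, ssr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-15))
    })
    opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
    lifetimes <- exp(opt$par)
    e1 <- exp(-t / lifetimes[1]); e2 <- exp(-t / lifetimes[2])
    a <- best_share(e1, e2)
    amplitudes <- c(a, 1 - a)
    ord <- order(lifetimes)
    lifetimes <- lifetimes[ord]
    amplitudes <- amplitudes[ord]
  }
  model <- .exp_mixture(t, amplitudes, lifetimes)
  res <- wt * (I - model)
  dof <- length(t) - (2 * n_components - 1)
  structure(
    list(n_components = as.integer(n_components),
         amplitudes = amplitudes, lifetimes = lifetimes,
         amplitude_weighted_lifetime = sum(amplitudes * lifetimes),
         weighted_residuals = res,
         chi2_reduced = sum(res^2) / dof,
         converged = opt$convergence == 0,
         message = if (opt$convergence == 0) "converged" else
           paste("optim code", opt$convergence, opt$message)),
    class = "expfit_result"
  )
}

#' @export
print.expfit_result <- function(x, ...) {
  cat(sprintf("%d-exponential fit%s\n", x$n_components,
              if (x$converged) "" else " (NOT CONVERGED)"))
  for (i in seq_len(x$n_components))
    cat(sprintf("  component %d: a = %.4f, tau = %.4f ns\n",
                i, x$amplitudes[i], x$lifetimes[i]))
  cat(sprintf("  <tau> (amplitude-weighted) = %.4f ns, reduced chi^2 = %.3g\n",
              x$amplitude_weighted_lifetime, x$chi2_reduced))
  invisible(x)
}

#' Apparent FRET efficiency from an average donor lifetime
#'
#' The lifetime-derived ("apparent") ensemble efficiency is
#' `1 - <tau>/tau0D`, where `<tau>` is the amplitude-weighted
#' (excitation-weighted) mean donor lifetime. For a binned efficiency
#' distribution, each bin contributes `tau_n = tau0D * (1 - E_n)` with
#' weight equal to its probability; for a fitted decay, `<tau>` is
#' `sum a_i tau_i`. Up to the binning error (at most one bin width), this
#' equals the microscopic mean efficiency.
#'
#' @param x An [efficiency_distribution()] or an [fit_exponentials()]
#'   result.
#' @param tau0D Donor lifetime in the absence of acceptor, ns.
#' @return The apparent efficiency.
#' @export
apparent_efficiency <- function(x, tau0D) {
  if (!is.finite(tau0D) || tau0D <= 0) stop("`tau0D` must be positive")
  UseMethod("apparent_efficiency")
}

#' @export
apparent_efficiency.efficiency_distribution <- function(x, tau0D) {
  w <- x$density * diff(x$bin_edges)
  tau_n <- tau0D * (1 - x$bin_centers)
  1 - sum(w * tau_n) / (sum(w) * tau0D)
}

#' @export
apparent_efficiency.expfit_result <- function(x, tau0D) {
  1 - x$amplitude_weighted_lifetime / tau0D
}
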