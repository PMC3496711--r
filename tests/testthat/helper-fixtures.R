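# Cerulean-Venus-like reference system used throughout: tau0D = 3 ns,
# R0 = 5.4 nm.
cv_system <- function(regime = "dynamic") {
  forster_system(tau0D = 3, R0 = 5.4, regime = regime)
}

# flat-top spectra for overlap-integral oracles
flat_spectrum <- function(from, to, value = 1, n = 2) {
  fret_spectrum(seq(from, to, length.out = n), rep(value, n))
}

# triangular emission band peaking mid-range
triangle_spectrum <- function(from, to, peak = 1, n = 51) {
  wl <- seq(from, to, length.out = n)
  mid <- (from + to) / 2
  fret_spectrum(wl, peak * (1 - abs(wl - mid) / ((to - from) / 2)))
}

# two-sided Kolmogorov-Smirnov distance between samples and an analytic CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}
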