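# Shared independent-oracle helpers for the test suite.

# Complex-step first derivative: exact to machine precision for functions
# analytic in a neighborhood of t (no subtractive cancellation).
cs_deriv <- function(f, t, h = 1e-20) {
  Im(f(complex(real = t, imaginary = h))) / h
}

# Richardson-extrapolated second derivative from central differences;
# converges to ~1e-12 for smooth f.
richardson_d2 <- function(f, x, h0 = 0.2, levels = 7) {
  D <- matrix(NA_real_, levels, levels)
  for (i in seq_len(levels)) {
    h <- h0 / 2^(i - 1)
    D[i, 1] <- (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  }
  for (j in 2:levels) {
    for (i in j:levels) {
      D[i, j] <- D[i, j - 1] + (D[i, j - 1] - D[i - 1, j - 1]) / (4^(j - 1) - 1)
    }
  }
  D[levels, levels]
}

# Fourier-cosine spectral derivative of an even pi-periodic sample vector
# (independent evaluation path used to verify finite-difference operators).
spectral_d <- function(u, order) {
  n1 <- length(u)
  M <- 2L * (n1 - 1L)
  ue <- c(u, rev(u[2:(n1 - 1L)]))
  k <- c(0:(M / 2), (-M / 2 + 1):(-1))
  uh <- stats::fft(ue) * (1i * k)^order
  if (order %% 2 == 1) uh[M / 2 + 1] <- 0
  Re(stats::fft(uh, inverse = TRUE) / M)[seq_len(n1)]
}

# time grid mapping a power-law blow-up x = ((p-1)(t*-t))^(1/(1-p)) onto a
# prescribed range of x values
power_tgrid <- function(p, x_lo, x_hi, n, x0 = 1) {
  t_star <- x0^(1 - p) / (p - 1)
  xs <- exp(seq(log(x_lo), log(x_hi), length.out = n))
  t_star - xs^(1 - p) / (p - 1)
}
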