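# Independent Mie oracle: expansion coefficients evaluated directly from base
# R half-integer Bessel functions (no logarithmic-derivative recurrence), so
# it shares no algorithmic path with the package implementation.
oracleMieQ <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2) + 10
  n <- seq_len(nmax)
  psi <- function(z, k) sqrt(pi * z / 2) * besselJ(z, k + 0.5)
  chi <- function(z, k) -sqrt(pi * z / 2) * besselY(z, k + 0.5)
  ps_x <- psi(x, n); ps_xm1 <- psi(x, n - 1)
  ch_x <- chi(x, n); ch_xm1 <- chi(x, n - 1)
  dps_x <- ps_xm1 - n * ps_x / x
  dch_x <- ch_xm1 - n * ch_x / x
  xi_x <- complex(real = ps_x, imaginary = -ch_x)
  dxi_x <- complex(real = dps_x, imaginary = -dch_x)
  ps_mx <- psi(m * x, n); ps_mxm1 <- psi(m * x, n - 1)
  dps_mx <- ps_mxm1 - n * ps_mx / (m * x)
  a <- (m * ps_mx * dps_x - ps_x * dps_mx) /
       (m * ps_mx * dxi_x - xi_x * dps_mx)
  b <- (ps_mx * dps_x - m * ps_x * dps_mx) /
       (ps_mx * dxi_x - m * xi_x * dps_mx)
  c(q_ext = (2 / x^2) * sum((2 * n + 1) * Re(a + b)),
    q_sca = (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2)))
}
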