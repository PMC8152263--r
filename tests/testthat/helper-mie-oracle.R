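# Independent Lorenz-Mie reference implementation used only as a test oracle.
#
# Deliberately different numerics from the package: the logarithmic
# derivative of the internal Riccati-Bessel function is evaluated per order
# by a modified-Lentz continued fraction (not a downward recurrence), and the
# external Riccati-Bessel functions come from R's half-integer Bessel
# functions rather than recurrences.

# continued fraction for R_n = j_n(rho) / j_{n-1}(rho), complex rho
oracle_ratio <- function(n, rho) {
  tiny <- 1e-280
  f <- tiny
  C <- f
  D <- 0
  k <- 0
  repeat {
    k <- k + 1
    a <- if (k == 1) 1 + 0i else -1 + 0i
    b <- (2 * (n + k) - 1) / rho
    D <- b + a * D
    if (D == 0) D <- tiny
    C <- b + a / C
    if (C == 0) C <- tiny
    D <- 1 / D
    delta <- C * D
    f <- f * delta
    if (abs(Mod(delta) - 1) < 1e-15 || k > 20000) break
  }
  f
}

oracle_mie_q <- function(x, m) {
  m <- as.complex(m)
  rho <- m * x
  n_max <- ceiling(x + 4 * x^(1 / 3) + 2)
  n <- seq_len(n_max)
  psi <- sqrt(pi * x / 2) * besselJ(x, n + 0.5)
  chi <- -sqrt(pi * x / 2) * besselY(x, n + 0.5)
  psi_l <- c(sin(x), psi[-n_max])
  chi_l <- c(cos(x), chi[-n_max])
  xi <- complex(real = psi, imaginary = -chi)
  xi_l <- complex(real = psi_l, imaginary = -chi_l)
  D <- vapply(n, function(nn) 1 / oracle_ratio(nn, rho) - nn / rho,
              complex(1))
  da <- D / m + n / x
  db <- D * m + n / x
  a <- (da * psi - psi_l) / (da * xi - xi_l)
  b <- (db * psi - psi_l) / (db * xi - xi_l)
  w <- 2 * n + 1
  list(
    q_ext = (2 / x^2) * sum(w * Re(a + b)),
    q_sca = (2 / x^2) * sum(w * (Mod(a)^2 + Mod(b)^2))
  )
}
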