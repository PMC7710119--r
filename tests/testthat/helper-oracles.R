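# Shared fixtures and independent oracles used across the test files.

# independent stoichiometry-matrix x flux-vector implementation of the
# apoptosis network (coded separately from the package's kernels)
apoptosis_stoich_oracle <- function(x, p) {
  St <- matrix(0, 8, 9)
  St[1, 1] <- -1; St[1, 2] <- 1
  St[2, 3] <- 1; St[2, 4] <- -1; St[2, 5] <- 1; St[2, 6] <- 1
  St[3, 4] <- -1; St[3, 5] <- 1
  St[4, 1] <- -1; St[4, 2] <- 1; St[4, 3] <- 1; St[4, 6] <- 1
  St[4, 7] <- -1; St[4, 8] <- 1
  St[5, 1] <- 1; St[5, 2] <- -1; St[5, 3] <- -1
  St[6, 4] <- 1; St[6, 5] <- -1; St[6, 6] <- -1
  St[7, 7] <- -1; St[7, 8] <- 1; St[7, 9] <- 1
  St[8, 7] <- 1; St[8, 8] <- -1; St[8, 9] <- -1
  mono <- c(x[1] * x[4], x[5], x[5], x[2] * x[3], x[6], x[6],
            x[4] * x[7], x[8], x[8])
  3600 * as.numeric(St %*% (p * mono))
}

# term-by-term hand evaluation of the glycolysis right-hand side
glycolysis_hand_oracle <- function(x, p) {
  J0 <- p[1]; k1 <- p[2]; k2 <- p[3]; k3 <- p[4]; k4 <- p[5]; k5 <- p[6]
  k6 <- p[7]; kk <- p[8]; kap <- p[9]; q <- p[10]; K1 <- p[11]
  psi <- p[12]; N <- p[13]; A <- p[14]
  v <- k1 * x[1] * x[6] / (1 + (x[6] / K1)^q)
  c(J0 - v,
    2 * v - k2 * x[2] * (N - x[5]) - k6 * x[2] * x[5],
    k2 * x[2] * (N - x[5]) - k3 * x[3] * (A - x[6]),
    k3 * x[3] * (A - x[6]) - k4 * x[4] * x[5] - kap * (x[4] - x[7]),
    k2 * x[2] * (N - x[5]) - k4 * x[4] * x[5] - k6 * x[2] * x[5],
    -2 * v + 2 * k3 * x[3] * (A - x[6]) - k5 * x[6],
    psi * kap * (x[4] - x[7]) - kk * x[7])
}

# small surrogate configuration for fast tests
tiny_config <- function(system, depth = 2, width = 8) {
  sbinn:::default_config(system, depth = depth, width = width)
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-12)
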