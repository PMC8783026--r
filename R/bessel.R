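# Exponentially scaled modified Bessel functions of complex argument,
# orders 0 and 1, for Re(z) > 0:
#   I0e = I0(z) e^{-Re z}, I1e = I1(z) e^{-Re z},
#   K0e = K0(z) e^{+Re z}, K1e = K1(z) e^{+Re z}.
# Power series near the origin, large-|z| asymptotic expansions beyond.
# The crossover for K is lower than for I because the K series subtracts
# log(z/2)*I terms and loses digits as |I| grows.

EULER_GAMMA <- 0.57721566490153286060651209

bessel_series <- function(z) {
  q <- z * z / 4
  I0 <- 1 + 0i
  I1s <- 1 + 0i          # sum for I1/(z/2)
  K0s <- 0 + 0i
  K1s <- (-2 * EULER_GAMMA + 1) + 0i  # k = 0 term of [psi(k+1)+psi(k+2)] sum
  term <- 1 + 0i
  t1 <- 1 + 0i
  Hk <- 0
  for (k in 1:80) {
    term <- term * q / (k * k)
    t1 <- t1 * q / (k * (k + 1))
    Hk <- Hk + 1 / k
    Hk1 <- Hk + 1 / (k + 1)
    I0 <- I0 + term
    I1s <- I1s + t1
    K0s <- K0s + term * Hk
    K1s <- K1s + t1 * (-2 * EULER_GAMMA + Hk + Hk1)
    if (Mod(term) < 1e-18 * Mod(I0) && Mod(t1) < 1e-18 * Mod(I1s)) break
  }
  lg <- log(z / 2)
  I1 <- I1s * z / 2
  K0 <- -(lg + EULER_GAMMA) * I0 + K0s
  K1 <- 1 / z + lg * I1 - (z / 4) * K1s
  list(I0 = I0, I1 = I1, K0 = K0, K1 = K1)
}

bessel_asym <- function(z, mu) {
  # returns c(S_I, S_K): I ~ e^z/sqrt(2 pi z) S_I, K ~ sqrt(pi/2z) e^-z S_K
  sI <- sK <- 1 + 0i
  t <- 1 + 0i
  prev <- Inf
  for (k in 1:16) {
    t <- t * (mu - (2 * k - 1)^2) / (8 * k * z)
    if (Mod(t) >= prev) break  # truncate at the smallest term
    sI <- sI + (-1)^k * t
    sK <- sK + t
    prev <- Mod(t)
  }
  c(sI, sK)
}

# scalar z with Re(z) > 0
bessel_ik_scaled <- function(z) {
  az <- Mod(z)
  if (az <= 10) {
    b <- bessel_series(z)
    ex <- exp(-Re(z))
    list(I0e = b$I0 * ex, I1e = b$I1 * ex,
         K0e = b$K0 / ex, K1e = b$K1 / ex)
  } else if (az <= 25) {
    # I from (stable) series, K from asymptotics
    b <- bessel_series(z)
    ex <- exp(-Re(z))
    a0 <- bessel_asym(z, 0)
    a1 <- bessel_asym(z, 4)
    eK <- sqrt(pi / (2 * z)) * exp(-1i * Im(z))
    list(I0e = b$I0 * ex, I1e = b$I1 * ex,
         K0e = eK * a0[2], K1e = eK * a1[2])
  } else {
    a0 <- bessel_asym(z, 0)
    a1 <- bessel_asym(z, 4)
    eI <- exp(1i * Im(z)) / sqrt(2 * pi * z)
    eK <- sqrt(pi / (2 * z)) * exp(-1i * Im(z))
    list(I0e = eI * a0[1], I1e = eI * a1[1],
         K0e = eK * a0[2], K1e = eK * a1[2])
  }
}
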