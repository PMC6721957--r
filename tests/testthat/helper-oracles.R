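# Independent oracles used to freeze expected values.

# Bisection root of the dimer mass balance 2 M^2 / K_D + M - C_T = 0,
# independent of the closed-form solution in the package.
bisect_partition <- function(C_T, K_D, tol = 1e-14) {
  if (C_T == 0) return(0)
  f <- function(M) 2 * M^2 / K_D + M - C_T
  lo <- 0; hi <- C_T
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol * C_T) break
  }
  (lo + hi) / 2
}

# forward LEM melt signal for constructing noiseless fixtures in tests
lem_melt_signal <- function(temp_K, Tm, dH, bf, bu) {
  R <- 1.987e-3
  Tref <- mean(temp_K)
  K <- exp(-dH * (1 - temp_K / Tm) / (R * temp_K))
  pu <- K / (1 + K)
  thetaF <- bf[1] + bf[2] * (temp_K - Tref)
  thetaU <- bu[1] + bu[2] * (temp_K - Tref)
  thetaF * (1 - pu) + thetaU * pu
}
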