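# Independent oracles, kept deliberately separate from the package's own
# solution paths.

# Equilibrium DA release by brute force: eliminate X_s, X_d, P from the
# linearized fixed-point system to get a cubic in Y,
#   Y (1+Y)^2 = (J_d (1+Y) - X_p (1 + (1-b) Y)) * (1 + (1-a) Y),
# and take its positive real root(s) via polyroot.  Valid for a, b <= 1
# (no gain clamping active).
oracle_equilibrium_y <- function(x_p, a, b, j_d = 1) {
  A <- j_d - x_p
  B <- j_d - x_p * (1 - b)
  C <- 1 - a
  coefs <- c(-A, 1 - (A * C + B), 2 - B * C, 1)  # Y^0 .. Y^3
  r <- polyroot(coefs)
  r <- Re(r[abs(Im(r)) < 1e-8])
  sort(r[r > 0])
}

# Closed-form simple OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
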