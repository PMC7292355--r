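# Analytic oracles used across test files.

# Bolus two-compartment disposition with constant clearance `cl` acting on
# the unbound central concentration: closed-form bi-exponential solution.
# Returns C1(t) plus the exact moment integrals. Independent of the ODE
# integrator and of the NCA code.
biexp_bolus <- function(t, dose, vc, vp, q, cl, fu = 1) {
  k10 <- cl * fu / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  a <- dose * (alpha - k21) / (vc * (alpha - beta))
  b <- dose * (k21 - beta) / (vc * (alpha - beta))
  list(
    conc = a * exp(-alpha * t) + b * exp(-beta * t),
    auc = a / alpha + b / beta,            # = dose / (cl * fu)
    aumc = a / alpha^2 + b / beta^2,
    alpha = alpha, beta = beta
  )
}

# Normal-equation OLS oracle: explicit (X'X)^-1 X'y, independent of lm().
ols_oracle <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1L]
}

# Small helper: the six-drug packaged table under the default conventions.
packaged_drugs <- function(...) load_drug_table(...)
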