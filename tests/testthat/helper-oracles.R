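# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: transmission probabilities come from a numeric
# Schroedinger solve, quadratures are plain trapezoids on dense grids, and
# profile extrema come from brute-force search on dense analytic sampling.

# --- quantum transmission through an asymmetric Eckart barrier -------------
# Reduced units (hbar = m = 1).  V(x) = A*y/(1+y) + B*y/(1+y)^2, y = e^(x/L)
# with A = V1 - V2 and B = (sqrt(V1)+sqrt(V2))^2.  Integrates the stationary
# Schroedinger equation from the transmitted side back to the incident side
# and extracts |t|^2 from the plane-wave decomposition.  Returns P(E) and the
# barrier-top "h*nu" (hbar * omega) implied by the curvature, so the package
# formula can be evaluated at exactly matching parameters.
odeEckart <- function(V1, V2, L, E) {
  A <- V1 - V2
  B <- (sqrt(V1) + sqrt(V2))^2
  V <- function(x) { y <- exp(x / L); A * y / (1 + y) + B * y / (1 + y)^2 }
  xstar <- stats::optimize(V, c(-12 * L, 12 * L), maximum = TRUE)$maximum
  h <- 1e-4
  Vpp <- (V(xstar + h) - 2 * V(xstar) + V(xstar - h)) / h^2
  hnu <- sqrt(-Vpp)                       # hbar * omega, reduced units
  k1 <- sqrt(2 * E)                       # incident wavevector
  k2 <- sqrt(2 * (E - A))                 # transmitted wavevector
  xR <- 18 * L; xL <- -18 * L
  rhs <- function(x, y, parms) {
    # y = (Re psi, Im psi, Re dpsi, Im dpsi)
    f <- 2 * (V(x) - E)
    list(c(y[3], y[4], f * y[1], f * y[2]))
  }
  y0 <- c(cos(k2 * xR), sin(k2 * xR), -k2 * sin(k2 * xR), k2 * cos(k2 * xR))
  sol <- deSolve::ode(y0, c(xR, xL), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  yf <- sol[nrow(sol), -1]
  psi <- complex(real = yf[1], imaginary = yf[2])
  dpsi <- complex(real = yf[3], imaginary = yf[4])
  a <- (psi + dpsi / (1i * k1)) / 2 * exp(-1i * k1 * xL)
  list(P = (k2 / k1) / Mod(a)^2, hnu = hnu)
}

# --- Boltzmann-averaged kappa by plain trapezoid quadrature ----------------
trapKappa <- function(V1, V2, nu_cm, temperature = 298.15, nGrid = 60001L) {
  RT <- physicalConstants()$R_kcal * temperature
  Emin <- max(0, V1 - V2)
  E <- seq(Emin, V1 + 45 * RT, length.out = nGrid)
  P <- eckartTransmission(E, V1, V2, nu_cm)
  f <- P * exp(-(E - V1) / RT) / RT
  sum((f[-1] + f[-nGrid]) / 2) * (E[2] - E[1])
}

# --- brute-force critical points of an analytic profile --------------------
bruteForceCriticalPoints <- function(Vfun, lo, hi, n = 2e5L) {
  x <- seq(lo, hi, length.out = n)
  V <- Vfun(x)
  rf <- -(V[-1] - V[-n]) / (x[2] - x[1])       # forward differences
  xm <- (x[-1] + x[-n]) / 2
  ibeta <- which.max(V)
  left <- xm < x[ibeta]; right <- xm > x[ibeta]
  sgn <- sign(rf)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  xc <- xm[cross]
  c(alpha = xm[left][which.min(rf[left])],
    beta = xc[which.min(abs(xc - x[ibeta]))],
    gamma = xm[right][which.max(rf[right])])
}

# a small scaffold with two chemically inequivalent sites (phenol ring)
inequivalentScaffold <- function(frags = data.frame(name = "F", smiles = "[*]F"))
  scaffoldSpec("Oc1ccc({R1})cc1{R2}", c("R1", "R2"), frags)
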