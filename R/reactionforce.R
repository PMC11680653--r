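#' Construct an IRC energy profile
#'
#' @param xi strictly increasing reaction-coordinate values (reactants at low
#'   `xi`; units are pass-through).
#' @param energy potential energy at each `xi`.
#' @param units `"kcal/mol"` (default) or `"hartree"` (converted at
#'   627.5095 kcal/mol per hartree).
#' @return An [IRCProfile-class] object.
#' @examples
#' xi <- seq(-6, 6, length.out = 121)
#' ircProfile(xi, 10 / cosh(xi)^2)
#' @export
ircProfile <- function(xi, energy, units = c("kcal/mol", "hartree")) {
  units <- match.arg(units)
  if (units == "hartree") energy <- energy * .hartree2kcal
  if (length(xi) < 7L) stop("insufficient data: an IRC profile needs at least 7 points")
  new("IRCProfile", xi = as.numeric(xi), energy = as.numeric(energy))
}

# Fit the profile once; returns list(V, RF) of functions of xi.
# spline: GCV smoothing cubic spline differentiated analytically (the default;
# QM grids are unevenly spaced and mildly noisy).  central_difference:
# second-order stencils on the raw data, interpolated for off-grid queries.
.fitProfile <- function(profile, method = c("spline", "central_difference")) {
  method <- match.arg(method)
  xi <- profile@xi; V <- profile@energy
  if (method == "spline") {
    # GCV smoothing spline; when the GCV fit shows the data are effectively
    # noiseless, switch to the interpolating spline so smooth analytic
    # profiles are differentiated without smoothing bias
    probe <- stats::smooth.spline(xi, V)
    noiseless <- stats::sd(stats::predict(probe, xi)$y - V) <
      1e-7 * max(diff(range(V)), .Machine$double.eps)
    if (noiseless) {
      f <- stats::splinefun(xi, V, method = "fmm")
      list(V = f, RF = function(x) -f(x, deriv = 1))
    } else {
      fit <- stats::smooth.spline(xi, V, all.knots = TRUE)
      list(V = function(x) stats::predict(fit, x)$y,
           RF = function(x) -stats::predict(fit, x, deriv = 1)$y)
    }
  } else {
    n <- length(xi)
    d <- numeric(n)
    # second-order non-uniform central stencil; one-sided second order at ends
    for (i in 2:(n - 1)) {
      h1 <- xi[i] - xi[i - 1]; h2 <- xi[i + 1] - xi[i]
      d[i] <- (V[i + 1] * h1^2 - V[i - 1] * h2^2 + V[i] * (h2^2 - h1^2)) /
        (h1 * h2 * (h1 + h2))
    }
    h1 <- xi[2] - xi[1]; h2 <- xi[3] - xi[2]
    d[1] <- (-V[3] * h1^2 + V[2] * (h1 + h2)^2 - V[1] * ((h1 + h2)^2 - h1^2)) /
      (h1 * h2 * (h1 + h2))
    h1 <- xi[n] - xi[n - 1]; h2 <- xi[n - 1] - xi[n - 2]
    d[n] <- (V[n - 2] * h1^2 - V[n - 1] * (h1 + h2)^2 + V[n] * ((h1 + h2)^2 - h1^2)) /
      (h1 * h2 * (h1 + h2))
    Vf <- stats::splinefun(xi, V, method = "fmm")
    RFf <- stats::splinefun(xi, -d, method = "fmm")
    list(V = Vf, RF = RFf)
  }
}

#' Reaction force along the IRC
#'
#' The reaction force is the negative derivative of the potential energy with
#' respect to the reaction coordinate, `RF = -dV/dxi`, evaluated on the
#' profile's grid.
#'
#' @param profile an [IRCProfile-class].
#' @param method `"spline"` (GCV smoothing cubic spline, differentiated
#'   analytically; the default) or `"central_difference"` (second-order
#'   stencils with one-sided ends, no smoothing).
#' @return numeric vector of force values on the grid.
#' @examples
#' xi <- seq(-2, 2, length.out = 81)
#' rf <- forceProfile(ircProfile(xi, 8 - xi^2 + xi^4/16))
#' @export
forceProfile <- function(profile, method = c("spline", "central_difference")) {
  stopifnot(is(profile, "IRCProfile"))
  validObject(profile)
  .fitProfile(profile, method)$RF(profile@xi)
}

#' Test the single-barrier requirement
#'
#' `TRUE` when the profile's global energy maximum is unique and interior --
#' the shape the critical-point analysis requires.
#'
#' @param profile an [IRCProfile-class].
#' @return logical(1).
#' @export
singleBarrier <- function(profile) {
  stopifnot(is(profile, "IRCProfile"))
  V <- profile@energy
  imax <- which(V == max(V))
  length(imax) == 1L && imax > 1L && imax < length(V)
}

# quadratic refinement of an extremum through three points
.quadRefine <- function(x, y) {
  d <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / d
  B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / d
  if (A == 0) x[2] else {
    v <- -B / (2 * A)
    if (v >= min(x) && v <= max(x)) v else x[2]
  }
}

#' Locate the alpha/beta/gamma critical points of the reaction force
#'
#' `beta` is the reaction-force zero crossing nearest the energy maximum (the
#' transition state); `alpha` is the force minimum on the reactant side and
#' `gamma` the force maximum on the product side.  Extrema and crossings are
#' located on a dense evaluation of the fitted force curve and refined by
#' local quadratic (extrema) or linear (crossing) interpolation.
#'
#' @inheritParams forceProfile
#' @param nFine number of dense evaluation points.
#' @return named numeric `c(alpha, beta, gamma)`.
#' @examples
#' xi <- seq(-6, 6, length.out = 201)
#' criticalPoints(ircProfile(xi, 10 / cosh(xi)^2))
#' @export
criticalPoints <- function(profile, method = c("spline", "central_difference"),
                           nFine = 4001L) {
  stopifnot(is(profile, "IRCProfile"))
  validObject(profile)
  if (!singleBarrier(profile))
    stop("no transition state: the profile has no unique interior energy maximum")
  fit <- .fitProfile(profile, method)
  xf <- seq(min(profile@xi), max(profile@xi), length.out = nFine)
  rf <- fit$RF(xf)
  xmax <- xf[which.max(fit$V(xf))]
  sgn <- sign(rf)
  cross <- which(sgn[-1] * sgn[-nFine] < 0)
  if (!length(cross))
    stop("no transition state: the reaction force never changes sign")
  # zero crossing nearest the energy maximum
  xc <- vapply(cross, function(i) {
    x1 <- xf[i]; x2 <- xf[i + 1]
    x1 - rf[i] * (x2 - x1) / (rf[i + 1] - rf[i])
  }, numeric(1))
  beta <- xc[which.min(abs(xc - xmax))]
  left <- which(xf < beta); right <- which(xf > beta)
  if (length(left) < 3L || length(right) < 3L)
    stop("transition state too close to the grid edge")
  imin <- left[which.min(rf[left])]
  imax <- right[which.max(rf[right])]
  idx3 <- function(i) max(2L, min(i, nFine - 1L)) + (-1L:1L)
  alpha <- .quadRefine(xf[idx3(imin)], rf[idx3(imin)])
  gamma <- .quadRefine(xf[idx3(imax)], rf[idx3(imax)])
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Zone decomposition of the activation energies
#'
#' Splits the forward activation energy into a preparation component
#' (reactants to `alpha`) and a transition component (`alpha` to `beta`),
#' and the reverse activation energy into products-to-`gamma` and
#' `gamma`-to-`beta` components.  Reactants and products are the first and
#' last grid points.  By construction each activation energy equals the sum
#' of its two components exactly.
#'
#' @inheritParams forceProfile
#' @param alpha,beta,gamma critical-point coordinates (see
#'   [criticalPoints()]).
#' @return named numeric with `prep_forward`, `transition_forward`,
#'   `act_forward`, `prep_reverse`, `transition_reverse`, `act_reverse`
#'   (kcal/mol).
#' @export
zoneDecomposition <- function(profile, alpha, beta, gamma,
                              method = c("spline", "central_difference")) {
  stopifnot(is(profile, "IRCProfile"))
  rng <- range(profile@xi)
  if (alpha < rng[1] || gamma > rng[2])
    stop("critical points outside the profile range")
  V <- .fitProfile(profile, method)$V
  pf <- unname(V(alpha) - V(rng[1]))
  tf <- unname(V(beta) - V(alpha))
  pr <- unname(V(gamma) - V(rng[2]))
  tr <- unname(V(beta) - V(gamma))
  c(prep_forward = pf, transition_forward = tf, act_forward = pf + tf,
    prep_reverse = pr, transition_reverse = tr, act_reverse = pr + tr)
}

#' Work integrals of the reaction force
#'
#' Areas under the force curve over the four zones delimited by the critical
#' points: `W1` (reactants to `alpha`), `W2` (`alpha` to `beta`), `W3`
#' (`beta` to `gamma`), `W4` (`gamma` to products), by adaptive quadrature
#' of the fitted force.  With this sign convention
#' `W1 + W2 = -dE_act_forward` and the four integrals sum to minus the
#' reaction energy.
#'
#' @inheritParams zoneDecomposition
#' @return named numeric `W1`..`W4`.
#' @export
workIntegrals <- function(profile, alpha, beta, gamma,
                          method = c("spline", "central_difference")) {
  stopifnot(is(profile, "IRCProfile"))
  RF <- .fitProfile(profile, method)$RF
  rng <- range(profile@xi)
  seg <- function(a, b) {
    q <- tryCatch(stats::integrate(RF, a, b, rel.tol = 1e-8,
                                   subdivisions = 400L)$value,
                  error = function(e) NULL)
    if (!is.null(q)) return(q)
    # adaptive quadrature can hit roundoff on nearly-flat tails; fall back
    # to a dense trapezoid, which is ample at these tolerances
    x <- seq(a, b, length.out = 20001L)
    y <- RF(x)
    sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  }
  c(W1 = seg(rng[1], alpha), W2 = seg(alpha, beta),
    W3 = seg(beta, gamma), W4 = seg(gamma, rng[2]))
}

#' Full reaction-force analysis of an IRC profile
#'
#' Computes the force profile, locates the critical points, decomposes the
#' activation energies into zone contributions, and evaluates the per-zone
#' work integrals.
#'
#' @inheritParams forceProfile
#' @return A [ForceAnalysis-class] object.
#' @examples
#' xi <- seq(-6, 6, length.out = 201)
#' analyzeReactionForce(ircProfile(xi, 10 / cosh(xi)^2))
#' @export
analyzeReactionForce <- function(profile, method = c("spline", "central_difference")) {
  method <- match.arg(method)
  cp <- criticalPoints(profile, method)
  zones <- zoneDecomposition(profile, cp["alpha"], cp["beta"], cp["gamma"], method)
  work <- workIntegrals(profile, cp["alpha"], cp["beta"], cp["gamma"], method)
  new("ForceAnalysis", profile = profile,
      force = forceProfile(profile, method),
      alpha = unname(cp["alpha"]), beta = unname(cp["beta"]),
      gamma = unname(cp["gamma"]), zones = zones, work = work,
      method = method)
}

#' Activation energies from tabulated zone components
#'
#' Additivity bookkeeping for externally tabulated zone energies: the
#' forward activation energy is the sum of the preparation
#' (reactants -> alpha) and transition (alpha -> beta) components, the
#' reverse one the sum of the products -> gamma and gamma -> beta
#' components.
#'
#' @param zones data.frame with columns `prep_forward`, `transition_forward`,
#'   `prep_reverse`, `transition_reverse` (kcal/mol).
#' @return the input with `act_forward` and `act_reverse` columns appended.
#' @examples
#' activationFromZones(data.frame(prep_forward = 4.95, transition_forward = 0.94,
#'                                prep_reverse = 10.15, transition_reverse = 6.22))
#' @export
activationFromZones <- function(zones) {
  need <- c("prep_forward", "transition_forward", "prep_reverse", "transition_reverse")
  miss <- setdiff(need, names(zones))
  if (length(miss)) stop("missing zone column(s): ", paste(miss, collapse = ", "))
  zones$act_forward <- zones$prep_forward + zones$transition_forward
  zones$act_reverse <- zones$prep_reverse + zones$transition_reverse
  zones
}
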