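#' Kinetic constants of the two-site enzyme-modifier scheme
#'
#' Rapid-equilibrium scheme in which a drug binds at two distinct sites of a
#' Michaelis-Menten enzyme. Occupancy of the *activation* site (dissociation
#' constant `K_act`, on both free enzyme and the enzyme-substrate complex)
#' facilitates substrate capture: it divides the apparent Michaelis constant
#' by `alpha` (`alpha > 1` = activation) and leaves the turnover number
#' untouched. Occupancy of the *inhibition* site (constant `K_inh`) is
#' restricted to substrate-bound states and is strictly dead-end -- the
#' signature of uncompetitive inhibition, where the inhibitor binds next to
#' the substrate. Multi-molecule binding is modeled with concerted
#' stoichiometry exponents `n_act` and `n_inh` (Hill-type), because dose-
#' response data report steepness, not microscopic site constants.
#'
#' @param kcat turnover number (1/s); total enzyme is normalized out, so
#'   rates are reported as fractions of `kcat * E0`.
#' @param Km Michaelis constant (molar).
#' @param K_act drug dissociation constant at the activation site (molar).
#' @param alpha factor (> 0) by which activation-site occupancy divides the
#'   apparent Km; `alpha > 1` means activation, `alpha = 1` a silent site.
#' @param K_inh drug dissociation constant at the inhibition site on the
#'   enzyme-substrate complex (molar).
#' @param n_act,n_inh site stoichiometry exponents (>= 1).
#' @return an object of class `mechanism_params`.
#' @export
mechanism_params <- function(kcat = 1, Km, K_act, alpha, K_inh,
                             n_act = 1, n_inh = 1) {
  vals <- c(kcat = kcat, Km = Km, K_act = K_act, alpha = alpha,
            K_inh = K_inh, n_act = n_act, n_inh = n_inh)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all mechanism constants must be finite and > 0")
  if (n_act < 1 || n_inh < 1)
    stop("site stoichiometries n_act and n_inh must be >= 1")
  structure(as.list(vals), class = "mechanism_params")
}

#' @export
print.mechanism_params <- function(x, ...) {
  cat("Two-site enzyme-modifier scheme\n")
  cat(sprintf("  kcat = %.3g /s, Km = %.3g M\n", x$kcat, x$Km))
  cat(sprintf("  activation site: K_act = %.3g M, Km / %.3g, n = %.3g\n",
              x$K_act, x$alpha, x$n_act))
  cat(sprintf("  inhibition site: K_inh = %.3g M (uncompetitive), n = %.3g\n",
              x$K_inh, x$n_inh))
  invisible(x)
}

#' Rapid-equilibrium velocity of the two-site modifier scheme
#'
#' Fractional velocity of E <-> ES -> P with drug occupancies
#' `a = (D / K_act)^n_act` and `b = (D / K_inh)^n_inh`:
#'
#' \deqn{v = kcat \cdot \frac{(S/Km)(1 + a\alpha)}
#'   {1 + a + (S/Km)(1 + a\alpha)(1 + b)}}
#'
#' The six enzyme states and their equilibrium weights are E: 1, EA: `a`,
#' ES: `S/Km`, ESA: `a alpha S/Km` (the activation site divides Km by
#' `alpha`), and the dead-end ESI / ESAI states carrying the extra factor
#' `b`. ES and ESA turn over at `kcat`; inhibition-site occupancy is
#' catalytically dead. At `D = 0` this is exactly Michaelis-Menten; at
#' `alpha = 1, n = 1` it collapses to the textbook uncompetitive form
#' `v = S / (Km + S (1 + D/K_inh))`.
#'
#' @param params a [mechanism_params] object.
#' @param S substrate concentration(s), molar, >= 0.
#' @param D drug concentration(s), molar, >= 0.
#' @return velocity in units of `kcat * E0` (with `kcat = 1`, the fraction of
#'   maximal turnover).
#' @export
velocity <- function(params, S, D) {
  stopifnot(inherits(params, "mechanism_params"))
  if (any(S < 0) || any(D < 0)) stop("S and D must be >= 0")
  a <- (D / params$K_act)^params$n_act
  b <- (D / params$K_inh)^params$n_inh
  s <- S / params$Km
  params$kcat * s * (1 + a * params$alpha) /
    (1 + a + s * (1 + a * params$alpha) * (1 + b))
}

#' Apparent Michaelis-Menten constants at fixed drug concentration
#'
#' At any fixed drug concentration the two-site rate law is exactly
#' hyperbolic in substrate, so apparent constants exist in closed form:
#' `Vmax_app = kcat / (1 + b)` and
#' `Km_app = Km (1 + a) / ((1 + a alpha)(1 + b))`.
#' `method = "fit"` instead recovers them numerically by least-squares
#' fitting of `v(S)` on a wide log-spaced substrate grid; the two routes must
#' agree, which is used as a consistency check.
#'
#' @param params a [mechanism_params] object.
#' @param D drug concentration (molar, scalar >= 0).
#' @param method `"analytic"` (closed form) or `"fit"` (numeric MM fit).
#' @return named numeric: `Vmax_app` (units of `kcat * E0`), `Km_app` (molar).
#' @export
apparent_mm <- function(params, D, method = c("analytic", "fit")) {
  stopifnot(inherits(params, "mechanism_params"), length(D) == 1L)
  if (D < 0) stop("D must be >= 0")
  method <- match.arg(method)
  if (method == "analytic") {
    a <- (D / params$K_act)^params$n_act
    b <- (D / params$K_inh)^params$n_inh
    return(c(Vmax_app = params$kcat / (1 + b),
             Km_app = params$Km * (1 + a) / ((1 + a * params$alpha) * (1 + b))))
  }
  S <- 10^seq(log10(params$Km) - 3, log10(params$Km) + 3, length.out = 60)
  v <- velocity(params, S, D)
  res <- function(th) v - th[1] * S / (th[2] + S)
  fit <- minpack.lm::nls.lm(par = c(max(v), params$Km), fn = res,
                            lower = c(0, 0),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  c(Vmax_app = fit$par[1], Km_app = fit$par[2])
}

#' Dose-response curve of the mechanism at fixed substrate
#'
#' Evaluates the velocity over a drug dose grid at a fixed substrate
#' concentration and normalizes to the zero-drug velocity as 100%. This is
#' the bridge from the mechanistic scheme to the empirical biphasic model:
#' the resulting curve can be fitted by [fit_biphasic()].
#'
#' @param params a [mechanism_params] object.
#' @param S substrate concentration (molar, scalar > 0).
#' @param dose_grid drug concentrations (molar, non-negative, strictly
#'   increasing; 0 allowed as first entry).
#' @return a [new_dose_response_curve] in percent of the zero-drug velocity.
#' @export
dose_response_curve <- function(params, S, dose_grid) {
  stopifnot(inherits(params, "mechanism_params"), length(S) == 1L, S > 0)
  v0 <- velocity(params, S, 0)
  v <- velocity(params, S, dose_grid)
  new_dose_response_curve(dose_grid, 100 * v / v0)
}

#' Classify the shape of a dose-response curve
#'
#' A curve is `biphasic` when its maximum exceeds *both* endpoints by more
#' than `tolerance`; otherwise it is `monotone_increasing` /
#' `monotone_decreasing` when consecutive differences beyond the tolerance
#' are all of one sign, and `flat` when no difference exceeds the tolerance.
#' A curve with sign changes but no interior peak above both endpoints (a
#' shallow dip) is assigned the monotone class of its net endpoint change.
#' The four classes are exhaustive and mutually exclusive at fixed tolerance.
#'
#' @param curve a [new_dose_response_curve] (or data.frame with `conc`,
#'   `response`), >= 3 grid points.
#' @param tolerance response-scale tolerance (same units as the curve; 1 =
#'   one percentage point for normalized mechanism curves).
#' @return one of `"flat"`, `"monotone_increasing"`, `"monotone_decreasing"`,
#'   `"biphasic"`.
#' @export
classify_response <- function(curve, tolerance = 1) {
  y <- curve$response
  if (length(y) < 3) stop("classification needs >= 3 grid points")
  d <- diff(y)
  up <- any(d > tolerance)
  down <- any(d < -tolerance)
  peak_above <- max(y) > y[1] + tolerance && max(y) > y[length(y)] + tolerance
  if (up && down && peak_above) return("biphasic")
  if (!up && !down) return("flat")
  if (up && !down) return("monotone_increasing")
  if (down && !up) return("monotone_decreasing")
  if (y[length(y)] < y[1] - tolerance) "monotone_decreasing" else "monotone_increasing"
}
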