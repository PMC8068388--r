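#' Parameters of the biphasic activation-inhibition dose-response model
#'
#' Bundles the seven quantities of the biphasic dose-response model into one
#' validated record. The model describes a response that first rises above the
#' vehicle baseline (activation) and then falls at higher drug concentrations
#' (inhibition):
#'
#' \deqn{S(x) = PA + (MA - PA) A(x) - (MA - MI) I(x)}
#'
#' with \eqn{x = \log_{10}(\mathrm{conc})},
#' \eqn{A(x) = 1 / (1 + 10^{(\log_{10} EC_{50} - x) p})} and
#' \eqn{I(x) = 1 / (1 + 10^{(\log_{10} IC_{50} - x) q})}.
#'
#' `PA` is the baseline activity at zero drug (the vehicle anchor), `MA` the
#' maximal activated plateau that would be reached if inhibition did not
#' compete, and `MI` the residual-activity plateau at saturating drug.
#' Midpoints are stored as log10 of molar concentration because dose designs
#' are logarithmic and logistic fitting is much better conditioned in log
#' space. `p` and `q` are the Hill coefficients of the activation and
#' inhibition transitions; values above one indicate that more than one drug
#' molecule participates in the binding event.
#'
#' An alternative field reading in which `MI` is an inhibition *magnitude*
#' (amount subtracted from `MA`) rather than a residual plateau is supported
#' through `mi_is_magnitude = TRUE`; the value is converted to the residual
#' plateau `MA - MI` at construction so that all downstream code sees one
#' convention.
#'
#' @param PA baseline activity at zero drug (response units, e.g. pM or
#'   percent of vehicle); must be >= 0.
#' @param MA maximal activated plateau, same units; `MA = PA` encodes "no
#'   activation".
#' @param MI residual activity plateau at saturating drug (or the inhibition
#'   magnitude when `mi_is_magnitude = TRUE`).
#' @param log10_EC50 log10 of the activation midpoint concentration (molar).
#' @param log10_IC50 log10 of the inhibition midpoint concentration (molar).
#' @param p,q activation and inhibition Hill coefficients (> 0).
#' @param mi_is_magnitude interpret `MI` as an inhibition magnitude below `MA`.
#' @param strict enforce the full invariant set (`MA >= PA`, `MI <= MA`,
#'   `PA, MI >= 0`). Fitting constructs relaxed records (`strict = FALSE`)
#'   because only `MA >= MI` is imposed during estimation.
#'
#' @return an object of class `biphasic_params`.
#' @export
biphasic_params <- function(PA, MA, MI, log10_EC50, log10_IC50, p, q,
                            mi_is_magnitude = FALSE, strict = TRUE) {
  vals <- c(PA = PA, MA = MA, MI = MI, log10_EC50 = log10_EC50,
            log10_IC50 = log10_IC50, p = p, q = q)
  if (!all(is.finite(vals)))
    stop("all biphasic parameters must be finite numbers")
  if (mi_is_magnitude) {
    MI <- MA - MI
    vals["MI"] <- MI
  }
  if (p <= 0 || q <= 0)
    stop("Hill coefficients p and q must be > 0")
  if (strict) {
    if (PA < 0 || MI < 0)
      stop("PA and MI must be >= 0")
    if (MA < PA)
      stop("MA must be >= PA (MA = PA encodes 'no activation')")
    if (MI > MA)
      stop("MI must be <= MA")
  }
  structure(as.list(vals), class = "biphasic_params")
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat("Biphasic dose-response parameters\n")
  cat(sprintf("  baseline PA        : %.4g\n", x$PA))
  cat(sprintf("  activated plateau  : %.4g (MA)\n", x$MA))
  cat(sprintf("  residual plateau   : %.4g (MI)\n", x$MI))
  cat(sprintf("  EC50               : %.3g M (log10 = %.3f), Hill p = %.3g\n",
              10^x$log10_EC50, x$log10_EC50, x$p))
  cat(sprintf("  IC50               : %.3g M (log10 = %.3f), Hill q = %.3g\n",
              10^x$log10_IC50, x$log10_IC50, x$q))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "biphasic_params"))
    stop("'params' must be a biphasic_params object")
  v <- unlist(params)
  if (!all(is.finite(v))) stop("non-finite biphasic parameter")
  if (params$p <= 0 || params$q <= 0) stop("Hill coefficients must be > 0")
  invisible(params)
}

.check_conc <- function(conc) {
  if (!is.numeric(conc) || anyNA(conc))
    stop("'conc' must be numeric and non-missing")
  if (any(conc < 0))
    stop("negative concentration: doses must be >= 0 molar")
  conc
}

# logistic rising term on log10-concentration scale; exact 0 at conc = 0
.logistic_rise <- function(conc, log10_mid, hill) {
  out <- numeric(length(conc))
  pos <- conc > 0
  out[pos] <- 1 / (1 + 10^((log10_mid - log10(conc[pos])) * hill))
  out
}

#' Evaluate the biphasic dose-response model
#'
#' Computes the full activation-minus-inhibition response at one or more drug
#' concentrations. The vehicle (`conc = 0`) is an exact special case that
#' returns `PA`; it is not approximated by a large negative log-dose, so no
#' pseudo-log floor constant can leak into fits.
#'
#' @param params a [biphasic_params] object.
#' @param conc drug concentration(s), molar, >= 0 (0 = vehicle).
#' @return numeric vector of responses, same length as `conc`.
#' @examples
#' pars <- biphasic_params(PA = 100, MA = 300, MI = 20,
#'                         log10_EC50 = -8, log10_IC50 = -6, p = 1, q = 2)
#' evaluate_biphasic(pars, c(0, 1e-8, 1e-7, 1e-5))
#' @export
evaluate_biphasic <- function(params, conc) {
  .check_params(params)
  .check_conc(conc)
  A <- .logistic_rise(conc, params$log10_EC50, params$p)
  I <- .logistic_rise(conc, params$log10_IC50, params$q)
  params$PA + (params$MA - params$PA) * A - (params$MA - params$MI) * I
}

#' Activation component of the biphasic model
#'
#' The rising half of the decomposition: `PA + (MA - PA) * A(x)`. Equals the
#' full model when `MI = MA` (no inhibition). This is the "activation event"
#' curve drawn separately from the inhibition event when the two binding
#' events can be separated.
#'
#' @inheritParams evaluate_biphasic
#' @return numeric vector of responses.
#' @export
activation_component <- function(params, conc) {
  .check_params(params)
  .check_conc(conc)
  params$PA + (params$MA - params$PA) * .logistic_rise(conc, params$log10_EC50, params$p)
}

#' Inhibition component of the biphasic model
#'
#' The falling half of the decomposition: `MA - (MA - MI) * I(x)`. It starts
#' from the un-opposed activation plateau `MA` and decays to the residual
#' plateau `MI`; it matches the full model at concentrations far above the
#' activation midpoint.
#'
#' @inheritParams evaluate_biphasic
#' @return numeric vector of responses.
#' @export
inhibition_component <- function(params, conc) {
  .check_params(params)
  .check_conc(conc)
  params$MA - (params$MA - params$MI) * .logistic_rise(conc, params$log10_IC50, params$q)
}

#' Locate the peak of a biphasic dose-response curve
#'
#' Maximizes the model over a concentration window by a dense log-spaced grid
#' scan refined with bounded one-dimensional optimization. When the curve has
#' no interior maximum above both window edges (flat or monotone within the
#' window) the result is flagged.
#'
#' @inheritParams evaluate_biphasic
#' @param conc_window numeric length-2, `c(lower, upper)` in molar; lower > 0.
#' @param tol flat/monotone detection tolerance on the response scale.
#' @return list with `conc_at_peak`, `peak_response`, and logical `monotone`
#'   (TRUE when the window contains no interior peak).
#' @export
peak_response <- function(params, conc_window, tol = 1e-9) {
  .check_params(params)
  if (length(conc_window) != 2 || anyNA(conc_window))
    stop("'conc_window' must be c(lower, upper) in molar")
  if (conc_window[1] <= 0) stop("window lower bound must be > 0 molar")
  if (conc_window[1] >= conc_window[2]) stop("empty or inverted window")
  lx <- log10(conc_window)
  f <- function(x) evaluate_biphasic(params, 10^x)
  grid <- seq(lx[1], lx[2], length.out = 1024L)
  sg <- f(grid)
  i <- which.max(sg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  peak <- max(opt$objective, sg[i])
  xpk <- if (opt$objective >= sg[i]) opt$maximum else grid[i]
  edge <- max(sg[1], sg[length(sg)])
  monotone <- peak <= edge + tol
  list(conc_at_peak = 10^xpk, peak_response = peak, monotone = monotone)
}

#' Serialize biphasic parameters to JSON
#'
#' Field names match the `biphasic_params` record exactly, so files written
#' here are readable by any JSON consumer and by [params_from_json()].
#'
#' @param params a [biphasic_params] object.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
params_to_json <- function(params, path = NULL) {
  .check_params(params)
  x <- unclass(params)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read biphasic parameters from JSON
#'
#' @param input a file path or a JSON string produced by [params_to_json()].
#' @param strict enforce full invariants (see [biphasic_params()]).
#' @return a [biphasic_params] object.
#' @export
params_from_json <- function(input, strict = TRUE) {
  x <- jsonlite::fromJSON(input)
  need <- c("PA", "MA", "MI", "log10_EC50", "log10_IC50", "p", "q")
  if (!all(need %in% names(x)))
    stop("JSON is missing biphasic parameter fields: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  biphasic_params(x$PA, x$MA, x$MI, x$log10_EC50, x$log10_IC50, x$p, x$q,
                  strict = strict)
}
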