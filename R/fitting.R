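#' Fitting options for dose-response regression
#'
#' @param n_starts number of multi-start initializations for the full
#'   biphasic model (>= 1). Sub-models in the nested family use their own
#'   small deterministic seed sets.
#' @param censored how to treat rows flagged outside the assay linear window:
#'   `"exclude"` (default), `"include"`, or `"downweight"` (weight x 0.1).
#' @param weighting `"none"` (unweighted least squares on the linear response
#'   scale, the default) or `"inverse_variance"` (weights from the
#'   per-concentration variance implied by a pooled-CV proportional noise
#'   model, `var_c` proportional to `mean_c^2`; appropriate when replicate
#'   scatter scales with the signal, as in ELISA readouts).
#' @param normalize `"none"` or `"percent_vehicle"` (divide responses by the
#'   mean vehicle response and multiply by 100 before fitting).
#' @param n_boot bootstrap replicates for parameter intervals (0 = skip).
#' @param seed integer seed for all stochastic steps (bootstrap resampling).
#' @param hill_max upper bound for both Hill coefficients.
#' @param mid_margin log10 units added on each side of the observed
#'   concentration range when bounding the midpoints (identifiability guard:
#'   midpoints far outside the design trade off against the plateaus).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 12L, censored = c("exclude", "include", "downweight"),
                       weighting = c("none", "inverse_variance"),
                       normalize = c("none", "percent_vehicle"),
                       n_boot = 0L, seed = 1L, hill_max = 10, mid_margin = 2) {
  if (n_starts < 1) stop("'n_starts' must be >= 1")
  structure(list(n_starts = as.integer(n_starts),
                 censored = match.arg(censored),
                 weighting = match.arg(weighting),
                 normalize = match.arg(normalize),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 hill_max = hill_max, mid_margin = mid_margin),
            class = "fit_config")
}

# ---- internal model family ---------------------------------------------------
# Internal parameterizations are chosen so every constraint is a box bound:
#   flat       c(mu)
#   activation c(PA, dA, e, p)        MA = PA + dA, dA >= 0
#   inhibition c(MI, dI, i, q)        PA = MA = MI + dI, dI >= 0
#   biphasic   c(PA, MI, d, e, i, p, q)  MA = MI + d, d >= 0  (MA >= MI)

.family_models <- c("flat", "activation_only", "inhibition_only", "biphasic")

.predict_model <- function(model, par, conc) {
  switch(model,
    flat = rep(par[1], length(conc)),
    activation_only = par[1] + par[2] *
      .logistic_rise(conc, par[3], par[4]),
    inhibition_only = (par[1] + par[2]) - par[2] *
      .logistic_rise(conc, par[3], par[4]),
    biphasic = {
      MA <- par[2] + par[3]
      par[1] + (MA - par[1]) * .logistic_rise(conc, par[4], par[6]) -
        par[3] * .logistic_rise(conc, par[5], par[7])
    },
    stop("unknown model: ", model))
}

.model_npar <- c(flat = 1L, activation_only = 4L, inhibition_only = 4L,
                 biphasic = 7L)

.xrange <- function(conc) range(log10(conc[conc > 0]))

.model_bounds <- function(model, conc, config) {
  xr <- .xrange(conc)
  lo_mid <- xr[1] - config$mid_margin
  hi_mid <- xr[2] + config$mid_margin
  hmax <- config$hill_max
  switch(model,
    flat = list(lower = -Inf, upper = Inf),
    activation_only = list(lower = c(0, 0, lo_mid, 1e-3),
                           upper = c(Inf, Inf, hi_mid, hmax)),
    inhibition_only = list(lower = c(0, 0, lo_mid, 1e-3),
                           upper = c(Inf, Inf, hi_mid, hmax)),
    biphasic = list(lower = c(0, 0, 0, lo_mid, lo_mid, 1e-3, 1e-3),
                    upper = c(Inf, Inf, Inf, hi_mid, hi_mid, hmax, hmax)))
}

#' Multi-start seeds for the biphasic fit
#'
#' Places the two log-midpoints on a deterministic grid over the observed
#' concentration range, always with `log10_EC50 < log10_IC50`: the EC50
#' candidates run across the range and the IC50 candidates sit at a grid of
#' positive offsets above each EC50. Plateau seeds come from response
#' quantiles (first response for `PA`, maximum for `MA`, last for `MI`), and
#' Hill coefficients start at 1. With `n_starts = 1` the midpoints sit at the
#' tertiles of the observed log-range.
#'
#' @param data a [dose_response_dataset].
#' @param n_starts number of seeds (>= 1).
#' @return list of relaxed [biphasic_params] seed records.
#' @export
multistart_seeds <- function(data, n_starts = 12L) {
  stopifnot(inherits(data, "dose_response_dataset"))
  if (n_starts < 1) stop("'n_starts' must be >= 1")
  ord <- order(data$conc_M)
  conc <- data$conc_M[ord]
  resp <- data$response[ord]
  xr <- .xrange(conc)
  span <- diff(xr)
  PA0 <- mean(resp[conc == min(conc)])
  MA0 <- max(resp)
  MI0 <- mean(resp[conc == max(conc)])
  if (diff(range(resp)) == 0) { MA0 <- PA0; MI0 <- PA0 }
  mk <- function(e, i) biphasic_params(PA = max(PA0, 0), MA = max(MA0, 0),
                                       MI = max(min(MI0, MA0), 0),
                                       log10_EC50 = e, log10_IC50 = i,
                                       p = 1, q = 1, strict = FALSE)
  if (n_starts == 1L)
    return(list(mk(xr[1] + span / 3, xr[1] + 2 * span / 3)))
  g <- ceiling(sqrt(n_starts))
  ecs <- seq(xr[1], xr[2] - span / g, length.out = g)
  offs <- seq(span / (g + 1), span * g / (g + 1), length.out = g)
  grid <- expand.grid(e = ecs, off = offs)
  grid <- grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(k) mk(grid$e[k], grid$e[k] + grid$off[k]))
}

.seed_to_internal <- function(seed) {
  d <- max(seed$MA - seed$MI, 0)
  c(seed$PA, seed$MI, d, seed$log10_EC50, seed$log10_IC50, seed$p, seed$q)
}

.submodel_seeds <- function(model, conc, resp) {
  ord <- order(conc)
  conc <- conc[ord]; resp <- resp[ord]
  xr <- .xrange(conc); span <- diff(xr)
  first <- mean(resp[conc == min(conc)])
  last <- mean(resp[conc == max(conc)])
  hi <- max(resp); lo <- min(resp)
  mids <- xr[1] + span * c(0.25, 0.5, 0.75)
  switch(model,
    flat = list(mean(resp)),
    activation_only = lapply(mids, function(m)
      c(max(first, 0), max(hi - first, 0), m, 1)),
    inhibition_only = lapply(mids, function(m)
      c(max(last, 0), max(first - last, 0), m, 1)),
    biphasic = NULL)
}

.fit_ls <- function(model, start, conc, y, w, bounds) {
  if (model == "flat") {
    mu <- sum(w * y) / sum(w)
    return(list(par = mu, rss = sum(w * (y - mu)^2), converged = TRUE))
  }
  res_fn <- function(par) sqrt(w) * (y - .predict_model(model, par, conc))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = res_fn,
                       lower = bounds$lower, upper = bounds$upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 400, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(par = fit$par, rss = fit$deviance,
       converged = fit$info %in% 1:4, fit = fit)
}

.fit_model_best <- function(model, conc, y, w, config, extra_starts = NULL) {
  bounds <- .model_bounds(model, conc, config)
  starts <- if (model == "biphasic") {
    dat <- dose_response_dataset("d", conc, y)
    c(lapply(multistart_seeds(dat, config$n_starts), .seed_to_internal),
      extra_starts)
  } else .submodel_seeds(model, conc, y)
  best <- NULL
  for (s in starts) {
    f <- .fit_ls(model, s, conc, y, w, bounds)
    if (is.null(f)) next
    if (is.null(best) || f$rss < best$rss) best <- f
  }
  if (!is.null(best)) best$n_starts_used <- length(starts)
  best
}

# small-sample corrected AIC for least squares; k counts the residual
# variance as one estimated parameter
.aicc <- function(rss, n, npar) {
  k <- npar + 1
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

.prepare_rows <- function(data, config) {
  w <- rep(1, nrow(data))
  keep <- rep(TRUE, nrow(data))
  out_of_window <- data$censored != "within"
  if (config$censored == "exclude") keep <- !out_of_window
  if (config$censored == "downweight") w[out_of_window] <- 0.1
  conc <- data$conc_M[keep]; y <- data$response[keep]; w <- w[keep]
  if (config$normalize == "percent_vehicle") {
    veh <- y[conc == 0]
    if (!length(veh)) stop("percent_vehicle normalization needs vehicle rows")
    y <- 100 * y / mean(veh)
  }
  if (config$weighting == "inverse_variance") {
    # per-concentration variance under a pooled-CV (proportional) noise
    # model: var_c = (CV * mean_c)^2. Raw per-concentration sample variances
    # from a handful of replicates are far too unstable to use as weights.
    mc <- tapply(y, conc, mean)
    v <- pmax(as.numeric(mc[match(as.character(conc), names(mc))]),
              1e-8 * max(abs(y), 1))^2
    w <- w / v
  }
  list(conc = conc, y = y, w = w)
}

.internal_to_params <- function(par) {
  biphasic_params(PA = par[1], MA = par[2] + par[3], MI = par[2],
                  log10_EC50 = par[4], log10_IC50 = par[5],
                  p = par[6], q = par[7], strict = FALSE)
}

.param_names <- c("PA", "MA", "MI", "log10_EC50", "log10_IC50", "p", "q")

.report_scale <- function(par) {
  c(PA = par[1], MA = par[2] + par[3], MI = par[2],
    log10_EC50 = par[4], log10_IC50 = par[5], p = par[6], q = par[7])
}

.se_reported <- function(fit, n) {
  k <- length(fit$par)
  if (is.null(fit$fit) || n <= k) return(stats::setNames(rep(NA_real_, 7), .param_names))
  sigma2 <- fit$rss / (n - k)
  cv <- tryCatch(sigma2 * solve(fit$fit$hessian), error = function(e) NULL)
  if (is.null(cv)) return(stats::setNames(rep(NA_real_, 7), .param_names))
  # gradient of (PA, MA, MI, e, i, p, q) wrt internal (PA, MI, d, e, i, p, q)
  G <- diag(7)[c(1, 2, 2, 4, 5, 6, 7), ]
  G[2, 3] <- 1            # MA = MI + d
  G[3, 3] <- 0            # MI row: only MI itself
  se <- sqrt(pmax(diag(G %*% cv %*% t(G)), 0))
  stats::setNames(se, .param_names)
}

#' Fit the nested dose-response model family and select by AICc
#'
#' Fits flat (1 parameter), activation-only (4), inhibition-only (4) and full
#' biphasic (7) models by bounded multi-start least squares, and ranks them by
#' small-sample corrected AIC. Models within 2 AICc units of the best are
#' treated as ties and resolved toward the fewer-parameter model, so the
#' biphasic claim must earn its three extra parameters.
#'
#' @param data a [dose_response_dataset].
#' @param config a [fit_config].
#' @return list with `model` (selected id) and `table` (per-model AICc,
#'   residual sum of squares, parameter count, convergence).
#' @export
select_model <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "dose_response_dataset"))
  rows <- .prepare_rows(data, config)
  n <- length(rows$y)
  tab <- data.frame(model = .family_models,
                    npar = as.integer(.model_npar[.family_models]),
                    rss = NA_real_, aicc = NA_real_, converged = NA)
  fits <- list()
  for (m in .family_models) {
    f <- tryCatch(.fit_model_best(m, rows$conc, rows$y, rows$w, config),
                  error = function(e) NULL)
    fits[[m]] <- f
    if (!is.null(f)) {
      i <- match(m, tab$model)
      tab$rss[i] <- f$rss
      tab$aicc[i] <- .aicc(f$rss, n, .model_npar[[m]])
      tab$converged[i] <- f$converged
    }
  }
  ok <- !is.na(tab$aicc)
  if (!any(ok)) stop("no model in the nested family could be fitted")
  best <- min(tab$aicc[ok])
  tied <- ok & (tab$aicc <= best + 2)
  cand <- tab[tied, ]
  cand <- cand[order(cand$npar, cand$aicc), ]
  list(model = cand$model[1], table = tab, fits = fits)
}

#' Fit the biphasic dose-response model to a dataset
#'
#' Bounded multi-start nonlinear least squares on the linear response scale.
#' Every start is a deterministic function of the data and `config`, so the
#' fit is reproducible; the reported solution is the lowest-RSS candidate.
#' Bounds: `PA, MI >= 0`, `MA >= MI` (via the fitted activation span),
#' `0 < p, q <= hill_max`, and both log-midpoints within the observed
#' concentration range widened by `mid_margin` log units. Vehicle rows take
#' part in the fit (they anchor `PA`). The nested model family is always
#' fitted alongside for the model-selection verdict.
#'
#' @param data a [dose_response_dataset] with >= 6 distinct non-zero
#'   concentrations; the non-zero concentrations must span >= 2 log10 units
#'   (below that the two transitions of a biphasic model are not
#'   identifiable and the fit refuses with guidance).
#' @param config a [fit_config]; `config$n_boot > 0` adds bootstrap
#'   percentile intervals.
#' @return an object of class `biphasic_fit`: `params` (point estimate),
#'   `se`, `ci` (bootstrap, or NULL), `rss`, `r_squared`, `converged`,
#'   `n_starts_used`, `selected_model`, `model_table`, `n_obs`.
#' @export
fit_biphasic <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "dose_response_dataset"))
  rows <- .prepare_rows(data, config)
  nz <- unique(rows$conc[rows$conc > 0])
  if (length(nz) < 6)
    stop("full biphasic fit needs >= 6 distinct non-zero concentrations ",
         "(got ", length(nz), "); extend the dose design or fit a sub-model ",
         "with select_model()")
  span <- diff(.xrange(rows$conc))
  if (span < 2)
    stop(sprintf(paste0("non-zero concentrations span only %.2f log10 units; ",
                        "a full biphasic fit needs >= 2 (ideally >= 3) so that ",
                        "both transitions are identifiable. Widen the dose ",
                        "range or fit a single-phase model."), span))
  sel <- select_model(data, config)
  bi <- sel$fits[["biphasic"]]
  if (is.null(bi))
    stop("all multi-start biphasic fits failed to converge")
  est <- .report_scale(bi$par)
  n <- length(rows$y)
  fitted_vals <- .predict_model("biphasic", bi$par, rows$conc)
  tss <- sum(rows$w * (rows$y - sum(rows$w * rows$y) / sum(rows$w))^2)
  out <- structure(list(
    drug = data$drug[1],
    params = .internal_to_params(bi$par),
    se = .se_reported(bi, n),
    ci = NULL,
    rss = bi$rss,
    r_squared = if (tss > 0) 1 - bi$rss / tss else NA_real_,
    converged = bi$converged,
    n_starts_used = bi$n_starts_used,
    selected_model = sel$model,
    model_table = sel$table,
    n_obs = n,
    fitted = fitted_vals,
    response_units = attr(data, "response_units")),
    class = "biphasic_fit")
  if (config$n_boot > 0)
    out$ci <- bootstrap_ci(data, config, n_boot = config$n_boot,
                           seed = config$seed)
  out
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("Biphasic dose-response fit: %s (%d observations)\n",
              x$drug, x$n_obs))
  cat(sprintf("  selected model: %s   RSS = %.6g   R^2 = %.4f\n",
              x$selected_model, x$rss, x$r_squared))
  est <- unlist(x$params)
  for (nm in .param_names)
    cat(sprintf("  %-11s %12.5g  (se %.3g)\n", nm, est[[nm]], x$se[[nm]]))
  invisible(x)
}

#' Bootstrap percentile intervals for biphasic parameters
#'
#' Two resampling schemes are available. `"case"` resamples replicates with
#' replacement within each concentration (every concentration keeps its
#' replicate count). `"residual"` resamples the pooled point-fit residuals
#' onto the fitted curve -- as *relative* residuals when all fitted values
#' are positive (the natural scaling for assay noise whose spread follows
#' the signal), raw residuals otherwise. The default `"auto"` picks
#' `"residual"` whenever any concentration has fewer than 4 replicates:
#' with a handful of replicates per concentration the within-cell case
#' bootstrap systematically understates the conditional variance (the
#' plug-in cell variance carries a factor (n-1)/n and is itself extremely
#' noisy), which drags interval coverage well below nominal, while pooling
#' residuals across the design restores close-to-nominal coverage. Refits
#' warm-start from the point estimate. Intervals are percentile intervals.
#'
#' @param data a [dose_response_dataset].
#' @param config a [fit_config].
#' @param n_boot number of bootstrap datasets (>= 100).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param level confidence level for the percentile interval.
#' @param scheme `"auto"`, `"case"`, or `"residual"` (see above).
#' @return data.frame with one row per parameter: `estimate`, `lower`,
#'   `upper`, plus attribute `scheme` (the scheme actually used).
#' @export
bootstrap_ci <- function(data, config = fit_config(), n_boot = 200L,
                         seed = config$seed, level = 0.95,
                         scheme = c("auto", "case", "residual")) {
  stopifnot(inherits(data, "dose_response_dataset"))
  if (n_boot < 100) stop("'n_boot' must be >= 100 for stable percentiles")
  scheme <- match.arg(scheme)
  cfg0 <- config; cfg0$n_boot <- 0L
  rows <- .prepare_rows(data, cfg0)
  point <- .fit_model_best("biphasic", rows$conc, rows$y, rows$w, cfg0)
  if (is.null(point)) stop("point fit failed; cannot bootstrap")
  est <- .report_scale(point$par)
  reps_per_conc <- table(rows$conc)
  if (scheme == "auto")
    scheme <- if (any(reps_per_conc < 4)) "residual" else "case"
  if (scheme == "case" && any(reps_per_conc < 2)) {
    warning("single replicate at some concentrations: ",
            "falling back to residual resampling")
    scheme <- "residual"
  }
  pred <- .predict_model("biphasic", point$par, rows$conc)
  resid <- rows$y - pred
  relative <- all(pred > 0)
  rel_resid <- if (relative) resid / pred else resid
  idx_by_conc <- split(seq_along(rows$conc), rows$conc)
  bounds <- .model_bounds("biphasic", rows$conc, cfg0)
  starts <- list(point$par,
                 .seed_to_internal(multistart_seeds(
                   dose_response_dataset("d", rows$conc, rows$y), 1L)[[1]]))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 7, dimnames = list(NULL, .param_names))
  for (b in seq_len(n_boot)) {
    if (scheme == "case") {
      take <- unlist(lapply(idx_by_conc, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      cb <- rows$conc[take]; yb <- rows$y[take]; wb <- rows$w[take]
    } else {
      cb <- rows$conc; wb <- rows$w
      draw <- rel_resid[sample.int(length(rel_resid), replace = TRUE)]
      yb <- if (relative) pred * (1 + draw) else pred + draw
    }
    best <- NULL
    for (s in starts) {
      f <- .fit_ls("biphasic", s, cb, yb, wb, bounds)
      if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
    }
    if (!is.null(best)) draws[b, ] <- .report_scale(best$par)
  }
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE,
              names = FALSE)
  out <- data.frame(parameter = .param_names,
                    estimate = as.numeric(est[.param_names]),
                    lower = pmin(qs[1, ], est[.param_names]),
                    upper = pmax(qs[2, ], est[.param_names]))
  attr(out, "scheme") <- scheme
  attr(out, "n_boot") <- n_boot
  out
}

#' Summarize fits as a per-drug parameter table
#'
#' One row per fitted drug with the fields reported for biphasic
#' dose-response tables: EC50 and IC50 on the molar scale, both Hill
#' coefficients, baseline and plateau activities, the selected model, and the
#' AICc margin of the biphasic model over the best competing model (negative
#' margins favor the biphasic model).
#'
#' @param fits a list of `biphasic_fit` objects.
#' @return a `data.frame` with columns drug, EC50_M, hill_activation, IC50_M,
#'   hill_inhibition, baseline_PA, max_activity_MA, residual_MI,
#'   selected_model, aicc_margin, r_squared.
#' @export
fit_summary_table <- function(fits) {
  if (inherits(fits, "biphasic_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    p <- f$params
    tab <- f$model_table
    others <- tab$aicc[tab$model != "biphasic"]
    margin <- tab$aicc[tab$model == "biphasic"] - min(others, na.rm = TRUE)
    data.frame(drug = f$drug,
               EC50_M = 10^p$log10_EC50, hill_activation = p$p,
               IC50_M = 10^p$log10_IC50, hill_inhibition = p$q,
               baseline_PA = p$PA, max_activity_MA = p$MA,
               residual_MI = p$MI,
               selected_model = f$selected_model,
               aicc_margin = margin, r_squared = f$r_squared)
  }))
}
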