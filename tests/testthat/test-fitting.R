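test_that("multi-start seeds follow the documented layout", {
  pars <- biphasic_params(100, 300, 20, -8, -6, 1, 2)
  d <- simulate_assay(pars, noisefree_design(), "x")
  s1 <- multistart_seeds(d, 1L)
  expect_length(s1, 1)
  xr <- range(log10(d$conc_M[d$conc_M > 0]))
  span <- diff(xr)
  expect_equal(s1[[1]]$log10_EC50, xr[1] + span / 3)
  expect_equal(s1[[1]]$log10_IC50, xr[1] + 2 * span / 3)
  expect_equal(s1[[1]]$p, 1); expect_equal(s1[[1]]$q, 1)
  expect_equal(s1[[1]]$MA, max(d$response))
  s16 <- multistart_seeds(d, 16L)
  expect_length(s16, 16)
  pairs <- t(vapply(s16, function(s) c(s$log10_EC50, s$log10_IC50), numeric(2)))
  expect_equal(nrow(unique(pairs)), 16)            # distinct pairs
  expect_length(unique(pairs[, 1]), 4)             # 4x4 midpoint grid
  expect_length(unique(round(pairs[, 2] - pairs[, 1], 10)), 4)
  expect_true(all(pairs[, 1] < pairs[, 2]))        # EC50 < IC50 everywhere
  # constant responses collapse the plateau seeds
  dc <- dose_response_dataset("x", 10^seq(-9, -5, length.out = 8), rep(42, 8))
  sc <- multistart_seeds(dc, 4L)
  for (s in sc) expect_true(s$PA == 42 && s$MA == 42 && s$MI == 42)
  expect_error(multistart_seeds(d, 0), ">= 1")
})

test_that("noise-free biphasic data are recovered to 1e-4 relative", {
  truth <- biphasic_params(100, 300, 20, -8, -6, 1.2, 2.4)
  d <- simulate_assay(truth, noisefree_design(), "x")
  f <- fit_biphasic(d)
  got <- unlist(f$params)
  want <- unlist(truth)
  expect_true(all(abs(got - want) / abs(want) < 1e-4))
  expect_equal(f$selected_model, "biphasic")
  expect_true(f$converged)
  # refitting its own predictions is a fixed point
  d2 <- dose_response_dataset("x", d$conc_M,
                              evaluate_biphasic(f$params, d$conc_M))
  f2 <- fit_biphasic(d2)
  expect_equal(unlist(f2$params), got, tolerance = 1e-6)
})

test_that("degenerate and single-phase generators select their own model", {
  # constant data
  dflat <- dose_response_dataset("x", c(0, 10^seq(-9, -5, length.out = 11)),
                                 rep(80, 12))
  sel <- select_model(dflat)
  expect_equal(sel$model, "flat")
  fflat <- fit_biphasic(dflat)
  expect_equal(fflat$selected_model, "flat")
  expect_lt(abs(fflat$params$MA - fflat$params$MI), 1e-3)
  expect_lt(abs(fflat$params$MA - fflat$params$PA), 1e-3)
  # pure inhibition curve (MA = PA): model and IC50 both recovered
  truth <- biphasic_params(100, 100, 20, -8, -6.2, 1, 1.8)
  d <- simulate_assay(truth, noisefree_design(), "x")
  sel <- select_model(d)
  expect_equal(sel$model, "inhibition_only")
  ic50_hat <- sel$fits$inhibition_only$par[3]
  expect_lt(abs(ic50_hat - truth$log10_IC50), 0.05)
})

test_that("fit refuses designs that cannot identify a biphasic model", {
  pars <- biphasic_params(100, 300, 20, -8, -6, 1, 2)
  narrow <- assay_design(conc_min = 1e-8, conc_max = 3e-7, n_conc = 8,
                         n_replicates = 1,
                         noise = list(type = "proportional", cv = 0),
                         elisa_window = c(-Inf, Inf))
  d <- simulate_assay(pars, narrow, "x")
  expect_error(fit_biphasic(d), "log10 units")
  few <- dose_response_dataset("x", c(0, 1e-8, 1e-7, 1e-6, 1e-5),
                               c(100, 150, 250, 150, 50))
  expect_error(fit_biphasic(few), "6 distinct")
})

test_that("objective scales as the square of response units; EC50/IC50 invariant", {
  truth <- biphasic_params(100, 300, 20, -8, -6, 1.2, 2.4)
  d <- simulate_assay(truth, noisy_design(11), "x")
  f1 <- fit_biphasic(d)
  d2 <- d; d2$response <- d$response * 7
  f2 <- fit_biphasic(d2)
  expect_equal(f2$rss, 49 * f1$rss, tolerance = 1e-6)
  expect_equal(f2$params$log10_EC50, f1$params$log10_EC50, tolerance = 1e-6)
  expect_equal(f2$params$log10_IC50, f1$params$log10_IC50, tolerance = 1e-6)
  expect_equal(f2$params$MA, 7 * f1$params$MA, tolerance = 1e-6)
})

test_that("parameter recovery under 5% assay noise meets the error budget", {
  set.seed(101)
  n_sim <- 60
  err <- matrix(NA_real_, n_sim, 4,
                dimnames = list(NULL, c("e", "i", "p", "q")))
  for (k in seq_len(n_sim)) {
    truth <- draw_true_params()
    d <- simulate_assay(truth, noisy_design(seed = 5000 + k), "x")
    f <- fit_biphasic(d, fit_config(n_starts = 12))
    err[k, ] <- c(f$params$log10_EC50 - truth$log10_EC50,
                  f$params$log10_IC50 - truth$log10_IC50,
                  f$params$p - truth$p, f$params$q - truth$q)
  }
  expect_lt(median(abs(err[, "e"])), 0.15)
  expect_lt(median(abs(err[, "i"])), 0.15)
  expect_lt(median(abs(err[, "p"])), 0.3)
  expect_lt(median(abs(err[, "q"])), 0.3)
})

test_that("steeper inhibition than activation is preserved by the fit", {
  set.seed(33)
  hits <- 0; n <- 20
  for (k in 1:n) {
    truth <- biphasic_params(100, 300, 15, -8.2, -6.2,
                             p = runif(1, 0.9, 1.3), q = runif(1, 2, 3))
    d <- simulate_assay(truth, noisy_design(seed = 700 + k), "x")
    f <- fit_biphasic(d)
    hits <- hits + (f$params$q > f$params$p)
  }
  expect_gte(hits, 18)
})

test_that("bootstrap intervals are reproducible, cover the estimate, and
           collapse on noise-free data", {
  truth <- biphasic_params(100, 300, 20, -8, -6, 1.2, 2.4)
  d <- simulate_assay(truth, noisy_design(3), "x")
  ci1 <- bootstrap_ci(d, fit_config(), n_boot = 120, seed = 99)
  ci2 <- bootstrap_ci(d, fit_config(), n_boot = 120, seed = 99)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower <= ci1$estimate & ci1$estimate <= ci1$upper))
  # 3 replicates per concentration: auto picks pooled residual resampling
  expect_identical(attr(ci1, "scheme"), "residual")
  cic <- bootstrap_ci(d, fit_config(), n_boot = 120, seed = 99,
                      scheme = "case")
  expect_identical(attr(cic, "scheme"), "case")
  expect_true(all(cic$lower <= cic$estimate & cic$estimate <= cic$upper))
  d0 <- simulate_assay(truth, noisefree_design(), "x")
  # explicit case scheme with single replicates: documented fallback
  expect_warning(ci0 <- bootstrap_ci(d0, fit_config(), n_boot = 120, seed = 1,
                                     scheme = "case"),
                 "residual")
  expect_true(all(ci0$upper - ci0$lower < 1e-6))
  expect_error(bootstrap_ci(d, n_boot = 50), ">= 100")
})

test_that("bootstrap 95% intervals cover the true activation midpoint at
           close to nominal rate", {
  set.seed(55)
  cover <- 0
  for (k in 1:100) {
    tr <- draw_true_params()
    d <- simulate_assay(tr, noisy_design(seed = 40000 + k), "x")
    ci <- bootstrap_ci(d, fit_config(), n_boot = 199, seed = 900 + k)
    e <- ci[ci$parameter == "log10_EC50", ]
    cover <- cover + (e$lower <= tr$log10_EC50 && tr$log10_EC50 <= e$upper)
  }
  expect_gte(cover, 90)
  expect_lte(cover, 99)
})

test_that("weighting, normalization and censor handling are honored", {
  truth <- biphasic_params(100, 300, 20, -8, -6, 1.2, 2.4)
  d <- simulate_assay(truth, noisy_design(8), "x")
  fw <- fit_biphasic(d, fit_config(weighting = "inverse_variance"))
  expect_equal(fw$selected_model, "biphasic")
  fn <- fit_biphasic(d, fit_config(normalize = "percent_vehicle"))
  expect_lt(abs(fn$params$PA - 100), 10)   # baseline is ~100% of vehicle
  # censored rows excluded by default, kept when asked
  dcens <- apply_elisa_window(d, c(50, 1e5))
  n_out <- sum(dcens$censored != "within")
  expect_gt(n_out, 0)
  f_ex <- fit_biphasic(dcens, fit_config(censored = "exclude"))
  f_in <- fit_biphasic(dcens, fit_config(censored = "include"))
  expect_equal(f_ex$n_obs, nrow(d) - n_out)
  expect_equal(f_in$n_obs, nrow(d))
})

test_that("the summary table mirrors the per-drug parameter table", {
  truth <- biphasic_params(100, 300, 20, -8, -6, 1.2, 2.4)
  d <- simulate_assay(truth, noisefree_design(), "drugA")
  tab <- fit_summary_table(fit_biphasic(d))
  expect_named(tab, c("drug", "EC50_M", "hill_activation", "IC50_M",
                      "hill_inhibition", "baseline_PA", "max_activity_MA",
                      "residual_MI", "selected_model", "aicc_margin",
                      "r_squared"))
  expect_equal(tab$EC50_M, 1e-8, tolerance = 1e-3)
  expect_equal(tab$selected_model, "biphasic")
  expect_lt(tab$aicc_margin, 0)
})
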