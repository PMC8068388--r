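#!/usr/bin/env Rscript
# Stage 3: the mechanistic argument. A two-site enzyme-modifier scheme --
# drug binding at an activation site that facilitates substrate capture
# (Km -> Km/alpha) plus dead-end uncompetitive binding on the
# enzyme-substrate complex -- reproduces the biphasic dose-response, but
# only at sub-saturating substrate. The generated curves are then fitted
# with the empirical biphasic model to show that the recovered EC50/IC50
# track the underlying binding constants.

library(biphasicdr)

outdir <- "results/mechanism"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
grid <- c(0, 10^seq(-10, -4, length.out = 40))
mp <- mechanism_params(kcat = 1, Km = 1e-6, K_act = 1e-8, alpha = 10,
                       K_inh = 1e-6, n_act = 1, n_inh = 2)

# 1. response shape across substrate saturation
svals <- mp$Km * 10^seq(-2, 3, length.out = 11)
scan <- do.call(rbind, lapply(svals, function(S) {
  crv <- dose_response_curve(mp, S, grid)
  data.frame(S_over_Km = S / mp$Km,
             class = classify_response(crv),
             peak_over_baseline = max(crv$response) / 100)
}))
write.csv(scan, file.path(outdir, "saturation_scan.csv"), row.names = FALSE)
cat("Response class vs substrate saturation (alpha = 10, K_act = 10 nM,\n",
    "K_inh = 1 uM, n_inh = 2):\n", sep = "")
print(scan, row.names = FALSE, digits = 3)
cat("\nThe biphasic shape exists only while S << Km; saturation abolishes\n")
cat("the activation phase and leaves plain uncompetitive inhibition.\n\n")

# 2. apparent Michaelis-Menten constants across drug dose
dvals <- c(0, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5)
app <- do.call(rbind, lapply(dvals, function(D) {
  a <- apparent_mm(mp, D)
  data.frame(D_M = D, Vmax_app = a[["Vmax_app"]], Km_app = a[["Km_app"]])
}))
write.csv(app, file.path(outdir, "apparent_mm.csv"), row.names = FALSE)
cat("Apparent MM constants vs drug dose (Km drops first via the activation\n")
cat("site, then Vmax falls as the uncompetitive site loads):\n")
print(app, row.names = FALSE, digits = 3)

# 3. bridge: fit mechanism-generated curves with the biphasic model
gridb <- c(0, 10^seq(-10.5, -3.5, length.out = 16))
bridge <- do.call(rbind, lapply(c(8, 10, 15), function(alpha) {
  do.call(rbind, lapply(c(1, 2), function(n) {
    m <- mechanism_params(kcat = 1, Km = 1e-6, K_act = 1e-8, alpha = alpha,
                          K_inh = 1e-6, n_act = n, n_inh = n)
    crv <- dose_response_curve(m, 0.1 * m$Km, gridb)
    f <- fit_biphasic(dose_response_dataset("mech", crv$conc, crv$response))
    data.frame(alpha = alpha, n = n, r_squared = f$r_squared,
               dlog10_EC50_vs_Kact = f$params$log10_EC50 - log10(m$K_act),
               dlog10_IC50_vs_Kinh = f$params$log10_IC50 - log10(m$K_inh),
               fit_p = f$params$p, fit_q = f$params$q)
  }))
}))
write.csv(bridge, file.path(outdir, "bridge_fits.csv"), row.names = FALSE)
cat("\nBiphasic fits of mechanism-generated curves at S = 0.1 Km:\n")
print(bridge, row.names = FALSE, digits = 3)
cat("\nRecovered midpoints sit within ~0.4 log of the binding constants,\n")
cat("and the fitted Hill coefficients track the site stoichiometry n.\n")
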