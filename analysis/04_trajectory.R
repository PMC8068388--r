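#!/usr/bin/env Rscript
# Stage 4: trajectory mobility layer on synthetic coordinate ensembles.
# Two 40-residue pseudo-CA trajectories emulate an apo protein with a
# mobile loop (residues 15-25) and a drug-bound state in which that loop
# is damped to 40% amplitude -- the signature a drug leaves when it rigidifies
# the flexible loops it binds. RMSF profiles, mobility classes, RMSD series,
# PCA spectra and the per-residue RMSF decrease are written as CSV tables.

library(biphasicdr)

seed <- 1L
outdir <- "results/trajectory"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config(seed = seed)

n_res <- 40
sig_apo <- rep(0.5, n_res); sig_apo[15:25] <- 1.2
sig_bound <- sig_apo; sig_bound[15:25] <- 1.2 * 0.4

t_apo <- simulate_trajectory(n_res, 600, sig_apo,
                             seed = derive_seed(seed, 41))
t_bound <- simulate_trajectory(n_res, 600, sig_bound,
                               seed = derive_seed(seed, 42))
f_apo <- file.path(tempdir(), "apo.pdb")
f_bound <- file.path(tempdir(), "bound.pdb")
write_trajectory(t_apo, f_apo)
write_trajectory(t_bound, f_bound)

paths <- suppressWarnings(run_traj(cfg, f_apo, outdir,
                                   compare_path = f_bound))

prof <- read.csv(paths$rmsf, comment.char = "#")
cat("\nApo RMSF profile: loop residues are the 'highest' mobility class:\n")
print(table(loop = seq_len(n_res) %in% 15:25, class = prof$class))

regions <- read.csv(paths$delta_regions, comment.char = "#")
cat("\nLargest drug-induced RMSF decrease region:\n")
print(regions[1, ], row.names = FALSE, digits = 3)
cat("\n(The generator damped residues 15-25; the analysis recovers that\n")
cat("window from coordinates alone.) Salt-bridge occupancy is empty here\n")
cat("because the pseudo-CA fixtures carry no charged side-chain atoms.\n")
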