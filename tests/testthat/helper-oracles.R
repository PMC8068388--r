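# Independent oracles and shared fixtures for the test suite.
# Every oracle is coded from the model definition along a different algebraic
# route than the package implementation, so agreement is informative.

# Brute-force biphasic response: logistic terms written via the equivalent
# 10^(x p) / (10^(x p) + 10^(m p)) form, vehicle handled by limits.
oracle_biphasic <- function(PA, MA, MI, e, i, p, q, conc) {
  vapply(conc, function(cc) {
    if (cc == 0) return(PA)
    x <- log10(cc)
    A <- 10^(x * p) / (10^(x * p) + 10^(e * p))
    I <- 10^(x * q) / (10^(x * q) + 10^(i * q))
    PA + (MA - PA) * A - (MA - MI) * I
  }, numeric(1))
}

# Species-balance oracle for the two-site modifier scheme: explicit state
# enumeration with weights accumulated along a canonical binding path
# (activation site first, then substrate, then the dead-end inhibition site).
oracle_velocity <- function(mp, S, D) {
  a <- (D / mp$K_act)^mp$n_act
  b <- (D / mp$K_inh)^mp$n_inh
  num <- 0; den <- 0
  for (act in 0:1) for (sub in 0:1) for (inh in 0:1) {
    if (inh == 1 && sub == 0) next            # inhibition site needs ES
    Km_eff <- if (act == 1) mp$Km / mp$alpha else mp$Km
    w <- (if (act == 1) a else 1) *
      (if (sub == 1) S / Km_eff else 1) *
      (if (inh == 1) b else 1)
    den <- den + w
    if (sub == 1 && inh == 0) num <- num + w  # catalytic states
  }
  mp$kcat * num / den
}

# documented truth ranges for the fitting simulations: baseline fixed at 100,
# 2-4x activation, residual 5-30% of baseline, activation midpoint in the
# middle of the dose design, inhibition 1.5-2.5 logs above it
draw_true_params <- function() {
  PA <- 100
  e <- stats::runif(1, -8.5, -7.5)
  biphasic_params(PA = PA,
                  MA = PA * stats::runif(1, 2, 4),
                  MI = PA * stats::runif(1, 0.05, 0.3),
                  log10_EC50 = e,
                  log10_IC50 = e + stats::runif(1, 1.5, 2.5),
                  p = stats::runif(1, 0.8, 2),
                  q = stats::runif(1, 1, 3))
}

noisefree_design <- function(n_conc = 12L)
  assay_design(n_conc = n_conc, n_replicates = 1L,
               noise = list(type = "proportional", cv = 0),
               elisa_window = c(-Inf, Inf))

noisy_design <- function(seed, cv = 0.05)
  assay_design(n_replicates = 3L,
               noise = list(type = "proportional", cv = cv),
               elisa_window = c(-Inf, Inf), seed = seed)

random_rotation_matrix <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# static helical chain replicated over frames, built directly (no rounding)
static_trajectory <- function(n_residues = 20, n_frames = 10) {
  t <- seq_len(n_residues)
  ang <- t * 100 * pi / 180
  base <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
  coords <- array(NA_real_, c(n_frames, n_residues, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- base
  trajectory(coords, data.frame(eleno = t, elety = "CA", resid = "ALA",
                                chain = "A", resno = t,
                                stringsAsFactors = FALSE))
}

apply_rigid <- function(traj, seed = 1) {
  set.seed(seed)
  out <- traj$coords
  for (f in seq_len(dim(out)[1])) {
    R <- random_rotation_matrix()
    shift <- matrix(stats::runif(3, -15, 15), dim(out)[2], 3, byrow = TRUE)
    out[f, , ] <- traj$coords[f, , ] %*% t(R) + shift
  }
  trajectory(out, traj$atoms)
}

# minimal two-residue (ASP, LYS) complex with a controllable NZ-OD1 distance
# per frame; includes CA atoms so the trajectory is not degenerate
salt_bridge_fixture <- function(nz_od1_dist) {
  n_fr <- length(nz_od1_dist)
  atoms <- data.frame(
    eleno = 1:4,
    elety = c("CA", "OD1", "CA", "NZ"),
    resid = c("ASP", "ASP", "LYS", "LYS"),
    chain = "A", resno = c(1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
  coords <- array(0, c(n_fr, 4, 3))
  for (f in seq_len(n_fr)) {
    coords[f, 1, ] <- c(0, 0, 0)
    coords[f, 2, ] <- c(1.5, 0, 0)
    coords[f, 3, ] <- c(0, 5, 0)
    coords[f, 4, ] <- c(1.5 + nz_od1_dist[f], 0, 0)
  }
  trajectory(coords, atoms)
}
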