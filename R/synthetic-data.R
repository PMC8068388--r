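#' Synthetic assay design
#'
#' Describes the dose design and noise model of a cell-based sandwich-ELISA
#' dose-response experiment: a log-spaced drug dose grid plus a DMSO vehicle
#' (0 M) row per replicate, overnight-incubation-style replicate noise, and
#' the detection window of the ELISA readout. Defaults mirror a desk-scale
#' version of the emulated assay: 12 log-spaced concentrations from 0.1 nM to
#' 100 uM plus vehicle, 3 replicates, and 5% proportional (CV) noise.
#'
#' @param conc_min,conc_max dose grid limits (molar), `conc_min < conc_max`.
#' @param n_conc number of log-spaced non-zero concentrations (>= 3).
#' @param n_replicates replicates per concentration.
#' @param include_vehicle add `conc_M = 0` vehicle rows.
#' @param noise list: either `list(type = "proportional", cv = ...)` or
#'   `list(type = "additive", sd = ...)`.
#' @param elisa_window assay linear range `c(low, high)` used to set per-row
#'   censor flags (units of the simulated response; the emulated Abeta 1-40
#'   kit is linear from 6 to 125 pM).
#' @param seed integer seed for the replicate noise.
#' @return a list of class `assay_design`.
#' @export
assay_design <- function(conc_min = 1e-10, conc_max = 1e-4, n_conc = 12L,
                         n_replicates = 3L, include_vehicle = TRUE,
                         noise = list(type = "proportional", cv = 0.05),
                         elisa_window = c(6, 125), seed = 1L) {
  if (conc_min <= 0 || conc_min >= conc_max) stop("need 0 < conc_min < conc_max")
  if (n_conc < 3) stop("need at least 3 concentrations")
  noise$type <- match.arg(noise$type, c("proportional", "additive"))
  lvl <- if (noise$type == "proportional") noise$cv else noise$sd
  if (is.null(lvl) || lvl < 0) stop("noise level (cv or sd) must be >= 0")
  structure(list(conc_min = conc_min, conc_max = conc_max,
                 n_conc = as.integer(n_conc),
                 n_replicates = as.integer(n_replicates),
                 include_vehicle = isTRUE(include_vehicle),
                 noise = noise, elisa_window = elisa_window,
                 seed = as.integer(seed)),
            class = "assay_design")
}

#' Dose grid of an assay design
#' @param design an [assay_design].
#' @return non-zero concentrations (molar), log-spaced, increasing.
#' @export
design_grid <- function(design) {
  10^seq(log10(design$conc_min), log10(design$conc_max),
         length.out = design$n_conc)
}

#' Simulate a dose-response dataset
#'
#' Generates replicate responses from a known ground truth -- either a
#' [biphasic_params] record (responses are model values) or a
#' [mechanism_params] record with a substrate concentration `S` (responses
#' are mechanism velocities normalized to vehicle = 100%) -- and adds
#' replicate noise per the design. Rows whose *measured* response falls
#' outside the ELISA window are censor-flagged, never dropped. Identical
#' seeds give identical datasets.
#'
#' @param truth a [biphasic_params] or [mechanism_params] object.
#' @param design an [assay_design].
#' @param drug_id drug label for the dataset.
#' @param S substrate concentration (molar), required for mechanism truth.
#' @return a [dose_response_dataset] with the ground truth attached as
#'   attribute `"truth"`.
#' @export
simulate_assay <- function(truth, design = assay_design(), drug_id = "drug",
                           S = NULL) {
  stopifnot(inherits(design, "assay_design"))
  grid <- design_grid(design)
  conc <- if (design$include_vehicle) c(0, grid) else grid
  if (inherits(truth, "biphasic_params")) {
    clean <- evaluate_biphasic(truth, conc)
    units <- "pM"
  } else if (inherits(truth, "mechanism_params")) {
    if (is.null(S)) stop("mechanism truth needs a substrate concentration S")
    clean <- 100 * velocity(truth, S, conc) / velocity(truth, S, 0)
    units <- "% of vehicle"
  } else stop("'truth' must be biphasic_params or mechanism_params")
  conc_all <- rep(conc, times = design$n_replicates)
  clean_all <- rep(clean, times = design$n_replicates)
  rep_all <- rep(seq_len(design$n_replicates), each = length(conc))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)
  z <- stats::rnorm(length(conc_all))
  resp <- if (design$noise$type == "proportional")
    clean_all * (1 + design$noise$cv * z)
  else clean_all + design$noise$sd * z
  out <- dose_response_dataset(drug_id, conc_all, resp, rep_all,
                               response_units = units)
  out <- apply_elisa_window(out, design$elisa_window)
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  out
}

#' Ground-truth parameters of the four-drug synthetic panel
#'
#' Encodes the qualitative between-drug structure reported for the four
#' best-known biphasic gamma-secretase drugs: LY-411,575 has the lowest
#' activation (EC50) and inhibition (IC50) midpoints, the highest Hill
#' coefficients and the highest maximal activation; DAPT has the highest
#' midpoints with the lowest Hill coefficients and the lowest maximal
#' activation; semagacestat sits between them; avagacestat matches
#' LY-411,575's midpoints but with lower Hill coefficients. The inhibition
#' Hill coefficient exceeds the activation one for every drug, and the
#' baseline `PA` is identical across drugs (one cell batch split four ways).
#' Responses are in pM of Abeta 1-40 within the emulated ELISA window.
#'
#' @return named list of four [biphasic_params] records
#'   (`LY-411575`, `avagacestat`, `semagacestat`, `DAPT`).
#' @export
four_drug_truth <- function() {
  list(
    "LY-411575"   = biphasic_params(25, 110, 8, -9.5, -8.3, 1.7, 2.8),
    "avagacestat" = biphasic_params(25, 70, 8, -9.3, -8.1, 1.0, 1.5),
    "semagacestat" = biphasic_params(25, 85, 8, -7.5, -6.3, 1.3, 2.0),
    "DAPT"        = biphasic_params(25, 60, 8, -6.8, -5.6, 1.0, 1.5))
}

#' Simulate the four-drug synthetic panel
#'
#' One dataset per drug from [four_drug_truth()] under a shared design; each
#' drug draws its noise from a distinct seed derived from `seed`, and every
#' dataset carries its truth record so the panel orderings are assertable.
#'
#' @param seed master seed.
#' @param design an [assay_design]; its own seed field is overridden per drug.
#' @return named list of four [dose_response_dataset]s.
#' @export
four_drug_panel <- function(seed = 1L, design = assay_design()) {
  truths <- four_drug_truth()
  out <- vector("list", length(truths))
  names(out) <- names(truths)
  for (k in seq_along(truths)) {
    d <- design
    d$seed <- derive_seed(seed, k)
    out[[k]] <- simulate_assay(truths[[k]], d, drug_id = names(truths)[k])
  }
  out
}

# ideal alpha-helical C-alpha backbone: 1.5 A rise, 100 deg turn, 2.3 A radius
.backbone_curve <- function(n_residues) {
  t <- seq_len(n_residues)
  ang <- t * 100 * pi / 180
  cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * t)
}

.random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Simulate a coordinate trajectory with known mobility structure
#'
#' Builds a pseudo C-alpha-per-residue chain on an ideal helical backbone and
#' displaces every residue independently in each frame with isotropic
#' Gaussian noise of known per-residue amplitude `sigma_i` (per coordinate,
#' Angstrom) -- so the expected RMSF of residue i is `sigma_i * sqrt(3)`.
#' With `rigid_motion = TRUE` every frame additionally receives a random
#' global rotation and translation, which superposition-based analyses must
#' remove. Coordinates are rounded to 0.001 A (PDB fixed-width precision) so
#' written files round-trip exactly.
#'
#' @param n_residues number of residues (one CA pseudo-atom each).
#' @param n_frames number of frames (>= 2).
#' @param amplitude_profile per-residue displacement sigma in Angstrom
#'   (scalar recycled, or length `n_residues`); >= 0.
#' @param rigid_motion apply a random global rotation + translation per frame.
#' @param seed integer seed.
#' @return a [trajectory] object.
#' @export
simulate_trajectory <- function(n_residues, n_frames, amplitude_profile = 0.5,
                                rigid_motion = FALSE, seed = 1L) {
  if (n_frames < 2) stop("a trajectory needs >= 2 frames")
  sigma <- rep_len(amplitude_profile, n_residues)
  if (any(sigma < 0)) stop("amplitude_profile must be >= 0")
  base <- .backbone_curve(n_residues)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  coords <- array(NA_real_, c(n_frames, n_residues, 3))
  for (f in seq_len(n_frames)) {
    disp <- matrix(stats::rnorm(n_residues * 3), n_residues, 3) * sigma
    fr <- base + disp
    if (rigid_motion)
      fr <- fr %*% t(.random_rotation()) +
        matrix(stats::runif(3, -20, 20), n_residues, 3, byrow = TRUE)
    coords[f, , ] <- fr
  }
  coords <- round(coords, 3)
  atoms <- data.frame(eleno = seq_len(n_residues), elety = "CA",
                      resid = "ALA", chain = "A",
                      resno = seq_len(n_residues),
                      stringsAsFactors = FALSE)
  traj <- trajectory(coords, atoms)
  attr(traj, "amplitude_profile") <- sigma
  traj
}
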