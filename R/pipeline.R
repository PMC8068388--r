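#' Derive a stage seed from a master seed
#'
#' Deterministic, collision-avoiding seed derivation so that every stochastic
#' stage of a pipeline run draws from its own stream while the whole run is
#' reproducible from one master seed. Kept below 2^31 - 1.
#'
#' @param master master integer seed.
#' @param stage small integer stage index (1, 2, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 48271 + stage * 100003) %%
               (.Machine$integer.max - 1)) + 1L
}

# 32-bit polynomial rolling hash of a string; provenance fingerprint only
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 2^31
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

.config_hash <- function(config) {
  .fnv1a(paste(utils::capture.output(utils::str(config)), collapse = "\n"))
}

#' Default pipeline configuration
#'
#' One nested list drives every stage; all stochastic stages receive seeds
#' derived deterministically from the master seed via [derive_seed()].
#'
#' @param seed master integer seed.
#' @return a list of class `pipeline_config` with components `seed`,
#'   `design` ([assay_design]), `fit` ([fit_config]), `mechanism`
#'   (parameters + substrate for mechanism-generated curves), and
#'   `trajectory` (analysis options).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    design = assay_design(),
    fit = fit_config(seed = derive_seed(seed, 10L)),
    mechanism = list(
      params = mechanism_params(kcat = 1, Km = 1e-6, K_act = 1e-8,
                                alpha = 10, K_inh = 1e-6,
                                n_act = 1, n_inh = 2),
      S = 1e-7,
      dose_grid = c(0, 10^seq(-10, -4, length.out = 24))),
    trajectory = list(selection = NULL, salt_bridge_cutoff = 4.0,
                      delta_threshold = 0.1)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly through [read_pipeline_config()]:
#' re-reading a written configuration reproduces the same object.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- default_config(seed = x$seed)
  cfg$design <- do.call(assay_design, x$design)
  cfg$fit <- do.call(fit_config, x$fit)
  cfg$mechanism <- list(params = do.call(mechanism_params, x$mechanism$params),
                        S = x$mechanism$S,
                        dose_grid = as.numeric(x$mechanism$dose_grid))
  cfg$trajectory <- x$trajectory
  cfg
}

.provenance <- function(config, stage) {
  c(sprintf("# biphasicdr %s", stage),
    sprintf("# seed=%d config=%s", config$seed, .config_hash(config)))
}

.say <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

#' Simulate the four-drug panel to disk
#'
#' Writes one CSV per synthetic drug (with provenance header) and a JSON
#' truth sidecar per dataset, plus a run manifest. Identical master seeds
#' produce byte-identical files.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param outdir output directory, created if needed.
#' @return named list of CSV paths, invisibly.
#' @export
run_simulate <- function(config = default_config(), outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  panel <- four_drug_panel(seed = config$seed, design = config$design)
  hdr <- .provenance(config, "simulate")
  paths <- character(0)
  for (nm in names(panel)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", nm)
    csv <- file.path(outdir, paste0("dataset_", slug, ".csv"))
    write_dose_response(panel[[nm]], csv, header = hdr)
    params_to_json(attr(panel[[nm]], "truth"),
                   file.path(outdir, paste0("truth_", slug, ".json")))
    paths[nm] <- csv
    .say("simulate", "%s -> %s (%d rows)", nm, csv, nrow(panel[[nm]]))
  }
  manifest <- list(stage = "simulate", seed = config$seed,
                   config = .config_hash(config),
                   files = as.list(unname(paths)))
  jsonlite::write_json(manifest, file.path(outdir, "simulate_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

.fit_result_json <- function(fit, path) {
  x <- list(drug = fit$drug,
            params = unclass(fit$params),
            se = as.list(fit$se),
            rss = fit$rss, r_squared = fit$r_squared,
            converged = fit$converged,
            n_starts_used = fit$n_starts_used,
            selected_model = fit$selected_model,
            model_table = fit$model_table,
            n_obs = fit$n_obs)
  if (!is.null(fit$ci))
    x$ci <- fit$ci
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Fit dose-response CSV files and tabulate the results
#'
#' Reads each dataset, runs [fit_biphasic()], writes a per-drug JSON fit
#' result and one summary CSV mirroring the per-drug parameter table (EC50,
#' activation Hill, max activity, IC50, inhibition Hill, baseline, selected
#' model). Per-drug failures are reported and collected rather than aborting
#' the run; any failure is signaled at the end.
#'
#' @param config a `pipeline_config`.
#' @param dataset_paths character vector of CSV paths (e.g. from
#'   [run_simulate()]).
#' @param outdir output directory.
#' @return the summary `data.frame`, invisibly.
#' @export
run_fit <- function(config, dataset_paths, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  missing <- dataset_paths[!file.exists(dataset_paths)]
  if (length(missing)) stop("missing dataset file(s): ",
                            paste(missing, collapse = ", "))
  fits <- list(); failures <- character(0)
  for (p in dataset_paths) {
    data <- read_dose_response(p)
    f <- tryCatch(fit_biphasic(data, config$fit), error = function(e) e)
    if (inherits(f, "error")) {
      .say("fit", "FAILED %s: %s", p, conditionMessage(f))
      failures <- c(failures, p)
      next
    }
    .say("fit", "%s: model=%s RSS=%.4g", f$drug, f$selected_model, f$rss)
    fits[[f$drug]] <- f
    slug <- gsub("[^A-Za-z0-9]+", "_", f$drug)
    .fit_result_json(f, file.path(outdir, paste0("fit_", slug, ".json")))
  }
  summary <- if (length(fits)) fit_summary_table(fits) else NULL
  if (!is.null(summary)) {
    csv <- file.path(outdir, "fit_summary.csv")
    con <- file(csv, "wt"); on.exit(close(con))
    writeLines(.provenance(config, "fit"), con)
    writeLines(paste(names(summary), collapse = ","), con)
    writeLines(apply(summary, 1, function(r)
      paste(vapply(r, function(v) {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) as.character(v) else sprintf("%.10g", num)
      }, character(1)), collapse = ",")), con)
    .say("fit", "summary -> %s", csv)
  }
  if (length(failures))
    stop("fit failed for ", length(failures), " dataset(s): ",
         paste(failures, collapse = ", "))
  invisible(summary)
}

.write_table_csv <- function(df, path, header) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df))
    writeLines(apply(df, 1, function(r)
      paste(vapply(seq_along(r), function(i) {
        num <- suppressWarnings(as.numeric(r[[i]]))
        if (is.na(num)) as.character(r[[i]]) else sprintf("%.10g", num)
      }, character(1)), collapse = ",")), con)
  invisible(path)
}

#' Run the trajectory mobility analyses
#'
#' RMSF profile (with mobility classes), RMSD time series, PCA eigenvalue
#' spectrum and per-residue first-mode amplitudes, and salt-bridge occupancy
#' for one trajectory file, each written as a provenance-headed CSV. When a
#' second trajectory is given, the per-residue RMSF decrease
#' (first minus second) and its contiguous decrease regions are written too.
#'
#' @param config a `pipeline_config`.
#' @param traj_path path to a multi-model PDB or XYZ trajectory.
#' @param outdir output directory.
#' @param compare_path optional second trajectory for the RMSF comparison.
#' @return named list of output paths, invisibly.
#' @export
run_traj <- function(config, traj_path, outdir = ".", compare_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance(config, "traj")
  traj <- tryCatch(read_trajectory(traj_path), error = function(e)
    stop("failed to parse trajectory '", traj_path, "': ",
         conditionMessage(e)))
  sel <- config$trajectory$selection
  prof <- rmsf_profile(traj, sel)
  rmsd <- rmsd_series(traj, 1L, sel)
  pca <- pca_modes(traj, sel)
  bridges <- suppressWarnings(
    salt_bridge_occupancy(traj, config$trajectory$salt_bridge_cutoff))
  out <- c(rmsf = file.path(outdir, "traj_rmsf.csv"),
           rmsd = file.path(outdir, "traj_rmsd.csv"),
           pca = file.path(outdir, "traj_pca.csv"),
           salt_bridges = file.path(outdir, "traj_salt_bridges.csv"))
  .write_table_csv(as.data.frame(prof), out["rmsf"], hdr)
  .write_table_csv(data.frame(frame = seq_along(rmsd), rmsd = rmsd),
                   out["rmsd"], hdr)
  .write_table_csv(data.frame(resno = pca$resno,
                              mode1_amplitude = pca$amplitudes[, 1],
                              stringsAsFactors = FALSE),
                   out["pca"], c(hdr, sprintf("# eigenvalue_sum=%.10g",
                                              sum(pca$values))))
  .write_table_csv(bridges, out["salt_bridges"], hdr)
  if (!is.null(compare_path)) {
    traj2 <- read_trajectory(compare_path)
    dr <- delta_rmsf(prof, rmsf_profile(traj2, sel),
                     config$trajectory$delta_threshold)
    out["delta_rmsf"] <- file.path(outdir, "traj_delta_rmsf.csv")
    out["delta_regions"] <- file.path(outdir, "traj_delta_regions.csv")
    .write_table_csv(dr$delta, out["delta_rmsf"], hdr)
    .write_table_csv(dr$decrease_regions, out["delta_regions"], hdr)
  }
  for (p in out) .say("traj", "-> %s", p)
  invisible(as.list(out))
}
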