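#' Construct a dose-response dataset
#'
#' A per-drug table of (concentration, response, replicate) rows with a
#' vehicle convention (`conc_M = 0`) and per-row assay-window censor flags.
#' This is the common currency between the synthetic-assay generator, the
#' fitting layer, and the pipeline CSV files.
#'
#' @param drug drug label (recycled to the number of rows).
#' @param conc_M drug concentrations in molar, >= 0; 0 encodes the DMSO
#'   vehicle.
#' @param response measured activity values.
#' @param replicate replicate labels (recycled).
#' @param response_units unit label, e.g. `"pM"` or `"% of vehicle"`.
#' @param censored optional per-row flag, one of `"within"`, `"below"`,
#'   `"above"`; defaults to `"within"` everywhere.
#' @return a `data.frame` of class `dose_response_dataset` with attribute
#'   `response_units`.
#' @export
dose_response_dataset <- function(drug, conc_M, response, replicate = 1L,
                                  response_units = "response",
                                  censored = NULL) {
  n <- length(conc_M)
  if (length(response) != n)
    stop("'conc_M' and 'response' must have equal length")
  if (any(!is.finite(conc_M)) || any(conc_M < 0))
    stop("concentrations must be finite and >= 0 molar")
  if (is.null(censored)) censored <- rep("within", n)
  censored <- match.arg(censored, c("within", "below", "above"),
                        several.ok = TRUE)
  if (length(censored) == 1L) censored <- rep(censored, n)
  out <- data.frame(drug = rep_len(as.character(drug), n),
                    conc_M = as.numeric(conc_M),
                    response = as.numeric(response),
                    replicate = rep_len(replicate, n),
                    censored = censored,
                    stringsAsFactors = FALSE)
  attr(out, "response_units") <- response_units
  class(out) <- c("dose_response_dataset", "data.frame")
  out
}

#' Flag rows outside an ELISA linear window
#'
#' Sandwich ELISA readouts are linear only within a stated analyte range
#' (6-125 pM for the Abeta 1-40 kit emulated by the synthetic generator).
#' Rows outside the window are flagged -- never dropped; exclusion is an
#' explicit fitting choice (`fit_config(censored = ...)`).
#'
#' @param data a [dose_response_dataset].
#' @param window numeric length-2 `c(low, high)` in the dataset's response
#'   units.
#' @return the dataset with its `censored` column updated.
#' @export
apply_elisa_window <- function(data, window = c(6, 125)) {
  stopifnot(inherits(data, "dose_response_dataset"), length(window) == 2)
  if (window[1] >= window[2]) stop("window low must be < high")
  cens <- rep("within", nrow(data))
  cens[data$response < window[1]] <- "below"
  cens[data$response > window[2]] <- "above"
  data$censored <- cens
  data
}

#' Read a dose-response dataset from CSV
#'
#' Expects header columns `drug`, `conc_M`, `response`, `replicate` and an
#' optional `censored` column; lines starting with `#` (provenance headers
#' written by the pipeline) are skipped. Vehicle rows are encoded as
#' `conc_M = 0`.
#'
#' @param path CSV file path.
#' @param response_units unit label attached to the result.
#' @return a [dose_response_dataset].
#' @export
read_dose_response <- function(path, response_units = "response") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("drug", "conc_M", "response", "replicate")
  if (!all(need %in% names(df)))
    stop("CSV must have columns drug, conc_M, response, replicate (got: ",
         paste(names(df), collapse = ", "), ")")
  dose_response_dataset(df$drug, df$conc_M, df$response, df$replicate,
                        response_units = response_units,
                        censored = if ("censored" %in% names(df)) df$censored)
}

#' Write a dose-response dataset to CSV
#'
#' Numbers are formatted with `%.10g` so that identical inputs produce
#' byte-identical files (the pipeline's end-to-end determinism contract).
#'
#' @param data a [dose_response_dataset].
#' @param path output file path.
#' @param header optional character vector of `# `-prefixed provenance lines
#'   to place above the column header.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path, header = NULL) {
  stopifnot(inherits(data, "dose_response_dataset"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines("drug,conc_M,response,replicate,censored", con)
  writeLines(sprintf("%s,%.10g,%.10g,%s,%s",
                     data$drug, data$conc_M, data$response,
                     as.character(data$replicate), data$censored), con)
  invisible(path)
}

#' Construct a dose-response curve (concentration/response pair)
#'
#' Lightweight container used where a noiseless model curve -- rather than a
#' replicated dataset -- is passed around, e.g. between the enzyme-modifier
#' simulator and response-shape classification.
#'
#' @param conc concentrations in molar, non-negative and strictly increasing.
#' @param response activity values, same length.
#' @return a `data.frame` of class `dose_response_curve`.
#' @export
new_dose_response_curve <- function(conc, response) {
  if (length(conc) != length(response))
    stop("'conc' and 'response' must have equal length")
  if (any(conc < 0)) stop("negative concentrations are not allowed")
  if (is.unsorted(conc, strictly = TRUE))
    stop("'conc' must be strictly increasing")
  structure(data.frame(conc = conc, response = response),
            class = c("dose_response_curve", "data.frame"))
}
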