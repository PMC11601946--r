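# Plain-text interchange: the CSV dialects the analysis consumes and the
# simulated-dataset writer.

#' Read a minute-level gas-exchange trace
#'
#' CSV columns: `participant_id`, `chamber_id`, `minute`, `vo2_l_min`,
#' `vco2_l_min` and optionally `activity_pct`.
#'
#' @param path CSV path.
#' @return A tibble with the trace columns renamed to `vo2`/`vco2`.
#' @export
read_gas_trace <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "chamber_id", "minute", "vo2_l_min", "vco2_l_min")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    stop("trace file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(dplyr::rename(x, vo2 = "vo2_l_min", vco2 = "vco2_l_min"))
}

#' Read a long-format metabolite panel
#'
#' CSV columns: `participant_id`, `diet`, `timepoint` (`pre`/`post`),
#' `metabolite`, `abundance` and optionally `class`, `chamber_order`. Empty
#' abundances become `NA` (missing is explicit, never imputed).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_metabolite_panel <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("participant_id", "diet", "timepoint", "metabolite", "abundance")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    stop("panel file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(x$abundance) & x$abundance <= 0
  if (any(bad)) stop("raw abundances must be positive or missing", call. = FALSE)
  x
}

#' Write a complete simulated dataset to a directory
#'
#' Emits the CSV dialects consumed by the analysis modules — participants,
#' schedules, chamber-session summaries, the long metabolite panel,
#' pooled-QC replicates and NEFA — plus the simulation ground truth as JSON.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, name) {
    utils::write.csv(d, file.path(dir, name), row.names = FALSE, na = "")
  }
  w(sim$participants[, setdiff(names(sim$participants), "weight_series")],
    "participants.csv")
  w(sim$schedules, "schedules.csv")
  w(sim$sessions, "sessions.csv")
  w(sim$panel, "metabolite_panel.csv")
  w(sim$qc_replicates, "qc_replicates.csv")
  w(sim$nefa, "nefa.csv")
  truth <- sim$truth
  truth$metabolome$participant_intercepts <- NULL  # matrix; reproducible from the seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(dir)
}
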