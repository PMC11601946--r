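# Metabolite quality control: pooled-QC CV, 5-SD prechamber outlier removal,
# any-missingness exclusion, log2 transform and fold-change construction.
# The pipeline order is fixed: outliers -> missingness -> transform.

#' Pooled-QC coefficient of variation per metabolite
#'
#' CV computed on raw (not log-transformed) pooled-QC replicate abundances:
#' `100 * SD / mean` per metabolite, with the median and interquartile range
#' across metabolites summarized. Metabolites with fewer than two replicates
#' are flagged and carry no CV.
#'
#' @param qc_replicates Tibble with `metabolite` and raw `abundance` columns
#'   (one row per replicate).
#' @return List with `per_metabolite` (metabolite, `n`, `cv_pct`, `flag`)
#'   and `summary` (`median_cv`, `q25_cv`, `q75_cv`).
#' @export
pooled_qc_cv <- function(qc_replicates) {
  per <- qc_replicates |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      n = sum(!is.na(.data$abundance)),
      cv_pct = ifelse(.data$n >= 2,
                      100 * stats::sd(.data$abundance, na.rm = TRUE) /
                        mean(.data$abundance, na.rm = TRUE),
                      NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = ifelse(.data$n < 2, "too_few_replicates", NA_character_))
  qs <- stats::quantile(per$cv_pct, c(0.25, 0.5, 0.75), na.rm = TRUE)
  list(
    per_metabolite = per,
    summary = tibble::tibble(median_cv = qs[[2]], q25_cv = qs[[1]], q75_cv = qs[[3]])
  )
}

#' Remove extreme prechamber measurements
#'
#' Within each (diet, metabolite) group, prechamber values more than
#' `sd_limit` SDs from the group mean (SD computed with the candidate value
#' included) are set to missing. Groups with fewer than `min_group` usable
#' values, or zero SD, are never trimmed. Postchamber values are not
#' screened.
#'
#' @param panel Long metabolite panel (`participant_id`, `diet`,
#'   `timepoint`, `metabolite`, `abundance`).
#' @param sd_limit Z-score threshold (default 5).
#' @param min_group Minimum group size for trimming (default 3).
#' @return List with the trimmed `panel` and a `removals` log (one row per
#'   removed measurement, with its z-score).
#' @export
remove_outliers <- function(panel, sd_limit = 5, min_group = 3) {
  pre <- panel$timepoint == "pre"
  z <- rep(NA_real_, nrow(panel))
  grp <- interaction(panel$diet[pre], panel$metabolite[pre], drop = TRUE)
  x <- panel$abundance[pre]
  mu <- stats::ave(x, grp, FUN = function(v) mean(v, na.rm = TRUE))
  sdv <- stats::ave(x, grp, FUN = function(v) stats::sd(v, na.rm = TRUE))
  nv <- stats::ave(x, grp, FUN = function(v) sum(!is.na(v)))
  z[pre] <- ifelse(nv >= min_group & sdv > 0, (x - mu) / sdv, NA_real_)
  drop <- !is.na(z) & abs(z) > sd_limit
  removals <- panel[drop, c("participant_id", "diet", "metabolite", "abundance")]
  if (nrow(removals)) removals$z <- z[drop]
  else removals$z <- numeric(0)
  panel$abundance[drop] <- NA_real_
  list(panel = panel, removals = removals)
}

#' Exclude metabolites with any missingness
#'
#' A metabolite is retained only if it has zero missing abundances across
#' all rows (including values removed as outliers).
#'
#' @param panel Long metabolite panel.
#' @return List: `panel` restricted to retained metabolites, `retained`
#'   (character), `excluded` (tibble of metabolite and missing count).
#' @export
missingness_filter <- function(panel) {
  miss <- panel |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(n_missing = sum(is.na(.data$abundance)), .groups = "drop")
  excluded <- dplyr::filter(miss, .data$n_missing > 0)
  retained <- setdiff(miss$metabolite, excluded$metabolite)
  list(
    panel = dplyr::filter(panel, .data$metabolite %in% retained),
    retained = retained,
    excluded = excluded
  )
}

#' Per-session log2 fold changes
#'
#' `log2(post) - log2(pre)` per (participant, chamber, metabolite), with the
#' prechamber log2 level carried as a model covariate. All modeling happens
#' in log2 units.
#'
#' @param panel Complete long panel (pre and post rows for each session and
#'   metabolite).
#' @return Tibble with `log2fc` and `pre_log2` (plus `post_log2`).
#' @export
log2_fold_change <- function(panel) {
  keys <- intersect(c("participant_id", "diet", "chamber_order",
                      "metabolite", "class"), names(panel))
  wide <- tidyr::pivot_wider(panel[, c(keys, "timepoint", "abundance")],
                             names_from = "timepoint", values_from = "abundance")
  dplyr::mutate(wide,
                pre_log2 = log2(.data$pre),
                post_log2 = log2(.data$post),
                log2fc = .data$post_log2 - .data$pre_log2)
}

#' Run the full QC pipeline
#'
#' Fixed, idempotent order: prechamber outlier removal, any-missingness
#' exclusion, log2 fold-change construction; plus the pooled-QC CV summary
#' when replicates are supplied.
#'
#' @param panel Long metabolite panel.
#' @param qc_replicates Optional pooled-QC replicate table.
#' @inheritParams remove_outliers
#' @return List: `fold_changes`, filtered `panel`, and a `report` holding
#'   the CV summary, outlier log, excluded/retained metabolites and counts
#'   (retained + excluded = input metabolites).
#' @export
run_qc <- function(panel, qc_replicates = NULL, sd_limit = 5, min_group = 3) {
  n_input <- length(unique(panel$metabolite))
  out <- remove_outliers(panel, sd_limit = sd_limit, min_group = min_group)
  mf <- missingness_filter(out$panel)
  cv <- if (!is.null(qc_replicates)) pooled_qc_cv(qc_replicates) else NULL
  report <- list(
    n_metabolites_input = n_input,
    n_retained = length(mf$retained),
    n_excluded = nrow(mf$excluded),
    retained = mf$retained,
    excluded = mf$excluded,
    outliers_removed = out$removals,
    qc_cv = cv
  )
  list(fold_changes = log2_fold_change(mf$panel), panel = mf$panel,
       report = report)
}

#' Write a QC report to JSON (and optionally plain text)
#'
#' @param report The `report` element of [run_qc()].
#' @param json_path Output JSON path.
#' @param text_path Optional human-readable summary path.
#' @return Invisibly, the JSON path.
#' @export
write_qc_report <- function(report, json_path, text_path = NULL) {
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(text_path)) {
    lines <- c(
      sprintf("metabolites in: %d", report$n_metabolites_input),
      sprintf("retained: %d", report$n_retained),
      sprintf("excluded for missingness: %d", report$n_excluded),
      sprintf("outlier measurements removed: %d", nrow(report$outliers_removed)),
      if (!is.null(report$qc_cv)) {
        sprintf("pooled-QC CV median %.1f%% (IQR %.1f-%.1f%%)",
                report$qc_cv$summary$median_cv, report$qc_cv$summary$q25_cv,
                report$qc_cv$summary$q75_cv)
      }
    )
    writeLines(lines, text_path)
  }
  invisible(json_path)
}
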