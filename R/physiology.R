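# Metabolite-physiology association models: pooled mixed models across all
# chambers, per-diet stratified linear models, NEFA models, and the
# baseline-versus-change concordance summary.

# Assemble the per-metabolite modeling frame: fold changes joined to session
# outcomes and participant covariates.
physiology_model_data <- function(sessions, fold_changes, participants, outcome) {
  stopifnot(outcome %in% names(sessions))
  if ("chamber_order" %in% names(sessions)) {
    # the eucaloric calibration session is not an analysis chamber
    sessions <- sessions[!is.na(sessions$chamber_order), ]
  }
  if (anyDuplicated(sessions[, c("participant_id", "diet")])) {
    stop("duplicate sessions per participant and diet", call. = FALSE)
  }
  dat <- fold_changes |>
    dplyr::inner_join(
      dplyr::rename(sessions[, c("participant_id", "diet", outcome)],
                    outcome_value = dplyr::all_of(outcome)),
      by = c("participant_id", "diet")
    ) |>
    dplyr::inner_join(
      participants[, c("participant_id", "age", "sex", "race", "bmi")],
      by = "participant_id"
    )
  dat$diet <- stats::relevel(factor(dat$diet), ref = "EB")
  dat$race <- factor(dat$race)
  dat
}

# Extract the fold-change and prechamber-level coefficients from a fitted
# model's coefficient matrix.
extract_betas <- function(co, flag = NA_character_) {
  pcol <- grep("^Pr\\(", colnames(co), value = TRUE)[1]
  tibble::tibble(
    beta_foldchange = co["log2fc", "Estimate"],
    se_foldchange = co["log2fc", "Std. Error"],
    p_foldchange = co["log2fc", pcol],
    beta_prelevel = co["pre_log2", "Estimate"],
    se_prelevel = co["pre_log2", "Std. Error"],
    p_prelevel = co["pre_log2", pcol],
    flag = flag
  )
}

failed_betas <- function(flag) {
  tibble::tibble(beta_foldchange = NA_real_, se_foldchange = NA_real_,
                 p_foldchange = NA_real_, beta_prelevel = NA_real_,
                 se_prelevel = NA_real_, p_prelevel = NA_real_, flag = flag)
}

#' Pooled metabolite-physiology mixed models
#'
#' Per metabolite, across all chambers:
#' `outcome ~ log2fc + pre_log2 + diet + age + sex + race + bmi +
#' (1 | participant)`. Both the fold-change and the prechamber-level
#' coefficients are returned (log2 units, so a beta reads as outcome change
#' per doubling). Metabolites with zero fold-change variance are skipped
#' with a log flag; BH q-values are computed per outcome across metabolites
#' (toggleable).
#'
#' @param sessions Session tibble carrying the outcome column (e.g. `rq24`,
#'   `ee24`, `lipox_kcal`).
#' @param fold_changes Tibble from [log2_fold_change()].
#' @param participants Covariate tibble (`age`, `sex`, `race`, `bmi`).
#' @param outcome Name of the outcome column in `sessions`.
#' @param adjust Compute BH q-values across metabolites for this outcome?
#' @return An association table: `metabolite`, `outcome`, both betas with
#'   SEs and p-values, `q`, `stratum = "pooled"`, `model = "mixed"`, `flag`.
#' @export
pooled_physiology_model <- function(sessions, fold_changes, participants,
                                    outcome = "rq24", adjust = TRUE) {
  dat <- physiology_model_data(sessions, fold_changes, participants, outcome)
  fit_one <- function(d) {
    if (sum(!is.na(d$log2fc)) < 3 || stats::sd(d$log2fc, na.rm = TRUE) == 0) {
      return(failed_betas("zero_variance_skipped"))
    }
    tryCatch({
      fit <- lmerTest::lmer(
        outcome_value ~ log2fc + pre_log2 + diet + age + sex + race + bmi +
          (1 | participant_id),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore")
      )
      extract_betas(stats::coef(summary(fit)),
                    flag = ifelse(lme4::isSingular(fit), "singular", NA_character_))
    }, error = function(e) failed_betas("failed"))
  }
  out <- dat |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(outcome = outcome, stratum = "pooled", model = "mixed")
  out$q <- if (adjust) bh_adjust(out$p_foldchange) else NA_real_
  out
}

#' Per-diet stratified linear models
#'
#' The pooled model's fixed-effect structure restricted to a single dietary
#' chamber (one session per participant, so no random effect):
#' `outcome ~ log2fc + pre_log2 + age + sex + race + bmi`.
#'
#' @inheritParams pooled_physiology_model
#' @param diet The single chamber condition to model.
#' @return An association table with `stratum = diet`, `model = "linear"`.
#' @export
stratified_diet_model <- function(sessions, fold_changes, participants,
                                  diet, outcome = "rq24", adjust = TRUE) {
  dat <- physiology_model_data(sessions, fold_changes, participants, outcome)
  dat <- dat[as.character(dat$diet) == diet, ]
  if (nrow(dat) == 0) stop("no sessions for diet ", diet, call. = FALSE)
  per_part <- table(dat$participant_id[dat$metabolite == dat$metabolite[1]])
  if (any(per_part > 1)) {
    stop("duplicate sessions per participant within diet ", diet, call. = FALSE)
  }
  n_part <- length(per_part)
  n_covar <- 4 + nlevels(droplevels(dat$race)) - 1 + 2  # fc, pre, age, bmi, race, sex, intercept
  if (n_part <= n_covar) {
    stop(sprintf("only %d sessions for diet %s: fewer than the %d model terms",
                 n_part, diet, n_covar), call. = FALSE)
  }
  fit_one <- function(d) {
    if (sum(!is.na(d$log2fc)) < 3 || stats::sd(d$log2fc, na.rm = TRUE) == 0) {
      return(failed_betas("zero_variance_skipped"))
    }
    tryCatch({
      fit <- stats::lm(outcome_value ~ log2fc + pre_log2 + age + sex + race + bmi,
                       data = d)
      extract_betas(stats::coef(summary(fit)))
    }, error = function(e) failed_betas("failed"))
  }
  out <- dat |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(outcome = outcome, stratum = diet, model = "linear")
  out$q <- if (adjust) bh_adjust(out$p_foldchange) else NA_real_
  out
}

#' NEFA association mixed models
#'
#' Per metabolite: `nefa_post ~ log2fc + pre_log2 + nefa_pre + diet + age +
#' sex + race + bmi + (1 | participant)`. Sessions missing the prechamber
#' NEFA are dropped and logged.
#'
#' @param nefa Tibble `participant_id`, `diet`, `nefa_pre`, `nefa_post`.
#' @inheritParams pooled_physiology_model
#' @return List: `table` (association table, `outcome = "NEFA_post"`) and
#'   `dropped_sessions` (sessions lacking prechamber NEFA).
#' @export
nefa_model <- function(nefa, fold_changes, participants, adjust = TRUE) {
  dropped <- nefa[is.na(nefa$nefa_pre), c("participant_id", "diet")]
  nefa <- nefa[!is.na(nefa$nefa_pre), ]
  dat <- fold_changes |>
    dplyr::inner_join(nefa, by = c("participant_id", "diet")) |>
    dplyr::inner_join(participants[, c("participant_id", "age", "sex", "race", "bmi")],
                      by = "participant_id")
  dat$diet <- stats::relevel(factor(dat$diet), ref = "EB")
  fit_one <- function(d) {
    if (sum(!is.na(d$log2fc)) < 3 || stats::sd(d$log2fc, na.rm = TRUE) == 0) {
      return(failed_betas("zero_variance_skipped"))
    }
    tryCatch({
      fit <- lmerTest::lmer(
        nefa_post ~ log2fc + pre_log2 + nefa_pre + diet + age + sex + race +
          bmi + (1 | participant_id),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore")
      )
      extract_betas(stats::coef(summary(fit)),
                    flag = ifelse(lme4::isSingular(fit), "singular", NA_character_))
    }, error = function(e) failed_betas("failed"))
  }
  out <- dat |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(outcome = "NEFA_post", stratum = "pooled", model = "mixed")
  out$q <- if (adjust) bh_adjust(out$p_foldchange) else NA_real_
  list(table = out, dropped_sessions = dropped)
}

#' Concordance of baseline and change coefficients
#'
#' Spearman correlation between the prechamber-level betas and the
#' fold-change betas for one outcome — a summary of whether metabolites
#' whose baseline level predicts a physiologic trait shift in the same
#' direction during the chamber.
#'
#' @param assoc Either an association table carrying `beta_prelevel` and
#'   `beta_foldchange`, or a numeric vector of baseline betas.
#' @param beta_foldchange Numeric vector of change betas (when `assoc` is a
#'   vector); must align with `assoc` metabolite-by-metabolite.
#' @return Spearman's rho.
#' @export
baseline_change_concordance <- function(assoc, beta_foldchange = NULL) {
  if (is.data.frame(assoc)) {
    pre <- assoc$beta_prelevel
    fc <- assoc$beta_foldchange
  } else {
    pre <- assoc
    fc <- beta_foldchange
  }
  stopifnot(length(pre) == length(fc))
  stats::cor(pre, fc, method = "spearman", use = "pairwise.complete.obs")
}
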