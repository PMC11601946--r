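# Per-chamber pre/post tests with BH FDR, crossover mixed models with a
# chamber-order term, and cross-diet pattern summaries.

#' Paired pre/post tests per metabolite and chamber
#'
#' Two-tailed paired t tests on log2 levels — equivalently, a one-sample t
#' test of the mean log2 fold change against zero — with Benjamini-Hochberg
#' q-values computed strictly within each dietary chamber's metabolite
#' family. Metabolites with fewer than `min_pairs` complete pairs are
#' skipped (flag `"too_few_pairs"`, excluded from the BH family); zero
#' variance pairs are degenerate and flagged.
#'
#' @param fold_changes Tibble from [log2_fold_change()] (needs `diet`,
#'   `metabolite`, `log2fc`).
#' @param min_pairs Minimum complete pairs per metabolite (default 3).
#' @return An effect table: `metabolite`, `diet`, `estimate` (mean log2FC),
#'   `se`, `statistic`, `df`, `p`, `q`, `n_pairs`, `model`, `flag`.
#' @export
paired_tests <- function(fold_changes, min_pairs = 3) {
  out <- fold_changes |>
    dplyr::group_by(.data$diet, .data$metabolite) |>
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$log2fc)),
      estimate = mean(.data$log2fc, na.rm = TRUE),
      sd_fc = stats::sd(.data$log2fc, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flag = dplyr::case_when(
        .data$n_pairs < min_pairs ~ "too_few_pairs",
        .data$sd_fc == 0 ~ "zero_variance",
        TRUE ~ NA_character_
      ),
      se = ifelse(is.na(.data$flag), .data$sd_fc / sqrt(.data$n_pairs), NA_real_),
      statistic = .data$estimate / .data$se,
      df = .data$n_pairs - 1,
      p = 2 * stats::pt(-abs(.data$statistic), .data$df),
      model = "paired_t"
    ) |>
    dplyr::group_by(.data$diet) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::select("metabolite", "diet", "estimate", "se", "statistic", "df",
                  "p", "q", "n_pairs", "model", "flag")
  out
}

# Benjamini-Hochberg step-up within one family, preserving NAs.
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Crossover mixed model for diet effects on the metabolome
#'
#' Per metabolite, fits
#' `post_log2 ~ pre_log2 + diet + chamber_order + (1 | participant)` with
#' the energy-balance chamber as the diet referent and chamber order coded
#' numerically (EB is order 1 for all participants) or categorically.
#' Returns the diet-contrast estimates versus EB with Satterthwaite p
#' values; non-converging metabolites are reported with flag `"failed"`,
#' never silently dropped, and singular fits (zero estimated participant
#' variance) are flagged but kept.
#'
#' @param fold_changes Tibble from [log2_fold_change()] including
#'   `chamber_order` (or joinable via `schedules`).
#' @param schedules Optional schedule tibble supplying `chamber_order` by
#'   (`participant_id`, `diet`).
#' @param order_coding `"numeric"` (default) or `"categorical"`.
#' @return An effect table with one row per metabolite x non-EB diet plus
#'   an EB referent row (estimate exactly 0), columns as in
#'   [paired_tests()] with `model = "mixed"`.
#' @export
crossover_mixed_model <- function(fold_changes, schedules = NULL,
                                  order_coding = c("numeric", "categorical")) {
  order_coding <- match.arg(order_coding)
  dat <- fold_changes
  if (!"chamber_order" %in% names(dat)) {
    stopifnot(!is.null(schedules))
    dat <- dplyr::left_join(
      dat, schedules[, c("participant_id", "diet", "chamber_order")],
      by = c("participant_id", "diet")
    )
  }
  dat <- dat[!is.na(dat$chamber_order), ]
  dat$diet <- stats::relevel(factor(dat$diet), ref = "EB")
  dat$order_term <- if (order_coding == "numeric") as.numeric(dat$chamber_order)
  else factor(dat$chamber_order)

  fit_one <- function(d) {
    res <- tryCatch({
      fit <- lmerTest::lmer(
        post_log2 ~ pre_log2 + diet + order_term + (1 | participant_id),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore")
      )
      co <- stats::coef(summary(fit))
      rows <- grep("^diet", rownames(co))
      tibble::tibble(
        diet = sub("^diet", "", rownames(co)[rows]),
        estimate = unname(co[rows, "Estimate"]),
        se = unname(co[rows, "Std. Error"]),
        statistic = unname(co[rows, "t value"]),
        df = unname(co[rows, "df"]),
        p = unname(co[rows, "Pr(>|t|)"]),
        flag = ifelse(lme4::isSingular(fit), "singular", NA_character_)
      )
    }, error = function(e) {
      tibble::tibble(diet = setdiff(levels(d$diet), "EB"),
                     estimate = NA_real_, se = NA_real_, statistic = NA_real_,
                     df = NA_real_, p = NA_real_, flag = "failed")
    })
    ref <- tibble::tibble(diet = "EB", estimate = 0, se = NA_real_,
                          statistic = NA_real_, df = NA_real_, p = NA_real_,
                          flag = "referent")
    dplyr::bind_rows(ref, res)
  }

  dat |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(model = "mixed") |>
    dplyr::select("metabolite", "diet", "estimate", "se", "statistic", "df",
                  "p", "model", "flag")
}

#' Significant-metabolite counts by class, diet and direction
#'
#' Counts metabolites reaching `q < q_threshold` in an effect table, split
#' by metabolite class, diet and sign of the estimate; zero cells are kept.
#'
#' @param effects An effect table with `q` computed.
#' @param class_map Tibble `metabolite`, `class`.
#' @param q_threshold FDR threshold (default 0.05).
#' @return Tibble `class`, `diet`, `direction` (`up`/`down`), `n`.
#' @export
class_summary <- function(effects, class_map, q_threshold = 0.05) {
  effects |>
    dplyr::inner_join(class_map, by = "metabolite") |>
    dplyr::filter(!is.na(.data$q), .data$q < q_threshold, .data$estimate != 0) |>
    dplyr::mutate(direction = dplyr::if_else(.data$estimate > 0, "up", "down")) |>
    dplyr::count(.data$class, .data$diet, .data$direction, name = "n") |>
    tidyr::complete(
      class = unique(class_map$class),
      diet = unique(effects$diet),
      direction = c("up", "down"),
      fill = list(n = 0L)
    )
}

#' Mean log2 fold-change pattern matrix
#'
#' @param fold_changes Tibble from [log2_fold_change()].
#' @return A diets x metabolites matrix of mean log2 fold changes.
#' @export
diet_pattern_matrix <- function(fold_changes) {
  wide <- fold_changes |>
    dplyr::group_by(.data$diet, .data$metabolite) |>
    dplyr::summarise(m = mean(.data$log2fc, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "m")
  out <- as.matrix(wide[, -1])
  rownames(out) <- wide$diet
  out
}

#' Pairwise Spearman correlation of diet response patterns
#'
#' Rank correlation between the mean log2 fold-change vectors of each pair
#' of diets, quantifying how similar two chambers' metabolome responses are.
#'
#' @param pattern A diets x metabolites matrix ([diet_pattern_matrix()])
#'   with at least 10 shared metabolites.
#' @return A symmetric diets x diets matrix of Spearman's rho (diagonal 1).
#' @export
diet_pattern_correlation <- function(pattern) {
  if (ncol(pattern) < 10) {
    stop("need at least 10 shared metabolites", call. = FALSE)
  }
  stats::cor(t(pattern), method = "spearman", use = "pairwise.complete.obs")
}
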