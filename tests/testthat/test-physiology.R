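# Builds a small direct dataset with a known metabolite-outcome coupling:
# outcome = beta * log2fc + participant effect + noise.
make_physio_data <- function(n, beta, participant_sd = 0.1, residual_sd = 0.1,
                             n_met = 3) {
  diets <- diet_library()$name
  d <- tidyr::expand_grid(participant_id = sprintf("P%03d", seq_len(n)),
                          diet = diets)
  participants <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = round(stats::runif(n, 20, 60)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    race = sample(c("groupA", "groupB"), n, replace = TRUE),
    bmi = stats::rnorm(n, 26, 3)
  )
  u <- stats::setNames(stats::rnorm(n, 0, participant_sd),
                       participants$participant_id)
  fc <- tidyr::expand_grid(d, metabolite = sprintf("M%d", seq_len(n_met)))
  fc$pre_log2 <- stats::rnorm(nrow(fc), 14, 0.4)
  fc$log2fc <- stats::rnorm(nrow(fc), 0, 0.5)
  target <- fc$metabolite == "M1"
  outcome <- fc[target, c("participant_id", "diet")]
  outcome$rq24 <- 0.85 + beta * fc$log2fc[target] +
    u[outcome$participant_id] + stats::rnorm(nrow(outcome), 0, residual_sd)
  list(sessions = outcome, fold_changes = fc, participants = participants)
}

test_that("the pooled mixed model recovers a known fold-change coupling", {
  set.seed(51)
  dat <- make_physio_data(80, beta = 0.3)
  res <- pooled_physiology_model(dat$sessions, dat$fold_changes,
                                 dat$participants, outcome = "rq24")
  row <- res[res$metabolite == "M1", ]
  expect_lt(abs(row$beta_foldchange - 0.3), 2.5 * row$se_foldchange)
  expect_lt(row$p_foldchange, 1e-6)
  # non-coupled metabolites are near null
  expect_gt(min(res$p_foldchange[res$metabolite != "M1"]), 0.001)
})

test_that("the pooled mixed model reduces to OLS without participant variance", {
  set.seed(52)
  dat <- make_physio_data(50, beta = 0.2, participant_sd = 0, n_met = 1)
  res <- pooled_physiology_model(dat$sessions, dat$fold_changes,
                                 dat$participants, outcome = "rq24")
  d <- dplyr::inner_join(dat$fold_changes, dat$sessions,
                         by = c("participant_id", "diet"))
  d <- dplyr::inner_join(d, dat$participants, by = "participant_id")
  d$diet <- stats::relevel(factor(d$diet), "EB")
  ref <- stats::lm(rq24 ~ log2fc + pre_log2 + diet + age + sex + race + bmi,
                   data = d)
  expect_equal(res$beta_foldchange, unname(stats::coef(ref)["log2fc"]),
               tolerance = 1e-4)
  expect_equal(res$beta_prelevel, unname(stats::coef(ref)["pre_log2"]),
               tolerance = 1e-4)
})

test_that("zero-variance metabolites are skipped with a log flag", {
  set.seed(53)
  dat <- make_physio_data(20, beta = 0)
  dat$fold_changes$log2fc[dat$fold_changes$metabolite == "M2"] <- 0.5
  res <- pooled_physiology_model(dat$sessions, dat$fold_changes,
                                 dat$participants, outcome = "rq24")
  expect_equal(res$flag[res$metabolite == "M2"], "zero_variance_skipped")
  expect_true(is.na(res$beta_foldchange[res$metabolite == "M2"]))
  expect_equal(nrow(res), 3)  # skipped metabolites stay in the table
})

test_that("stratified models match pooled estimates under homogeneous effects", {
  set.seed(54)
  dat <- make_physio_data(60, beta = 0.3, n_met = 1)
  pooled <- pooled_physiology_model(dat$sessions, dat$fold_changes,
                                    dat$participants, outcome = "rq24")
  strat <- stratified_diet_model(dat$sessions, dat$fold_changes,
                                 dat$participants, diet = "FAST",
                                 outcome = "rq24")
  expect_equal(strat$model, "linear")
  expect_equal(strat$stratum, "FAST")
  expect_lt(abs(strat$beta_foldchange - pooled$beta_foldchange),
            2 * strat$se_foldchange)
})

test_that("stratified models refuse duplicated or underdetermined designs", {
  set.seed(55)
  dat <- make_physio_data(20, beta = 0, n_met = 1)
  dup <- dat
  extra <- dup$fold_changes[dup$fold_changes$diet == "FAST", ][1, ]
  dup$fold_changes <- rbind(dup$fold_changes, extra)
  dup$sessions <- rbind(dup$sessions, dat$sessions[dat$sessions$diet == "FAST", ][1, ])
  expect_error(stratified_diet_model(dup$sessions, dup$fold_changes,
                                     dup$participants, diet = "FAST",
                                     outcome = "rq24"),
               "duplicate")
  small <- make_physio_data(6, beta = 0, n_met = 1)
  expect_error(stratified_diet_model(small$sessions, small$fold_changes,
                                     small$participants, diet = "FAST",
                                     outcome = "rq24"),
               "fewer than")
})

test_that("NEFA models drop sessions missing prechamber NEFA and log them", {
  set.seed(56)
  dat <- make_physio_data(30, beta = 0, n_met = 2)
  nefa <- dat$sessions[, c("participant_id", "diet")]
  nefa$nefa_pre <- stats::rnorm(nrow(nefa), 0.5, 0.05)
  nefa$nefa_post <- nefa$nefa_pre + stats::rnorm(nrow(nefa), 0, 0.05)
  nefa$nefa_pre[1:3] <- NA
  res <- nefa_model(nefa, dat$fold_changes, dat$participants)
  expect_equal(nrow(res$dropped_sessions), 3)
  expect_equal(res$table$outcome, rep("NEFA_post", 2))
  # null coupling: betas near zero
  expect_lt(max(abs(res$table$beta_foldchange)), 0.05)
})

test_that("acylcarnitine excursions map onto substrate oxidation physiology", {
  acyl <- class_members("acylcarnitine")
  rq <- default_pooled("rq24")
  lip <- default_pooled("lipox_kcal")
  expect_lt(mean(rq$beta_foldchange[rq$metabolite %in% acyl], na.rm = TRUE), 0)
  expect_gt(mean(lip$beta_foldchange[lip$metabolite %in% acyl], na.rm = TRUE), 0)
  # and the acylcarnitine-NEFA coupling is positive on average
  sim <- default_sim()
  nefa <- nefa_model(sim$nefa, default_qc()$fold_changes, sim$participants)
  expect_gt(mean(nefa$table$beta_foldchange[nefa$table$metabolite %in% acyl],
                 na.rm = TRUE), 0)
})

test_that("association tables carry one row per metabolite and stratum", {
  res <- default_pooled("rq24")
  expect_equal(anyDuplicated(res[, c("metabolite", "outcome", "stratum")]), 0)
  expect_equal(sort(unique(res$metabolite)),
               sort(unique(default_qc()$fold_changes$metabolite)))
})

test_that("baseline and change coefficients are concordant when coupled", {
  expect_equal(baseline_change_concordance(1:10, 1:10), 1)
  set.seed(57)
  a <- stats::rnorm(200)
  b <- stats::rnorm(200)
  expect_lt(abs(baseline_change_concordance(a, b)), 0.2)
  # in the default cohort a shared latent lipid-oxidation propensity drives
  # both baseline levels and excursions, so concordance is positive
  expect_gt(baseline_change_concordance(default_pooled("rq24")), 0)
})
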