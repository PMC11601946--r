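test_that("the full generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 4, n_metabolites = 12, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$schedules, b$schedules)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$panel, b$panel)
  expect_identical(a$nefa, b$nefa)
})

test_that("participant marginals match the configured cohort structure", {
  set.seed(5)
  p <- simulate_participants(sim_config(), n = 1000)
  frac_f <- mean(p$sex == "F")
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(frac_f - 0.20), 3 * se)
  expect_true(all(p$fasting_glucose < 100 & p$glucose_2h < 140))
  cvs <- vapply(p$weight_series, weight_stability_cv, numeric(1))
  expect_equal(median(cvs), 0.9, tolerance = 0.2)
  # empty cohort is allowed
  empty <- simulate_participants(sim_config(), n = 0)
  expect_equal(nrow(empty), 0)
  expect_true("energy_need_kcal" %in% names(empty))
})

test_that("zero-noise traces obey pure-fuel stoichiometry", {
  cfg <- sim_config(seed = 1)
  fat_day <- simulate_trace("EB", 2200, cfg,
                            fuel_mix = c(carb = 0, fat = 1, protein = 0),
                            noise_sd = 0)
  agg <- aggregate_24h(fat_day$trace)
  expect_equal(agg$rq24, 1.427 / 2.019, tolerance = 1e-9)
  expect_equal(fat_day$nitrogen_g, 0)
  glu_day <- simulate_trace("EB", 2200, cfg,
                            fuel_mix = c(carb = 1, fat = 0, protein = 0),
                            noise_sd = 0)
  expect_equal(aggregate_24h(glu_day$trace)$rq24, 1, tolerance = 1e-9)
})

test_that("carbohydrate-heavy diets run a higher 24-h RQ than fat-heavy diets", {
  cfg <- sim_config(seed = 1)
  rq_of <- function(diet) {
    day <- simulate_trace(diet, 2300, cfg, noise_sd = 0)
    aggregate_24h(day$trace)$rq24
  }
  expect_gt(rq_of("CNP"), rq_of("FNP"))
  expect_gt(rq_of("EB"), rq_of("FAST"))
})

test_that("calorimetry round trip recovers the simulated substrate masses", {
  cfg <- sim_config(seed = 2)
  for (diet in c("EB", "FAST", "CNP", "FNP")) {
    day <- simulate_trace(diet, 2450, cfg, noise_sd = 0)
    s <- summarize_chamber_day(day$trace, day$nitrogen_g)
    total <- day$truth$carb_g + day$truth$fat_g + day$truth$prot_g
    expect_lt(abs(s$carbox_g - day$truth$carb_g), 0.02 * total)
    expect_lt(abs(s$lipox_g - day$truth$fat_g), 0.02 * total)
    expect_equal(s$protox_g, day$truth$prot_g, tolerance = 1e-9)
    # EB oxidized energy is recovered within 1%
    if (diet == "EB") expect_equal(s$ee24, 2450, tolerance = 0.01)
  }
})

test_that("simulated RQ stays in the physiologic band across the diet library", {
  cfg <- sim_config(seed = 8)
  for (diet in diet_library()$name) {
    day <- simulate_trace(diet, 2300, cfg)
    rq <- aggregate_24h(day$trace)$rq24
    expect_gt(rq, 0.69)
    expect_lt(rq, 1.05)
  }
})

test_that("a zero effect matrix with zero noise yields zero fold changes", {
  cfg <- sim_config(n_participants = 3, n_metabolites = 8, seed = 4,
                    effect_matrix = default_effect_matrix() * 0,
                    participant_sd = 0, residual_sd = 0, fat_shift_sd = 0,
                    missing_metab_frac = 0)
  sim <- simulate_cohort(cfg)
  fc <- log2_fold_change(sim$panel)
  expect_equal(fc$log2fc, rep(0, nrow(fc)), tolerance = 1e-12)
})

test_that("an injected class effect is recovered in the observed fold changes", {
  em <- default_effect_matrix() * 0
  em["FAST", "amino_acid"] <- 1
  cfg <- sim_config(n_participants = 30, n_metabolites = 30, seed = 6,
                    effect_matrix = em, fat_shift_sd = 0,
                    missing_metab_frac = 0)
  sim <- simulate_cohort(cfg)
  fc <- log2_fold_change(sim$panel)
  aa <- sim$metabolites$metabolite[sim$metabolites$class == "amino_acid"]
  obs <- fc$log2fc[fc$diet == "FAST" & fc$metabolite %in% aa]
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - 1), 3 * se)
})

test_that("the mean fold-change sign pattern reproduces the configured matrix", {
  sim <- default_sim()
  fc <- log2_fold_change(sim$panel)  # carries the class labels through
  cells <- fc |>
    dplyr::filter(!is.na(.data$log2fc)) |>
    dplyr::group_by(.data$diet, .data$class) |>
    dplyr::summarise(m = mean(.data$log2fc), .groups = "drop")
  em <- sim$truth$effect_matrix
  truth <- em[cbind(match(cells$diet, rownames(em)),
                    match(cells$class, colnames(em)))]
  informative <- abs(truth) >= 0.1
  agree <- sign(cells$m[informative]) == sign(truth[informative])
  expect_gte(mean(agree), 0.95)
})

test_that("NEFA excursions track lipid oxidation", {
  cfg0 <- sim_config(seed = 3, nefa_slope = 0, nefa_noise_sd = 0)
  sessions <- tibble::tibble(participant_id = sprintf("P%02d", 1:40),
                             diet = "EB", lipox_kcal = stats::rnorm(40, 700, 150))
  set.seed(9)
  n0 <- simulate_nefa(sessions, cfg0)
  expect_equal(n0$nefa_post, n0$nefa_pre)
  set.seed(9)
  n1 <- simulate_nefa(sessions, sim_config(seed = 3, nefa_slope = 0.3))
  expect_gt(stats::cor(n1$nefa_post - n1$nefa_pre, sessions$lipox_kcal), 0)
  # in the full default cohort, fasting has the highest lipid oxidation and
  # the largest NEFA excursion
  sim <- default_sim()
  lip <- tapply(sim$sessions$lipox_kcal[!is.na(sim$sessions$chamber_order)],
                sim$sessions$diet[!is.na(sim$sessions$chamber_order)], mean)
  expect_equal(names(which.max(lip)), "FAST")
  dn <- tapply(sim$nefa$nefa_post - sim$nefa$nefa_pre, sim$nefa$diet, mean)
  expect_equal(names(which.max(dn)), "FAST")
})

test_that("the dataset writer emits the full CSV/JSON dialect", {
  cfg <- sim_config(n_participants = 3, n_metabolites = 8, seed = 12)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  files <- list.files(dir)
  expect_setequal(files, c("participants.csv", "schedules.csv", "sessions.csv",
                           "metabolite_panel.csv", "qc_replicates.csv",
                           "nefa.csv", "truth.json"))
  panel <- read_metabolite_panel(file.path(dir, "metabolite_panel.csv"))
  expect_equal(nrow(panel), nrow(sim$panel))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$nefa_slope, cfg$nefa_slope)
})
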