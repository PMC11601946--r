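# Synthetic cohort generator: participants, crossover schedules, gas-exchange
# traces built by forward stoichiometry, urinary nitrogen, metabolite panels
# with diet-by-class effects, and NEFA coupled to lipid oxidation. The
# stand-in for the study's controlled-access data; ground truth is retained
# for parameter-recovery tests.

.metab_classes <- c("acylcarnitine", "amino_acid", "bcaa",
                    "glycerophospholipid", "fatty_acyl", "other")

#' Default diet-by-class log2 effect matrix
#'
#' Mean log2 fold-change effects of each chamber condition on each metabolite
#' class. Signs encode the expected physiology: acylcarnitines rise under
#' fasting and high-fat overfeeding and fall under high-carbohydrate
#' overfeeding; glycerophospholipids move oppositely; non-branched amino
#' acids fall during fasting while branched-chain amino acids rise. The EB
#' row is zero (referent condition).
#'
#' @return A diets x classes numeric matrix (log2 units).
#' @export
default_effect_matrix <- function() {
  m <- rbind(
    EB   = c(0,     0,    0,    0,     0,     0),
    FAST = c(0.8,  -0.5,  0.4, -0.6,   0.5,   0),
    SOF  = c(0.1,   0.1,  0.1,  0.15,  0.05,  0.05),
    LPF  = c(-0.1, -0.4, -0.2,  0.1,  -0.05,  0.2),
    FNP  = c(0.5,   0,    0.1, -0.4,   0.3,   0),
    HPF  = c(0.4,   0.3,  0.3, -0.3,   0.2,   0),
    CNP  = c(-0.5,  0.1, -0.1,  0.5,  -0.3,   0.05)
  )
  colnames(m) <- .metab_classes
  m
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort. Defaults encode the study
#' conditions the pipeline expects: ~20% female, median age 38, median BMI
#' 26, weight CV ~0.9%; meals at 11:00, 16:00 and 19:00 (chamber entry at
#' 07:00, so minutes 240/540/720); oxidized-fuel mix blending the prescribed
#' macronutrient split with a 50/30/20 endogenous baseline; fasting fuel mix
#' drifting from 50/30/20 to 15/70/15 over the day; pooled-QC replicates
#' targeting a 5% CV; 5% of metabolites carrying injected missingness.
#'
#' @param n_participants,n_metabolites Cohort and panel sizes.
#' @param seed Integer seed governing all randomness.
#' @param effect_matrix Diet x class log2 effect matrix
#'   ([default_effect_matrix()]).
#' @param class_props Named proportions of metabolites per class.
#' @param participant_sd SD of the per-participant (per-metabolite) random
#'   intercept on the log2 fold change.
#' @param residual_sd Residual SD of the log2 fold change.
#' @param baseline_sd SD of prechamber log2 abundance around its metabolite
#'   mean.
#' @param trace_noise_sd,trace_ar1 Multiplicative AR(1) noise on the
#'   per-minute gas trace (stationary SD; AR coefficient in `[0, 1)`).
#' @param meal_minutes Meal times as minutes since chamber entry.
#' @param fat_shift_sd SD of the session-level shift of oxidized energy from
#'   carbohydrate to fat (couples physiology to the metabolome).
#' @param coupling Named per-class coefficients linking the session fat shift
#'   to metabolite log2 fold changes.
#' @param pre_coupling Named per-class coefficients linking a participant's
#'   latent lipid-oxidation propensity to prechamber log2 levels.
#' @param ee_response Named per-diet multipliers of EB energy need giving
#'   oxidized (expended) energy for the day.
#' @param diet_mix_weight Weight of the prescribed macronutrient split in the
#'   oxidized mix (remainder from the 50/30/20 baseline).
#' @param fast_mix_start,fast_mix_end Oxidized-fuel energy fractions at the
#'   start and end of a fasting day.
#' @param qc_replicates,qc_cv_pct Pooled-QC replicate count per metabolite
#'   and target percent CV.
#' @param missing_metab_frac Fraction of metabolites given missing values.
#' @param nefa_baseline,nefa_baseline_sd,nefa_slope,nefa_noise_sd NEFA
#'   (mEq/L): prechamber mean/SD, slope on standardized LIPOX, residual SD.
#' @param washout_days Washout between chambers (days).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 50,
                       n_metabolites = 60,
                       seed = 1L,
                       effect_matrix = default_effect_matrix(),
                       class_props = c(acylcarnitine = 0.20, amino_acid = 0.15,
                                       bcaa = 0.05, glycerophospholipid = 0.25,
                                       fatty_acyl = 0.15, other = 0.20),
                       participant_sd = 0.15,
                       residual_sd = 0.20,
                       baseline_sd = 0.40,
                       trace_noise_sd = 0.02,
                       trace_ar1 = 0.9,
                       meal_minutes = c(240, 540, 720),
                       fat_shift_sd = 0.08,
                       coupling = c(acylcarnitine = 4, amino_acid = 0, bcaa = 0,
                                    glycerophospholipid = -3, fatty_acyl = 1.5,
                                    other = 0),
                       pre_coupling = c(acylcarnitine = 0.25, amino_acid = 0,
                                        bcaa = 0, glycerophospholipid = -0.2,
                                        fatty_acyl = 0.1, other = 0),
                       ee_response = c(EB = 1, FAST = 0.92, SOF = 1.08,
                                       LPF = 1.06, FNP = 1.06, HPF = 1.10,
                                       CNP = 1.15),
                       diet_mix_weight = 0.4,
                       fast_mix_start = c(carb = 0.50, fat = 0.30, protein = 0.20),
                       fast_mix_end = c(carb = 0.15, fat = 0.70, protein = 0.15),
                       qc_replicates = 8,
                       qc_cv_pct = 5,
                       missing_metab_frac = 0.05,
                       nefa_baseline = 0.5,
                       nefa_baseline_sd = 0.08,
                       nefa_slope = 0.15,
                       nefa_noise_sd = 0.05,
                       washout_days = 3) {
  stopifnot(
    n_participants >= 0, n_metabolites >= 1,
    participant_sd >= 0, residual_sd >= 0, baseline_sd >= 0,
    trace_noise_sd >= 0, trace_ar1 >= 0, trace_ar1 < 1,
    fat_shift_sd >= 0, qc_cv_pct >= 0, nefa_noise_sd >= 0,
    missing_metab_frac >= 0, missing_metab_frac <= 1
  )
  stopifnot(
    all(rownames(effect_matrix) == diet_library()$name),
    identical(colnames(effect_matrix), names(class_props)),
    abs(sum(class_props) - 1) < 1e-9
  )
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a participant cohort
#'
#' Draws ages, sexes, race, weight, BMI, a daily weight series (CV ~0.9%)
#' and OGTT glucose values (eligible by construction), plus an allometric
#' EB energy need `70 * weight^0.75` kcal/day used only for its relative
#' structure.
#'
#' @param config A [sim_config()].
#' @param n Number of participants (defaults to the config value).
#' @return A participant tibble; `weight_series` is a list column.
#' @export
simulate_participants <- function(config = sim_config(), n = config$n_participants) {
  if (n == 0) {
    return(tibble::tibble(
      participant_id = character(), age = numeric(), sex = character(),
      race = character(), weight_kg = numeric(), bmi = numeric(),
      fasting_glucose = numeric(), glucose_2h = numeric(),
      weight_series = list(), energy_need_kcal = numeric()
    ))
  }
  weight <- pmin(pmax(stats::rnorm(n, 85, 15), 50), 140)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = round(pmin(pmax(stats::rnorm(n, 38, 10), 18), 70)),
    sex = ifelse(stats::runif(n) < 0.20, "F", "M"),
    race = sample(c("groupA", "groupB", "groupC"), n, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15)),
    weight_kg = weight,
    bmi = pmin(pmax(stats::rnorm(n, 26, 4), 18), 42),
    fasting_glucose = pmin(pmax(stats::rnorm(n, 88, 5), 70), 99.5),
    glucose_2h = pmin(pmax(stats::rnorm(n, 112, 12), 70), 139.5),
    weight_series = lapply(weight, function(w) w * (1 + stats::rnorm(37, 0, 0.009))),
    energy_need_kcal = 70 * weight^0.75
  )
}

# Oxidized-fuel energy-fraction mix for one session: a 1440 x 3 matrix
# (carb, fat, protein). Fed diets blend the prescription with the 50/30/20
# baseline; fasting drifts linearly toward fat across the day. fat_shift
# moves energy from carbohydrate to fat (session-level heterogeneity).
session_fuel_mix <- function(diet_name, config, fat_shift = 0, fuel_mix = NULL) {
  if (!is.null(fuel_mix)) {
    mix <- matrix(rep(fuel_mix[c("carb", "fat", "protein")], each = 1440), nrow = 1440)
  } else if (diet_name == "FAST") {
    a <- (0:1439) / 1439
    mix <- (1 - a) %o% config$fast_mix_start + a %o% config$fast_mix_end
  } else {
    diets <- diet_library()
    d <- diets[diets$name == diet_name, ]
    if (nrow(d) == 0) stop("unknown diet: ", diet_name, call. = FALSE)
    w <- config$diet_mix_weight
    base <- w * c(d$carb_frac, d$fat_frac, d$prot_frac) +
      (1 - w) * c(0.5, 0.3, 0.2)
    mix <- matrix(rep(base, each = 1440), nrow = 1440)
  }
  colnames(mix) <- c("carb", "fat", "protein")
  if (fat_shift != 0) {
    mix[, "fat"] <- pmax(mix[, "fat"] + fat_shift, 0.01)
    mix[, "carb"] <- pmax(mix[, "carb"] - fat_shift, 0.01)
    mix <- mix / rowSums(mix)
  }
  mix
}

# Diurnal energy-expenditure profile: unit baseline, post-meal thermogenesis
# bumps (fed diets) and a sleep dip from 23:00 to 06:30.
diurnal_profile <- function(fed, meal_minutes) {
  profile <- rep(1, 1440)
  if (fed) {
    for (m in meal_minutes) {
      idx <- m:min(m + 119, 1439)
      profile[idx + 1] <- profile[idx + 1] + 0.35 * exp(-(idx - m) / 45)
    }
  }
  sleep <- 961:1410  # minutes 960..1409 since 07:00 entry
  profile[sleep] <- profile[sleep] * 0.82
  profile
}

#' Simulate one chamber day of gas exchange
#'
#' Forward-synthesizes a minute-level VO2/VCO2 trace from a daily oxidized
#' energy budget and a fuel mix via the per-gram stoichiometry in
#' [fuel_stoichiometry()], shaped by a diurnal profile (sleep dip, post-meal
#' thermogenesis) and multiplied by stationary AR(1) noise. Urinary nitrogen
#' is the oxidized protein mass divided by 6.25, so the calorimetry engine
#' applied to a zero-noise trace recovers the true substrate masses.
#'
#' @param diet Diet name from the library.
#' @param eb_ee The participant's EB energy need (kcal/day); the day's
#'   oxidized energy is `eb_ee * ee_response[diet]`.
#' @param config A [sim_config()].
#' @param fat_shift Session-level carbohydrate-to-fat shift of the oxidized
#'   mix (energy fraction).
#' @param fuel_mix Optional fixed energy-fraction mix (named `carb`, `fat`,
#'   `protein`) overriding the diet-derived mix.
#' @param noise_sd Override of the trace noise SD (set 0 for a noise-free
#'   day).
#' @return List with `trace` (tibble `minute`, `vo2`, `vco2`), `nitrogen_g`
#'   and `truth` (oxidized `carb_g`, `fat_g`, `prot_g`, `kcal`).
#' @export
simulate_trace <- function(diet, eb_ee, config = sim_config(), fat_shift = 0,
                           fuel_mix = NULL, noise_sd = config$trace_noise_sd) {
  stopifnot(eb_ee > 0)
  resp <- config$ee_response
  total_kcal <- eb_ee * if (diet %in% names(resp)) resp[[diet]] else 1
  mix <- session_fuel_mix(diet, config, fat_shift = fat_shift, fuel_mix = fuel_mix)
  fed <- !(diet == "FAST" && is.null(fuel_mix))
  profile <- diurnal_profile(fed, config$meal_minutes)
  e_min <- total_kcal * profile / sum(profile)
  grams <- (e_min * mix) %*% diag(1 / .fuel$kcal)  # columns carb, fat, protein
  colnames(grams) <- names(.fuel$kcal)
  vo2 <- as.numeric(grams %*% .fuel$o2)
  vco2 <- as.numeric(grams %*% .fuel$co2)
  if (noise_sd > 0) {
    phi <- config$trace_ar1
    innov_sd <- noise_sd * sqrt(1 - phi^2)
    e1 <- as.numeric(stats::filter(stats::rnorm(1440, 0, innov_sd), phi,
                                   method = "recursive"))
    e2 <- as.numeric(stats::filter(stats::rnorm(1440, 0, innov_sd), phi,
                                   method = "recursive"))
    vo2 <- pmax(vo2 * (1 + e1), 1e-6)
    vco2 <- pmax(vco2 * (1 + e2), 0)
  }
  totals <- colSums(grams)
  list(
    trace = tibble::tibble(minute = 0:1439, vo2 = vo2, vco2 = vco2),
    nitrogen_g = totals[["protein"]] / .nitrogen_to_protein,
    truth = list(carb_g = totals[["carb"]], fat_g = totals[["fat"]],
                 prot_g = totals[["protein"]], kcal = total_kcal)
  )
}

#' Simulate metabolite panels for a set of chamber sessions
#'
#' Prechamber abundances are log-normal around per-metabolite means (shifted
#' by the participant's latent lipid-oxidation propensity through
#' `pre_coupling`); postchamber log2 levels add the diet-by-class effect, a
#' per-participant random intercept, the session fat-shift coupling and
#' residual noise. Pooled-QC replicates and per-metabolite missingness are
#' injected per the config.
#'
#' @param sessions Analysis-session tibble (needs `participant_id`, `diet`,
#'   `chamber_order`, `fat_shift`).
#' @param participants Participant tibble (for the propensity join).
#' @param config A [sim_config()].
#' @param propensity Named numeric (by participant id) latent propensity;
#'   zeros when omitted.
#' @return List: `panel` (long tibble with `timepoint` pre/post and raw
#'   `abundance`), `metabolites` (id/class map), `qc_replicates`, `truth`.
#' @export
simulate_metabolome <- function(sessions, participants, config = sim_config(),
                                propensity = NULL) {
  n_met <- config$n_metabolites
  props <- config$class_props
  counts <- diff(round(cumsum(c(0, props)) * n_met))
  classes <- rep(names(props), counts)
  if (length(classes) < n_met) {
    classes <- c(classes, rep(names(props)[length(props)], n_met - length(classes)))
  }
  metabolites <- tibble::tibble(
    metabolite = sprintf("M%03d", seq_len(n_met)),
    class = classes[seq_len(n_met)]
  )
  mu <- stats::runif(n_met, 10, 20)
  ids <- unique(sessions$participant_id)
  if (is.null(propensity)) propensity <- stats::setNames(rep(0, length(ids)), ids)
  u <- matrix(stats::rnorm(length(ids) * n_met, 0, config$participant_sd),
              nrow = length(ids), dimnames = list(ids, metabolites$metabolite))

  grid <- dplyr::cross_join(
    sessions[, c("participant_id", "diet", "chamber_order", "fat_shift")],
    metabolites
  )
  p_idx <- match(grid$participant_id, ids)
  m_idx <- match(grid$metabolite, metabolites$metabolite)
  eff <- config$effect_matrix[cbind(match(grid$diet, rownames(config$effect_matrix)),
                                    match(grid$class, colnames(config$effect_matrix)))]
  pre_log2 <- as.numeric(mu[m_idx] +
    config$pre_coupling[grid$class] * propensity[p_idx] +
    stats::rnorm(nrow(grid), 0, config$baseline_sd))
  delta <- as.numeric(eff + u[cbind(p_idx, m_idx)] +
    config$coupling[grid$class] * grid$fat_shift +
    stats::rnorm(nrow(grid), 0, config$residual_sd))
  base <- grid[, c("participant_id", "diet", "chamber_order", "metabolite", "class")]
  panel <- dplyr::bind_rows(
    dplyr::mutate(base, timepoint = "pre", abundance = 2^pre_log2),
    dplyr::mutate(base, timepoint = "post", abundance = 2^(pre_log2 + delta))
  )

  missing_mets <- character(0)
  n_miss <- round(config$missing_metab_frac * n_met)
  if (n_miss > 0) {
    missing_mets <- sample(metabolites$metabolite, n_miss)
    for (m in missing_mets) {
      rows <- which(panel$metabolite == m)
      panel$abundance[sample(rows, sample(1:3, 1))] <- NA_real_
    }
  }

  k <- config$qc_replicates
  qc <- tibble::tibble(
    metabolite = rep(metabolites$metabolite, each = k),
    replicate = rep(seq_len(k), n_met),
    abundance = 2^rep(mu, each = k) *
      exp(stats::rnorm(n_met * k, 0, config$qc_cv_pct / 100))
  )

  list(
    panel = panel,
    metabolites = metabolites,
    qc_replicates = qc,
    truth = list(mu_log2 = stats::setNames(mu, metabolites$metabolite),
                 participant_intercepts = u,
                 missing_metabolites = missing_mets)
  )
}

#' Simulate pre/post chamber NEFA
#'
#' Postchamber nonesterified fatty acids rise with the session's lipid
#' oxidation: `post = pre + slope * standardized(LIPOX) + noise`, in mEq/L.
#'
#' @param sessions Analysis sessions with a `lipox_kcal` column.
#' @param config A [sim_config()].
#' @return Tibble `participant_id`, `diet`, `nefa_pre`, `nefa_post`.
#' @export
simulate_nefa <- function(sessions, config = sim_config()) {
  n <- nrow(sessions)
  z <- as.numeric(scale(sessions$lipox_kcal))
  if (n < 2 || anyNA(z)) z <- rep(0, n)
  pre <- pmax(stats::rnorm(n, config$nefa_baseline, config$nefa_baseline_sd), 0.05)
  post <- pmax(pre + config$nefa_slope * z +
                 stats::rnorm(n, 0, config$nefa_noise_sd), 0.05)
  tibble::tibble(
    participant_id = sessions$participant_id,
    diet = sessions$diet,
    nefa_pre = pre,
    nefa_post = post
  )
}

#' Simulate a complete chamber study
#'
#' Orchestrates the full synthetic dataset under one seed: participants,
#' randomized crossover schedules with energy-balance calibration from the
#' simulated first eucaloric chamber, per-session gas-exchange traces
#' summarized by the calorimetry engine, metabolite panels, pooled-QC
#' replicates and NEFA. All ground truth is retained.
#'
#' @param config A [sim_config()].
#' @param keep_traces Keep the minute-level traces (list column of tibbles)?
#'   Off by default to bound memory.
#' @return List: `participants`, `schedules`, `sessions` (one row per chamber
#'   session with calorimetry summary and true substrate masses), `panel`,
#'   `metabolites`, `qc_replicates`, `nefa`, `truth` and optionally `traces`.
#' @export
simulate_cohort <- function(config = sim_config(), keep_traces = FALSE) {
  set.seed(config$seed)
  participants <- simulate_participants(config)
  n <- nrow(participants)
  if (n == 0) stop("cannot simulate a cohort with 0 participants", call. = FALSE)
  sched_seeds <- sample.int(.Machine$integer.max - 1L, n)
  propensity <- stats::setNames(stats::rnorm(n), participants$participant_id)

  schedules <- vector("list", n)
  session_rows <- vector("list", n)
  traces <- if (keep_traces) list() else NULL
  for (i in seq_len(n)) {
    p <- participants[i, ]
    sch <- randomize_schedule(p$participant_id, seed = sched_seeds[i],
                              estimated_kcal = p$energy_need_kcal,
                              washout_days = config$washout_days)
    rows <- vector("list", nrow(sch))
    for (s in seq_len(nrow(sch))) {
      shift <- config$fat_shift_sd *
        (sqrt(0.4) * propensity[[i]] + sqrt(0.6) * stats::rnorm(1))
      sim <- simulate_trace(sch$diet[s], p$energy_need_kcal, config,
                            fat_shift = shift)
      summ <- summarize_chamber_day(sim$trace, sim$nitrogen_g)
      if (s == 1) sch <- apply_calibration(sch, summ$ee24)
      rows[[s]] <- dplyr::bind_cols(
        sch[s, c("participant_id", "session", "chamber_order", "diet",
                 "prescribed_kcal")],
        tibble::tibble(fat_shift = shift, nitrogen_g = sim$nitrogen_g,
                       true_carb_g = sim$truth$carb_g,
                       true_fat_g = sim$truth$fat_g,
                       true_prot_g = sim$truth$prot_g,
                       true_kcal = sim$truth$kcal),
        summ
      )
      if (keep_traces) {
        traces[[paste(p$participant_id, s, sep = "_")]] <- sim$trace
      }
    }
    schedules[[i]] <- sch
    session_rows[[i]] <- dplyr::bind_rows(rows)
  }
  schedules <- dplyr::bind_rows(schedules)
  sessions <- dplyr::bind_rows(session_rows)

  analysis <- sessions[!is.na(sessions$chamber_order), ]
  metab <- simulate_metabolome(analysis, participants, config,
                               propensity = propensity)
  nefa <- simulate_nefa(analysis, config)

  out <- list(
    config = config,
    participants = participants,
    schedules = schedules,
    sessions = sessions,
    panel = metab$panel,
    metabolites = metab$metabolites,
    qc_replicates = metab$qc_replicates,
    nefa = nefa,
    truth = list(
      effect_matrix = config$effect_matrix,
      coupling = config$coupling,
      pre_coupling = config$pre_coupling,
      propensity = propensity,
      nefa_slope = config$nefa_slope,
      metabolome = metab$truth
    )
  )
  if (keep_traces) out$traces <- traces
  out
}

#' Inject a prechamber outlier into a panel
#'
#' Sets one prechamber measurement of the given metabolite/diet group to the
#' group mean plus `z` group SDs (raw scale), for exercising the outlier
#' rule.
#'
#' @param panel A long metabolite panel.
#' @param metabolite,diet Group to perturb.
#' @param z Number of SDs above the group mean.
#' @return The perturbed panel.
#' @export
inject_outlier <- function(panel, metabolite, diet, z = 8) {
  rows <- which(panel$metabolite == metabolite & panel$diet == diet &
                  panel$timepoint == "pre")
  if (!length(rows)) stop("no matching prechamber rows", call. = FALSE)
  vals <- panel$abundance[rows]
  panel$abundance[rows[1]] <- mean(vals, na.rm = TRUE) +
    z * stats::sd(vals, na.rm = TRUE)
  panel
}
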