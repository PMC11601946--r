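# Study-design encoding: diet library, crossover schedule with energy-balance
# calibration, eligibility and compliance filters.

.diet_names <- c("EB", "FAST", "SOF", "LPF", "FNP", "HPF", "CNP")

#' Diet prescription library
#'
#' The seven chamber conditions: energy balance (EB), 24-hour fasting (FAST)
#' and five 200%-of-energy-needs overfeeding diets — standard (SOF),
#' low-protein (LPF, 3% protein), high-fat/normal-protein (FNP),
#' high-fat/high-protein (HPF) and high-carbohydrate/normal-protein (CNP).
#' Macronutrient fractions are energy fractions and are synthetic defaults
#' (configurable via `overrides` or [read_diet_library()]); the multiplier is
#' intake as a multiple of the measured EB 24-hour energy expenditure
#' (0 for fasting, 1 for energy balance, 2 for all overfeeding diets).
#'
#' @param overrides Optional tibble/data frame with columns `name`,
#'   `carb_frac`, `fat_frac`, `prot_frac`, `energy_multiplier` replacing the
#'   defaults for the named diets.
#' @return A validated tibble of diet prescriptions.
#' @export
diet_library <- function(overrides = NULL) {
  diets <- tibble::tribble(
    ~name,  ~carb_frac, ~fat_frac, ~prot_frac, ~energy_multiplier,
    "EB",   0.50,       0.30,      0.20,       1,
    "FAST", 0,          0,         0,          0,
    "SOF",  0.50,       0.30,      0.20,       2,
    "LPF",  0.51,       0.46,      0.03,       2,
    "FNP",  0.20,       0.60,      0.20,       2,
    "HPF",  0.25,       0.45,      0.30,       2,
    "CNP",  0.75,       0.05,      0.20,       2
  )
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    stopifnot(all(names(diets) %in% names(overrides)))
    diets <- dplyr::rows_update(diets, overrides[names(diets)], by = "name")
  }
  validate_diet_library(diets)
  diets
}

validate_diet_library <- function(diets) {
  fr <- as.matrix(diets[, c("carb_frac", "fat_frac", "prot_frac")])
  bad <- rowSums(is.na(fr)) > 0 | fr[, 1] < 0 | fr[, 2] < 0 | fr[, 3] < 0 |
    fr[, 1] > 1 | fr[, 2] > 1 | fr[, 3] > 1
  fed <- diets$energy_multiplier > 0
  bad_sum <- fed & abs(rowSums(fr) - 1) > 1e-9
  if (any(bad | bad_sum)) {
    stop("malformed macronutrient fractions for diet(s): ",
         paste(diets$name[bad | bad_sum], collapse = ", "), call. = FALSE)
  }
  invisible(diets)
}

#' Read a diet library from a YAML config file
#'
#' Each top-level key is a diet name mapping to `carb`, `fat`, `protein`
#' fractions of energy and an intake `multiplier`.
#'
#' @param path Path to the YAML file.
#' @return A validated diet tibble (same shape as [diet_library()]).
#' @export
read_diet_library <- function(path) {
  raw <- yaml::read_yaml(path)
  field <- function(key) {
    unname(vapply(raw, function(d) as.numeric(d[[key]]), numeric(1)))
  }
  diets <- tibble::tibble(
    name = names(raw),
    carb_frac = field("carb"),
    fat_frac = field("fat"),
    prot_frac = field("protein"),
    energy_multiplier = field("multiplier")
  )
  validate_diet_library(diets)
  diets
}

#' Energy-balance calibration
#'
#' The measured 24-hour EE of the first eucaloric chamber becomes the
#' prescribed intake of the second (energy-balance) chamber.
#'
#' @param first_chamber_ee Measured 24-h EE (kcal/day), positive.
#' @return The prescribed intake (kcal/day), identical to the input.
#' @export
calibrate_energy_balance <- function(first_chamber_ee) {
  if (any(!is.finite(first_chamber_ee)) || any(first_chamber_ee <= 0)) {
    stop("first-chamber EE must be positive", call. = FALSE)
  }
  first_chamber_ee
}

#' Prescribed intake for a chamber condition
#'
#' Intake is the diet's energy multiplier times the individual's EB 24-hour
#' EE: 0 for fasting, 1x for energy balance, 2x (200% caloric excess) for
#' all overfeeding diets.
#'
#' @param diet A diet name or a one-row diet tibble.
#' @param eb_ee EB 24-hour EE (kcal/day), positive.
#' @param diets Diet library to resolve names against.
#' @return Prescribed intake (kcal/day).
#' @export
prescribe_intake <- function(diet, eb_ee, diets = diet_library()) {
  if (any(eb_ee <= 0)) stop("eb_ee must be positive", call. = FALSE)
  if (is.character(diet)) {
    idx <- match(diet, diets$name)
    if (anyNA(idx)) stop("unknown diet: ", paste(diet[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    mult <- diets$energy_multiplier[idx]
  } else {
    mult <- diet$energy_multiplier
  }
  mult * eb_ee
}

#' Randomized crossover chamber schedule
#'
#' Builds one participant's schedule: an initial eucaloric calibration
#' session, the energy-balance chamber (intake set later from the measured
#' calibration EE via [apply_calibration()]), then all non-EB intervention
#' chambers in seeded-random (Fisher-Yates) order, each preceded by a
#' washout on a weight-maintaining diet. The calibration session carries
#' `chamber_order = NA`; analysis chambers are ordered 1 (EB) through
#' 1 + number of interventions.
#'
#' @param participant_id Participant identifier.
#' @param seed Integer seed; the intervention order is a uniform permutation,
#'   deterministic given the seed. The surrounding RNG state is untouched.
#' @param diets Diet library (must include EB).
#' @param estimated_kcal Weight-maintenance estimate (kcal/day) used as the
#'   calibration-session intake.
#' @param washout_days Washout length before each post-calibration session
#'   (days, at least 3).
#' @return A schedule tibble: `participant_id`, `session`, `chamber_order`,
#'   `diet`, `prescribed_kcal`, `washout_days_before`, `start_day`.
#' @export
randomize_schedule <- function(participant_id, seed, diets = diet_library(),
                               estimated_kcal = NA_real_, washout_days = 3) {
  stopifnot(!missing(seed), washout_days >= 3)
  if (!"EB" %in% diets$name) stop("diet library must include EB", call. = FALSE)
  interventions <- setdiff(diets$name, "EB")
  order <- withr::with_seed(seed, sample(interventions))
  diet_seq <- c("EB", "EB", order)
  n <- length(diet_seq)
  washout <- c(0, rep(washout_days, n - 1))
  tibble::tibble(
    participant_id = participant_id,
    session = seq_len(n),
    chamber_order = c(NA_integer_, seq_len(n - 1L)),
    diet = diet_seq,
    prescribed_kcal = c(estimated_kcal, rep(NA_real_, n - 1)),
    washout_days_before = washout,
    start_day = cumsum(c(1, washout[-1] + 1))
  )
}

#' Fill a schedule's prescriptions from the measured calibration EE
#'
#' Sets the EB chamber intake to the measured first-chamber EE
#' ([calibrate_energy_balance()]) and every other chamber to its diet's
#' multiple of that EB energy.
#'
#' @param schedule A schedule from [randomize_schedule()].
#' @param measured_ee Measured 24-h EE of the calibration session (kcal/day).
#' @param diets Diet library.
#' @return The schedule with `prescribed_kcal` filled for all sessions.
#' @export
apply_calibration <- function(schedule, measured_ee, diets = diet_library()) {
  eb_ee <- calibrate_energy_balance(measured_ee)
  fill <- is.na(schedule$prescribed_kcal) | schedule$session > 1
  schedule$prescribed_kcal[fill] <-
    prescribe_intake(schedule$diet[fill], eb_ee, diets = diets)
  schedule
}

#' Glucose-regulation eligibility filter
#'
#' Excludes participants meeting impaired-glucose-regulation thresholds
#' (fasting glucose >= 100 mg/dL or 2-hour glucose >= 140 mg/dL) or type 2
#' diabetes thresholds (fasting >= 126 or 2-hour >= 200), recording the
#' reason. Idempotent: filtering the retained set changes nothing.
#'
#' @param participants Tibble with `fasting_glucose` and `glucose_2h` (mg/dL).
#' @return List with `retained` and `excluded` (the latter with an
#'   `exclusion_reason` column).
#' @export
eligibility_filter <- function(participants) {
  fg <- participants$fasting_glucose
  g2 <- participants$glucose_2h
  if (anyNA(fg) || anyNA(g2)) stop("glucose fields must be present", call. = FALSE)
  if (any(fg <= 0) || any(g2 <= 0)) stop("glucose values must be positive", call. = FALSE)
  t2d <- fg >= 126 | g2 >= 200
  impaired <- !t2d & (fg >= 100 | g2 >= 140)
  reason <- dplyr::case_when(
    t2d ~ "type_2_diabetes",
    impaired ~ "impaired_glucose_regulation",
    TRUE ~ NA_character_
  )
  excluded <- participants[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  list(retained = participants[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Food-consumption compliance filter
#'
#' Sessions in which less than or exactly 95% of the provided food energy was
#' consumed are withdrawn; fasting sessions (no food provided) are always
#' kept.
#'
#' @param consumed_kcal,provided_kcal Energy consumed / provided (kcal).
#' @param diet Diet name(s); `"FAST"` sessions are always kept.
#' @return Logical vector: `TRUE` to keep the session.
#' @export
compliance_filter <- function(consumed_kcal, provided_kcal, diet = NULL) {
  if (any(provided_kcal < 0)) stop("provided_kcal must be nonnegative", call. = FALSE)
  fasting <- if (is.null(diet)) rep(FALSE, length(provided_kcal)) else diet == "FAST"
  fasting | provided_kcal == 0 | (consumed_kcal / provided_kcal > 0.95)
}

#' Weight stability as a percent coefficient of variation
#'
#' @param weight_series Daily weights (kg), at least two values.
#' @return `100 * sd / mean` of the series.
#' @export
weight_stability_cv <- function(weight_series) {
  weight_series <- weight_series[!is.na(weight_series)]
  if (length(weight_series) < 2) {
    stop("need at least 2 weights to compute a CV", call. = FALSE)
  }
  100 * stats::sd(weight_series) / mean(weight_series)
}
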