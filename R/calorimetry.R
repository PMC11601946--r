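# Indirect-calorimetry engine: per-minute RQ/EE, 24-h aggregation, and
# nitrogen-corrected substrate oxidation (Frayn stoichiometry).

# Lusk caloric-equivalent-of-oxygen constants (kcal/L O2 at RQ = 0.707,
# plus the RQ-dependence increment).
.lusk <- list(base = 4.686, rq0 = 0.707, num = 0.361, den = 0.293)

# Per-gram gas volumes (L) and energy densities (kcal) for the three fuels.
.fuel <- list(
  o2   = c(carb = 0.746, fat = 2.019, protein = 0.966),
  co2  = c(carb = 0.746, fat = 1.427, protein = 0.782),
  kcal = c(carb = 3.74,  fat = 9.46,  protein = 4.70)
)

# Urinary nitrogen to oxidized protein mass.
.nitrogen_to_protein <- 6.25

# Frayn-form inversion coefficients (g oxidized from L of gas and g of N).
.frayn <- c(carb_vco2 = 4.55, carb_vo2 = 3.21, carb_n = 2.87,
            fat_gas = 1.67, fat_n = 1.92)

#' Fuel stoichiometry table
#'
#' Per-gram oxygen consumption, carbon dioxide production and energy density
#' for carbohydrate (as glucose), fat and protein, as used throughout the
#' calorimetry calculations. Pure-fuel respiratory quotients are the CO2/O2
#' ratios of these rows (1.0 for carbohydrate, ~0.707 for fat).
#'
#' @return A tibble with columns `fuel`, `o2_l_per_g`, `co2_l_per_g`,
#'   `kcal_per_g`.
#' @export
fuel_stoichiometry <- function() {
  tibble::tibble(
    fuel = names(.fuel$o2),
    o2_l_per_g = unname(.fuel$o2),
    co2_l_per_g = unname(.fuel$co2),
    kcal_per_g = unname(.fuel$kcal)
  )
}

#' Per-minute respiratory quotient
#'
#' @param vo2 Oxygen consumption (L/min), must be positive.
#' @param vco2 Carbon dioxide production (L/min), must be nonnegative.
#' @return `vco2 / vo2`, vectorized.
#' @export
per_minute_rq <- function(vo2, vco2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0)) {
    stop("invalid minute: vo2 must be positive and finite", call. = FALSE)
  }
  if (any(vco2 < 0, na.rm = TRUE)) {
    stop("invalid minute: vco2 must be nonnegative", call. = FALSE)
  }
  vco2 / vo2
}

#' Per-minute energy expenditure (Lusk equation)
#'
#' Energy expenditure as the caloric equivalent of oxygen scaled by oxygen
#' consumption: `vo2 * (4.686 + (rq - 0.707) * 0.361/0.293)` kcal/min.
#' At RQ 0.707 (pure fat) one liter of O2 yields 4.686 kcal; the equivalent
#' rises linearly with RQ to 5.047 kcal/L at RQ 1 (pure carbohydrate).
#'
#' @param vo2 Oxygen consumption (L/min), positive.
#' @param rq Respiratory quotient, within (0.6, 1.3).
#' @return Energy expenditure (kcal/min), vectorized.
#' @export
per_minute_ee <- function(vo2, rq) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0)) {
    stop("vo2 must be positive and finite", call. = FALSE)
  }
  if (any(rq <= 0.6 | rq >= 1.3)) {
    stop("rq outside the physiologic range (0.6, 1.3)", call. = FALSE)
  }
  vo2 * (.lusk$base + (rq - .lusk$rq0) * .lusk$num / .lusk$den)
}

# Fill gaps of <= max_gap missing minutes by linear interpolation; reject
# sessions with longer gaps or < min_coverage minute coverage.
fill_minute_gaps <- function(trace, max_gap = 5, min_coverage = 0.95) {
  stopifnot(all(c("minute", "vo2", "vco2") %in% names(trace)))
  if (anyDuplicated(trace$minute)) {
    stop("minute indices must be unique", call. = FALSE)
  }
  if (any(trace$minute < 0 | trace$minute > 1439)) {
    stop("minute indices must lie in 0..1439", call. = FALSE)
  }
  trace <- dplyr::arrange(trace, .data$minute)
  present <- trace$minute
  coverage <- length(present) / 1440
  if (coverage < min_coverage) {
    stop(sprintf("invalid session: minute coverage %.1f%% below %.0f%%",
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  missing <- setdiff(0:1439, present)
  if (length(missing)) {
    runs <- split(missing, cumsum(c(1, diff(missing) != 1)))
    run_len <- vapply(runs, length, integer(1))
    if (any(run_len > max_gap)) {
      stop(sprintf("invalid session: gap of %d consecutive minutes exceeds %d",
                   max(run_len), max_gap), call. = FALSE)
    }
    vo2 <- stats::approx(present, trace$vo2, xout = 0:1439, rule = 2)$y
    vco2 <- stats::approx(present, trace$vco2, xout = 0:1439, rule = 2)$y
    trace <- tibble::tibble(minute = 0:1439, vo2 = vo2, vco2 = vco2)
  }
  trace
}

#' Aggregate a chamber day to 24-hour totals
#'
#' Applies the minute-gap policy (linear interpolation of gaps of at most
#' `max_gap` minutes; sessions with longer gaps or below `min_coverage`
#' coverage are rejected), then extrapolates per-minute EE to 24 hours
#' (mean per-minute EE multiplied by 1,440) and computes the 24-hour RQ as
#' the ratio of total VCO2 to total VO2 over retained minutes.
#'
#' @param trace Tibble with columns `minute` (0..1439), `vo2`, `vco2` (L/min).
#' @param max_gap Longest interpolable run of missing minutes.
#' @param min_coverage Minimum fraction of the 1,440 minutes present.
#' @return A one-row tibble: `ee24` (kcal/day), `rq24`, `vo2_24h`, `vco2_24h`
#'   (L/day), `n_minutes` (minutes observed before interpolation).
#' @export
aggregate_24h <- function(trace, max_gap = 5, min_coverage = 0.95) {
  n_obs <- nrow(trace)
  trace <- fill_minute_gaps(trace, max_gap = max_gap, min_coverage = min_coverage)
  rq <- per_minute_rq(trace$vo2, trace$vco2)
  ee <- per_minute_ee(trace$vo2, rq)
  tibble::tibble(
    ee24 = mean(ee) * 1440,
    rq24 = sum(trace$vco2) / sum(trace$vo2),
    vo2_24h = mean(trace$vo2) * 1440,
    vco2_24h = mean(trace$vco2) * 1440,
    n_minutes = n_obs
  )
}

#' Protein oxidation from 24-hour urinary nitrogen
#'
#' @param nitrogen_g_day Urinary nitrogen excretion (g/24 h), nonnegative.
#' @return List with `protox_g` (6.25 g protein per g N) and `protox_kcal`
#'   (at 4.70 kcal/g protein).
#' @export
protein_oxidation <- function(nitrogen_g_day) {
  if (any(nitrogen_g_day < 0)) {
    stop("urinary nitrogen must be nonnegative", call. = FALSE)
  }
  protox_g <- .nitrogen_to_protein * nitrogen_g_day
  list(protox_g = protox_g, protox_kcal = protox_g * .fuel$kcal[["protein"]])
}

#' Nonprotein respiratory quotient
#'
#' Subtracts the gas exchange attributable to protein oxidation (0.966 L O2
#' and 0.782 L CO2 per g protein) from the 24-hour totals before taking the
#' ratio. Values outside (0.69, 1.05) are flagged, not dropped.
#'
#' @param vo2_24h,vco2_24h Total 24-hour gas volumes (L/day).
#' @param protox_g Oxidized protein mass (g/day).
#' @return List with `nprq` and `flag` (`NA` or `"nprq_out_of_range"`).
#' @export
nonprotein_rq <- function(vo2_24h, vco2_24h, protox_g) {
  o2_prot <- .fuel$o2[["protein"]] * protox_g
  co2_prot <- .fuel$co2[["protein"]] * protox_g
  if (o2_prot >= vo2_24h) {
    stop("protein-attributed O2 exceeds total VO2", call. = FALSE)
  }
  nprq <- (vco2_24h - co2_prot) / (vo2_24h - o2_prot)
  flag <- if (nprq <= 0.69 || nprq >= 1.05) "nprq_out_of_range" else NA_character_
  list(nprq = nprq, flag = flag)
}

#' 24-hour substrate oxidation rates
#'
#' Frayn-form inversion of total gas exchange and urinary nitrogen into
#' oxidized carbohydrate, fat and protein masses:
#' `carbox_g = 4.55 VCO2 - 3.21 VO2 - 2.87 N` and
#' `lipox_g = 1.67 (VO2 - VCO2) - 1.92 N` with volumes in L/day and N in
#' g/day. Negative rates (possible at extreme RQ) are retained and flagged
#' rather than clipped so downstream models can exclude them explicitly.
#'
#' @param vo2_24h,vco2_24h Total 24-hour gas volumes (L/day).
#' @param nitrogen_g_day Urinary nitrogen (g/day).
#' @return One-row tibble with oxidized masses (`carbox_g`, `lipox_g`,
#'   `protox_g`), energies (`carbox_kcal`, `lipox_kcal`, `protox_kcal`) and a
#'   `flag` column (`"negative_oxidation"` when any mass is below zero).
#' @export
substrate_oxidation <- function(vo2_24h, vco2_24h, nitrogen_g_day) {
  stopifnot(vo2_24h > 0, vco2_24h >= 0, nitrogen_g_day >= 0)
  protox_g <- .nitrogen_to_protein * nitrogen_g_day
  carbox_g <- .frayn[["carb_vco2"]] * vco2_24h - .frayn[["carb_vo2"]] * vo2_24h -
    .frayn[["carb_n"]] * nitrogen_g_day
  lipox_g <- .frayn[["fat_gas"]] * (vo2_24h - vco2_24h) -
    .frayn[["fat_n"]] * nitrogen_g_day
  flag <- if (carbox_g < 0 || lipox_g < 0) "negative_oxidation" else NA_character_
  tibble::tibble(
    carbox_g = carbox_g,
    lipox_g = lipox_g,
    protox_g = protox_g,
    carbox_kcal = carbox_g * .fuel$kcal[["carb"]],
    lipox_kcal = lipox_g * .fuel$kcal[["fat"]],
    protox_kcal = protox_g * .fuel$kcal[["protein"]],
    flag = flag
  )
}

#' Energy-closure error of a chamber summary
#'
#' Relative mismatch between substrate-derived energy and Lusk energy
#' expenditure: `|carbox + lipox + protox - ee24| / ee24`. A consistency
#' check; small values indicate the two routes from gas exchange to energy
#' agree.
#'
#' @param summary A one-row summary holding `ee24`, `carbox_kcal`,
#'   `lipox_kcal`, `protox_kcal` (e.g. from [summarize_chamber_day()]).
#' @return Closure error as a fraction of `ee24`.
#' @export
energy_closure <- function(summary) {
  substrate <- summary$carbox_kcal + summary$lipox_kcal + summary$protox_kcal
  abs(substrate - summary$ee24) / summary$ee24
}

#' Summarize one chamber session
#'
#' Runs the full indirect-calorimetry computation for a single session:
#' 24-hour EE and RQ from the minute trace, protein oxidation from urinary
#' nitrogen, nonprotein RQ, carbohydrate and lipid oxidation, and the
#' energy-closure error.
#'
#' @param trace Minute-level gas exchange (`minute`, `vo2`, `vco2`).
#' @param nitrogen_g_day 24-hour urinary nitrogen (g).
#' @inheritParams aggregate_24h
#' @return A one-row tibble (`ee24`, `rq24`, `nprq`, oxidation masses and
#'   energies, `closure_error`, `flags`).
#' @export
summarize_chamber_day <- function(trace, nitrogen_g_day,
                                  max_gap = 5, min_coverage = 0.95) {
  agg <- aggregate_24h(trace, max_gap = max_gap, min_coverage = min_coverage)
  ox <- substrate_oxidation(agg$vo2_24h, agg$vco2_24h, nitrogen_g_day)
  np <- nonprotein_rq(agg$vo2_24h, agg$vco2_24h, ox$protox_g)
  out <- dplyr::bind_cols(agg, ox[setdiff(names(ox), "flag")])
  out$nprq <- np$nprq
  out$closure_error <- energy_closure(out)
  flags <- c(ox$flag, np$flag)
  if (out$rq24 <= 0.6 || out$rq24 >= 1.3) flags <- c(flags, "rq24_out_of_range")
  out$flags <- paste(flags[!is.na(flags)], collapse = ";")
  out
}
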