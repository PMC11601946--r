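# Shared fixtures, memoised so heavy simulations run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The study-conditions cohort: generator defaults, fixed seed.
default_sim <- function() {
  cached("sim", simulate_cohort(sim_config(seed = 101)))
}

default_qc <- function() {
  cached("qc", {
    sim <- default_sim()
    run_qc(sim$panel, sim$qc_replicates)
  })
}

default_pooled <- function(outcome) {
  cached(paste0("pooled_", outcome), {
    sim <- default_sim()
    pooled_physiology_model(sim$sessions, default_qc()$fold_changes,
                            sim$participants, outcome = outcome)
  })
}

# Metabolites of one class in the default simulation.
class_members <- function(class) {
  m <- default_sim()$metabolites
  m$metabolite[m$class == class]
}

# Constant-rate trace with the given per-minute gas volumes.
constant_trace <- function(vo2, vco2, minutes = 0:1439) {
  tibble::tibble(minute = minutes, vo2 = vo2, vco2 = vco2)
}

# Forward-stoichiometry day from known oxidized masses (uniform over the
# day); the independent leg of the round-trip oracle uses simulate_trace,
# this builds totals directly from the published per-gram volumes.
forward_totals <- function(carb_g, fat_g, prot_g) {
  st <- fuel_stoichiometry()
  g <- c(carb_g, fat_g, prot_g)
  list(vo2_24h = sum(g * st$o2_l_per_g),
       vco2_24h = sum(g * st$co2_l_per_g),
       nitrogen_g = prot_g / 6.25,
       kcal = sum(g * st$kcal_per_g))
}

# One-metabolite crossover dataset with known diet effects (log2 units),
# randomized chamber order, participant random intercepts.
make_crossover_data <- function(n, effects, participant_sd = 0.15,
                                residual_sd = 0.2, metabolite = "M1") {
  diets <- names(effects)
  stopifnot(diets[1] == "EB")
  rows <- lapply(seq_len(n), function(i) {
    order <- c(1, 1 + sample(length(diets) - 1))
    tibble::tibble(participant_id = sprintf("P%03d", i), diet = diets,
                   chamber_order = order)
  })
  d <- dplyr::bind_rows(rows)
  u <- stats::rnorm(n, 0, participant_sd)
  d$metabolite <- metabolite
  d$pre_log2 <- stats::rnorm(nrow(d), 14, 0.4)
  d$post_log2 <- d$pre_log2 + effects[d$diet] +
    u[match(d$participant_id, sprintf("P%03d", seq_len(n)))] +
    stats::rnorm(nrow(d), 0, residual_sd)
  d$log2fc <- d$post_log2 - d$pre_log2
  d
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  qs <- vapply(seq_len(m),
               function(i) min(sorted[i:m] * m / (i:m)), numeric(1))
  out <- numeric(m)
  out[o] <- pmin(qs, 1)
  out
}
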