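#' Calibrate the normal-weight baseline incidence
#'
#' Population incidence rates reflect the population's weight-status mix.
#' Given the weight-specific relative risks, the incidence among
#' normal-weight individuals solves
#' `i_pop = i_normal * (p_n + p_ow * rr_ow + p_ob * rr_ob)`.
#' Re-mixing `i_normal` with the same distribution recovers `i_pop`
#' exactly; mixing with an arm-specific distribution yields the
#' arm-adjusted incidence.
#'
#' @param i_pop Population annual incidence probability in \[0, 1\].
#' @param dist Reference weight distribution the population rate reflects.
#' @param rr_overweight,rr_obese Relative risks (> 0) versus normal weight.
#' @return Normal-weight baseline incidence.
#' @export
#' @examples
#' calibrate_baseline_incidence(0.01, weight_dist(0.5, 0.3, 0.2), 2.25, 5.50)
calibrate_baseline_incidence <- function(i_pop, dist, rr_overweight, rr_obese) {
  check_weight_dist(dist)
  if (any(i_pop < 0 | i_pop > 1)) stop("population incidence must lie in [0, 1]")
  denom <- dist[["normal"]] + dist[["overweight"]] * rr_overweight +
    dist[["obese"]] * rr_obese
  if (any(denom <= 0)) stop("weight-mixed relative risk denominator is zero")
  i_pop / denom
}

#' Mix a normal-weight baseline incidence over a weight distribution
#'
#' Inverse of [calibrate_baseline_incidence()]:
#' `i = i_normal * (p_n + p_ow * rr_ow + p_ob * rr_ob)`.
#' Results above 1 are clamped with a warning.
#'
#' @inheritParams calibrate_baseline_incidence
#' @param i_normal Normal-weight baseline incidence.
#' @return Annual incidence probability under `dist`.
#' @export
mixed_incidence <- function(i_normal, dist, rr_overweight, rr_obese) {
  check_weight_dist(dist)
  i <- i_normal * (dist[["normal"]] + dist[["overweight"]] * rr_overweight +
    dist[["obese"]] * rr_obese)
  if (any(i > 1)) {
    warning("mixed incidence exceeded 1 and was clamped")
    i <- pmin(i, 1)
  }
  i
}

#' Annual transition probability for diabetic patients
#'
#' Diabetic patients develop comorbidities at a multiple of the healthy
#' (at-risk) probability.  The default applies the relative risk
#' multiplicatively to the annual probability and caps at 1; the rate mode
#' applies it on the constant-hazard scale,
#' `1 - (1 - p)^rr`, which stays below 1 for any baseline.
#'
#' @param p_base At-risk annual transition probability.
#' @param rr Relative risk for diabetic patients (> 0).
#' @param mode `"product"` (default) or `"rate"`.
#' @return Adjusted annual probability.
#' @export
diabetic_transition <- function(p_base, rr, mode = c("product", "rate")) {
  mode <- match.arg(mode)
  if (any(p_base < 0 | p_base > 1)) stop("baseline probability must lie in [0, 1]")
  if (mode == "product") {
    pmin(1, p_base * rr)
  } else {
    1 - exp(-rr * (-log(1 - p_base)))
  }
}

# ---- per-stratum rate lookups ----------------------------------------------

# Expand band-keyed values (age_lo ascending) to per-age vectors over `ages`.
band_expand <- function(age_lo, value, ages) {
  o <- order(age_lo)
  value[o][findInterval(ages, age_lo[o])]
}

# Precompute all age-indexed rates and relative risks for one
# (country, sex); ages 30..99, index age - 29.
stratum_rates <- function(pack, country, sex) {
  ages <- 30:99
  ep <- pack$epidemiology[pack$epidemiology$country == country &
                            pack$epidemiology$sex == sex, ]
  if (nrow(ep) == 0) stop("no epidemiology for ", country, "/", sex)
  get_series <- function(measure, disease = NA) {
    rows <- ep[ep$measure == measure &
                 (if (is.na(disease)) is.na(ep$disease) else !is.na(ep$disease) & ep$disease == disease), ]
    if (nrow(rows) == 0) stop("missing epidemiology cell: ", country, "/", sex, "/", measure,
                              if (!is.na(disease)) paste0("/", disease) else "")
    band_expand(rows$age_lo, rows$value, ages)
  }
  rrt <- pack$rr_table[pack$rr_table$sex == sex, ]
  get_rr <- function(population, outcome, weight_status = NA) {
    rows <- rrt[rrt$population == population & rrt$outcome == outcome &
                  (if (is.na(weight_status)) is.na(rrt$weight_status)
                   else !is.na(rrt$weight_status) & rrt$weight_status == weight_status), ]
    if (nrow(rows) == 0) return(NULL)
    band_expand(rows$age_lo, rows$rr, ages)
  }

  diseases <- disease_names()
  inc <- lapply(stats::setNames(diseases, diseases), function(d) get_series("incidence", d))
  cf1 <- lapply(stats::setNames(c("stroke", "chd", "crc", "bc"), c("stroke", "chd", "crc", "bc")),
                function(d) get_series("case_fatality_first", d))
  cf2 <- lapply(stats::setNames(c("stroke", "chd", "crc", "bc"), c("stroke", "chd", "crc", "bc")),
                function(d) get_series("case_fatality_followup", d))

  rr_ow <- lapply(stats::setNames(c("all_cause_mortality", diseases),
                                  c("all_cause_mortality", diseases)),
                  function(o) get_rr("at_risk", o, "overweight"))
  rr_ob <- lapply(stats::setNames(c("all_cause_mortality", diseases),
                                  c("all_cause_mortality", diseases)),
                  function(o) get_rr("at_risk", o, "obese"))
  rr_dm <- lapply(stats::setNames(c("all_cause_mortality", "stroke", "chd", "crc", "bc"),
                                  c("all_cause_mortality", "stroke", "chd", "crc", "bc")),
                  function(o) get_rr("diabetic", o))

  wp <- pack$weight_prevalence
  nat <- wp[wp$population == "adult" & wp$country == country & wp$sex == sex, ]
  ref_dist <- weight_dist(nat$p_normal, nat$p_overweight, nat$p_obese)

  list(
    ages = ages, sex = sex, country = country,
    m = get_series("all_cause_mortality"),
    inc = inc, cf1 = cf1, cf2 = cf2,
    rr_ow = rr_ow, rr_ob = rr_ob, rr_dm = rr_dm,
    ref_dist = ref_dist
  )
}

mix_rr <- function(dist, rr_ow, rr_ob) {
  dist[["normal"]] + dist[["overweight"]] * rr_ow + dist[["obese"]] * rr_ob
}

#' Annual death probability by health state
#'
#' At-risk members die at the all-cause rate scaled by the weight-mixed
#' all-cause mortality relative risk; diabetic members at the all-cause
#' rate times the diabetic mortality relative risk; disease-state members
#' at the disease- and phase-specific case fatality.  Capped at 1.
#'
#' @param pack A `parameter_pack`.
#' @param country,sex Stratum.
#' @param state A health-state name (see [health_states()]).
#' @param age Current age (30-99; older ages reuse the oldest band).
#' @param arm_dist Arm weight distribution (used for the at-risk state).
#' @return Annual death probability.
#' @export
death_probability <- function(pack, country, sex, state, age, arm_dist) {
  rates <- stratum_rates(pack, country, sex)
  death_probability_(rates, state, min(age, 99) - 29, arm_dist)
}

death_probability_ <- function(rates, state, k, arm_dist) {
  st <- health_states()
  row <- st[st$state == state, ]
  if (nrow(row) != 1) stop("unknown state: ", state)
  p <- switch(row$phase,
    entry = rates$m[k] * mix_rr(arm_dist,
      rates$rr_ow$all_cause_mortality[k], rates$rr_ob$all_cause_mortality[k]),
    chronic = rates$m[k] * rates$rr_dm$all_cause_mortality[k],
    first = rates$cf1[[row$disease]][k],
    followup = rates$cf2[[row$disease]][k],
    absorbing = 0
  )
  min(1, p)
}

# ---- transition matrices ----------------------------------------------------

# Vectorised over all ages: weight-mixed at-risk incidences (calibrated
# against the national mix), at-risk and diabetic death probabilities, and
# diabetic comorbidity incidences.  Returns per-age vectors/matrices.
arm_rates_ <- function(rates, arm_dist, mode = "product") {
  male <- rates$sex == "male"
  diseases <- disease_names()
  nk <- length(rates$ages)
  mix_ref <- function(ow, ob) {
    rates$ref_dist[["normal"]] + rates$ref_dist[["overweight"]] * ow +
      rates$ref_dist[["obese"]] * ob
  }
  mix_arm <- function(ow, ob) {
    arm_dist[["normal"]] + arm_dist[["overweight"]] * ow +
      arm_dist[["obese"]] * ob
  }
  d_ar <- pmin(1, rates$m * mix_arm(rates$rr_ow$all_cause_mortality,
                                    rates$rr_ob$all_cause_mortality))
  inc_ar <- sapply(diseases, function(dis) {
    if (dis == "bc" && male) return(numeric(nk))
    ow <- rates$rr_ow[[dis]]; ob <- rates$rr_ob[[dis]]
    pmin(1, rates$inc[[dis]] / mix_ref(ow, ob) * mix_arm(ow, ob))
  })
  d_dm <- pmin(1, rates$m * rates$rr_dm$all_cause_mortality)
  inc_dm <- sapply(c("stroke", "chd", "crc", "bc"), function(dis) {
    if (dis == "bc" && male) return(numeric(nk))
    if (mode == "product") {
      pmin(1, inc_ar[, dis] * rates$rr_dm[[dis]])
    } else {
      1 - (1 - inc_ar[, dis])^rates$rr_dm[[dis]]
    }
  })
  list(d_ar = d_ar, inc_ar = inc_ar, d_dm = d_dm, inc_dm = inc_dm)
}

build_matrix_ <- function(rates, k, arm_dist, mode = "product",
                          ar = arm_rates_(rates, arm_dist, mode)) {
  sn <- state_names()
  P <- matrix(0, 11, 11, dimnames = list(sn, sn))
  first_of <- c(diabetes = "Diabetes", stroke = "Stroke1", chd = "CHD1",
                crc = "CRC1", bc = "BC1")

  # at-risk row: death claimed first, incidences rescaled if they would
  # exceed the residual mass
  d <- ar$d_ar[k]
  inc <- ar$inc_ar[k, ]
  if (sum(inc) > 1 - d) {
    warning("at-risk outgoing transitions exceeded the residual after death; rescaled")
    inc <- inc * (1 - d) / sum(inc)
  }
  P["AtRisk", "Death"] <- d
  P["AtRisk", first_of] <- inc
  P["AtRisk", "AtRisk"] <- 1 - d - sum(inc)

  # diabetes row
  d <- ar$d_dm[k]
  inc <- ar$inc_dm[k, ]
  if (sum(inc) > 1 - d) {
    warning("diabetic outgoing transitions exceeded the residual after death; rescaled")
    inc <- inc * (1 - d) / sum(inc)
  }
  P["Diabetes", "Death"] <- d
  P["Diabetes", first_of[c("stroke", "chd", "crc", "bc")]] <- inc
  P["Diabetes", "Diabetes"] <- 1 - d - sum(inc)

  # tunnel and follow-up rows: stay alive = 1 - death
  for (dis in c("stroke", "chd", "crc", "bc")) {
    s1 <- first_of[[dis]]; s2 <- paste0(s1, "plus")
    d1 <- min(1, rates$cf1[[dis]][k])
    d2 <- min(1, rates$cf2[[dis]][k])
    P[s1, "Death"] <- d1
    P[s1, s2] <- 1 - d1
    P[s2, "Death"] <- d2
    P[s2, s2] <- 1 - d2
  }
  P["Death", "Death"] <- 1
  P
}

#' Build one annual transition matrix
#'
#' Assembles the 11x11 row-stochastic transition matrix for a stratum at a
#' given age under an arm-specific weight-status distribution.  The at-risk
#' row carries weight-mixed disease incidences (calibrated so the national
#' weight mix reproduces the national rates) and weight-mixed all-cause
#' mortality; the diabetes row scales the at-risk incidences by the
#' diabetic comorbidity relative risks and mortality by the diabetic
#' mortality relative risk; first-year states pass to their follow-up
#' partner with probability one minus death; death is absorbing.  Male
#' strata have a zero breast-cancer column.  Death is claimed first; if
#' outgoing disease transitions would exceed the remaining mass they are
#' rescaled proportionally with a warning.
#'
#' @inheritParams death_probability
#' @param arm_dist Weight distribution of the arm.
#' @return 11x11 matrix with state dimnames, rows summing to 1.
#' @export
build_transition_matrix <- function(pack, country, sex, age, arm_dist) {
  rates <- stratum_rates(pack, country, sex)
  build_matrix_(rates, min(age, 99) - 29, arm_dist,
                pack$manifest$transition_mode %||% "product")
}

# All matrices for ages 30..99 for one stratum/arm (list indexed age - 29).
transition_matrices <- function(pack, country, sex, arm_dist) {
  rates <- stratum_rates(pack, country, sex)
  mode <- pack$manifest$transition_mode %||% "product"
  ar <- arm_rates_(rates, arm_dist, mode)
  lapply(seq_along(rates$ages), function(k) {
    build_matrix_(rates, k, arm_dist, mode, ar)
  })
}

# Iterate a trace: init (length 11), matrices[[t]] used for cycle t.
markov_trace <- function(matrices, init, n_cycles = length(matrices)) {
  occ <- matrix(0, n_cycles + 1, length(init),
                dimnames = list(NULL, names(init)))
  occ[1, ] <- init
  cur <- init
  for (t in seq_len(n_cycles)) {
    M <- matrices[[min(t, length(matrices))]]
    cur <- as.numeric(cur %*% M)
    occ[t + 1, ] <- cur
  }
  occ
}

#' Run the Markov cohort model
#'
#' Runs the cohort through 70 one-year cycles (by default), starting
#' entirely in the at-risk state.  The entry schedule spreads the cohort
#' over entry ages (parents; see [parent_entry_schedule()]) or places it all
#' at the entry age of 30 (children).  Cycle `t` of a sub-cohort entering at
#' age `a` uses the transition matrix for age `a + t - 1`; ages beyond the
#' oldest band reuse the oldest band's parameters.
#'
#' @inheritParams build_transition_matrix
#' @param entry_schedule Tibble with `age` and `weight` (summing to 1), or
#'   `NULL` for everyone at the manifest entry age.
#' @param n_cycles Number of one-year cycles (default from the manifest).
#' @return A `cohort_trace`: list with `by_entry` (tibble `entry_age`,
#'   `weight`, `cycle`, `age`, `state`, `occupancy`) and `trace` (the
#'   entry-weighted combined tibble `cycle`, `state`, `occupancy`).
#' @export
run_cohort <- function(pack, country, sex, arm_dist, entry_schedule = NULL,
                       n_cycles = NULL) {
  n_cycles <- n_cycles %||% pack$manifest$n_cycles
  if (is.null(entry_schedule)) {
    entry_schedule <- tibble::tibble(age = pack$manifest$entry_age, weight = 1)
  }
  if (abs(sum(entry_schedule$weight) - 1) > 1e-9) {
    stop("entry weights must sum to 1")
  }
  rates <- stratum_rates(pack, country, sex)
  mode <- pack$manifest$transition_mode %||% "product"
  ar <- arm_rates_(rates, arm_dist, mode)
  mats <- lapply(seq_along(rates$ages), function(k) {
    build_matrix_(rates, k, arm_dist, mode, ar)
  })
  sn <- state_names()
  init <- stats::setNames(c(1, rep(0, 10)), sn)

  by_entry <- purrr::pmap_dfr(entry_schedule, function(age, weight) {
    cycle_mats <- lapply(seq_len(n_cycles), function(t) {
      mats[[min(age + t - 1, 99) - 29]]
    })
    occ <- markov_trace(cycle_mats, init, n_cycles)
    tibble::tibble(
      entry_age = age, weight = weight,
      cycle = rep(0:n_cycles, each = 11),
      age = pmin(age + rep(0:n_cycles, each = 11), 99),
      state = rep(sn, n_cycles + 1),
      occupancy = as.numeric(t(occ))
    )
  })
  trace <- by_entry |>
    dplyr::group_by(.data$cycle, .data$state) |>
    dplyr::summarise(occupancy = sum(.data$weight * .data$occupancy), .groups = "drop")
  structure(
    list(by_entry = by_entry, trace = trace, country = country, sex = sex,
         arm_dist = arm_dist, n_cycles = n_cycles),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace>", x$country, x$sex, "-", x$n_cycles, "cycles\n")
  final <- x$trace[x$trace$cycle == x$n_cycles, ]
  cat("  final death occupancy:", round(final$occupancy[final$state == "Death"], 4), "\n")
  invisible(x)
}

#' Microsimulation oracle for the cohort model
#'
#' Simulates `n` individuals through the same per-age transition matrices
#' the cohort model uses, by multinomial sampling of each cycle's
#' transitions.  The cohort trace is the exact expectation of this
#' simulation, so the two agree within binomial sampling error; the
#' function exists as an independent validation path for the deterministic
#' engine.
#'
#' @inheritParams run_cohort
#' @param n Number of simulated individuals.
#' @param seed Integer seed (reproducible).
#' @param entry_age Single entry age (default: manifest entry age).
#' @return Tibble `cycle`, `state`, `occupancy` (fractions of `n`).
#' @export
microsim_oracle <- function(pack, country, sex, arm_dist, n = 1000, seed = 1,
                            entry_age = NULL, n_cycles = NULL) {
  stopifnot(n >= 1)
  n_cycles <- n_cycles %||% pack$manifest$n_cycles
  entry_age <- entry_age %||% pack$manifest$entry_age
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  rates <- stratum_rates(pack, country, sex)
  mode <- pack$manifest$transition_mode %||% "product"
  ar <- arm_rates_(rates, arm_dist, mode)
  sn <- state_names()
  counts <- stats::setNames(c(n, rep(0, 10)), sn)
  occ <- matrix(0, n_cycles + 1, 11, dimnames = list(NULL, sn))
  occ[1, ] <- counts
  for (t in seq_len(n_cycles)) {
    k <- min(entry_age + t - 1, 99) - 29
    M <- build_matrix_(rates, k, arm_dist, mode, ar)
    nxt <- stats::setNames(numeric(11), sn)
    for (s in which(counts > 0)) {
      nxt <- nxt + as.numeric(stats::rmultinom(1, counts[s], M[s, ]))
    }
    counts <- nxt
    occ[t + 1, ] <- counts
  }
  tibble::tibble(
    cycle = rep(0:n_cycles, each = 11),
    state = rep(sn, n_cycles + 1),
    occupancy = as.numeric(t(occ)) / n
  )
}
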