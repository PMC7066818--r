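#' Relapse adjustment of follow-up values
#'
#' Follow-up years carry better utilities and lower costs than the first
#' year after diagnosis, but patients risk a relapse.  The adjusted
#' follow-up value is the relapse-probability-weighted mean
#' `(1 - p) * value_followup + p * value_first`.
#'
#' @param value_first First-year value (utility or cost).
#' @param value_followup Follow-up value.
#' @param p_relapse Annual relapse probability in \[0, 1\].
#' @return Adjusted follow-up value.
#' @export
relapse_adjust <- function(value_first, value_followup, p_relapse) {
  if (any(p_relapse < 0 | p_relapse > 1)) stop("relapse probability must lie in [0, 1]")
  (1 - p_relapse) * value_followup + p_relapse * value_first
}

#' Discount factor with lead time
#'
#' `(1 + rate)^-(t + lead)`.  The lead accounts for cohorts whose
#' discounting clock started before Markov entry: for children the clock
#' runs from the intervention (mean age 8.2) to adult entry at 30, so all
#' their effects and costs are discounted by the lead years on top of the
#' cycle index.
#'
#' @param rate Annual discount rate (>= 0).
#' @param t Cycle index (years since Markov entry).
#' @param lead Lead-time years before entry (default 0).
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, t, lead = 0) {
  if (any(rate < 0)) stop("discount rate must be non-negative")
  (1 + rate)^-(t + lead)
}

# ---- state utilities --------------------------------------------------------

# Named utility lookup for every (state, age) combination; relapse-adjusted
# follow-up decrements, clamped to [0, 1]; Death = 0.
state_utility_fun <- function(pack, sex) {
  ub <- pack$utility_baseline[pack$utility_baseline$sex == sex, ]
  if (nrow(ub) == 0) stop("missing baseline utilities for sex ", sex)
  ud <- pack$utility_decrements
  st <- health_states()
  dec <- stats::setNames(numeric(11), st$state)
  for (i in seq_len(11)) {
    if (st$phase[i] %in% c("entry", "absorbing")) next
    row <- ud[ud$disease == st$disease[i], ]
    if (nrow(row) != 1) stop("missing utility decrement for disease ", st$disease[i])
    dec[i] <- switch(st$phase[i],
      chronic = row$dec_first,
      first = row$dec_first,
      followup = relapse_adjust(row$dec_first, row$dec_followup, row$relapse)
    )
  }
  function(state, age) {
    u0 <- band_expand(ub$age_lo, ub$utility, pmin(age, 99))
    u <- u0 - dec[state]
    u[state == "Death"] <- 0
    pmin(pmax(u, 0), 1)
  }
}

#' Discounted QALYs from a cohort trace
#'
#' Sums occupancy times state utility times the effect discount factor over
#' cycles 1..T.  Utilities are the age- and sex-specific baseline minus the
#' disease decrement (relapse-adjusted in follow-up states); death
#' contributes zero.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param pack A `parameter_pack`.
#' @param rate Effect discount rate; default from the manifest (1.50%).
#' @param lead Lead-time years (children: manifest `child_lead_years`).
#' @return Discounted QALYs per cohort member.
#' @export
qalys_from_trace <- function(trace, pack, rate = NULL, lead = 0) {
  rate <- rate %||% pack$manifest$discount_effects
  ufun <- state_utility_fun(pack, trace$sex)
  df <- trace$by_entry |> dplyr::filter(.data$cycle >= 1)
  sum(df$weight * df$occupancy * ufun(df$state, df$age) *
        discount_factor(rate, df$cycle, lead))
}

# ---- state costs ------------------------------------------------------------

# Annual cost lookup per (state, age) for one country.
# direct + indirect (multiplier- or ratio-derived; stroke indirect = direct),
# plus the diabetes-comorbidity add-on (share of the total diabetes cost),
# relapse-adjusted in follow-up states.  Diabetes costs split at age 55,
# other diseases at 65.
state_cost_fun <- function(pack, country, perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  cs <- pack$costs[pack$costs$country == country, ]
  if (nrow(cs) == 0) stop("no costs for country ", country)
  man <- pack$manifest
  mult <- unlist(man$indirect_multipliers)
  frac <- unlist(man$comorbidity_fractions)

  direct_of <- function(disease, phase, age) {
    rows <- cs[cs$disease == disease & cs$phase == phase, ]
    if (nrow(rows) == 0 || any(is.na(rows$direct))) {
      stop("missing cost cell: ", country, "/", disease, "/", phase)
    }
    band_expand(rows$age_lo, rows$direct, age)
  }
  total_of <- function(disease, phase, age) {
    d <- direct_of(disease, phase, age)
    im <- if (disease == "crc") man$crc_indirect_ratio else mult[[disease]]
    ind <- if (perspective == "societal") d * im else 0
    tot <- d + ind
    if (disease != "diabetes") { # diabetes-as-comorbidity add-on
      tot <- tot + frac[[disease]] * total_of("diabetes", "chronic", age)
    }
    tot
  }

  st <- health_states()
  function(state, age) {
    n <- max(length(state), length(age))
    state <- rep_len(state, n)
    age <- rep_len(age, n)
    out <- numeric(n)
    for (s in unique(state)) {
      i <- st$state == s
      sel <- state == s
      if (!any(i) || st$phase[i] %in% c("entry", "absorbing")) next
      dis <- st$disease[i]
      out[sel] <- switch(st$phase[i],
        chronic = total_of(dis, "chronic", age[sel]),
        first = total_of(dis, "first", age[sel]),
        followup = {
          row <- pack$utility_decrements[pack$utility_decrements$disease == dis, ]
          relapse_adjust(
            total_of(dis, "first", age[sel]),
            total_of(dis, "followup", age[sel]),
            row$relapse
          )
        }
      )
    }
    out
  }
}

#' Friction-cost of one death
#'
#' Productivity loss of a death at working age, valued over the friction
#' period only: hours worked within the period times the hourly
#' productivity cost, adjusted for the country's unemployment rate and for
#' labour-time elasticity (production drops 8% when labour time drops 10%
#' at the default elasticity of 0.8).  Zero outside the eligible age window
#' (30-64 by default).
#'
#' @param pack A `parameter_pack`.
#' @param country Country.
#' @param age Age at death.
#' @return EUR (2016) per death.
#' @export
friction_death_cost <- function(pack, country, age) {
  man <- pack$manifest
  fr <- pack$friction[pack$friction$country == country, ]
  if (nrow(fr) != 1) stop("no friction parameters for ", country)
  eligible <- age >= man$friction_age_min & age <= man$friction_age_max
  ifelse(eligible,
    fr$hours * fr$cost_per_hour * (1 - fr$unemployment) * man$friction_elasticity,
    0
  )
}

#' Production loss under labour-time elasticity
#'
#' The friction-cost method scales lost labour time by the labour-time
#' elasticity: a fractional labour-time reduction `x` translates into a
#' production loss of `x * elasticity` (10% less labour time -> 8% less
#' production at the default elasticity of 0.8).
#'
#' @param labour_time_reduction Fractional reduction in labour time.
#' @param elasticity Labour-time elasticity in (0, 1\].
#' @return Fractional production loss.
#' @export
production_loss <- function(labour_time_reduction, elasticity = 0.8) {
  if (elasticity <= 0 || elasticity > 1) stop("elasticity must lie in (0, 1]")
  labour_time_reduction * elasticity
}

#' Per-cycle cost stream of a cohort trace
#'
#' Undiscounted annual costs per cohort member, split into direct and
#' indirect disease costs and friction-cost productivity losses from new
#' deaths at working age.  Feeds both the discounted totals
#' ([costs_from_trace()]) and the budget impact analysis (which uses the
#' direct component only).
#'
#' @inheritParams qalys_from_trace
#' @param country Country the cohort lives in.
#' @return Tibble `cycle`, `direct`, `indirect`, `friction`.
#' @export
cost_stream <- function(trace, pack, country) {
  cf_dir <- state_cost_fun(pack, country, "payer")      # direct only
  cf_all <- state_cost_fun(pack, country, "societal")   # direct + indirect

  df <- trace$by_entry |> dplyr::filter(.data$cycle >= 1)
  unit_direct <- cf_dir(df$state, df$age)
  unit_total <- cf_all(df$state, df$age)
  disease <- df |>
    dplyr::mutate(direct = .data$weight * .data$occupancy * unit_direct,
                  indirect = .data$weight * .data$occupancy * (unit_total - unit_direct)) |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(direct = sum(.data$direct), indirect = sum(.data$indirect),
                     .groups = "drop")

  deaths <- trace$by_entry |>
    dplyr::filter(.data$state == "Death") |>
    dplyr::group_by(.data$entry_age) |>
    dplyr::arrange(.data$cycle, .by_group = TRUE) |>
    dplyr::mutate(new_deaths = .data$occupancy - dplyr::lag(.data$occupancy, default = 0)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$cycle >= 1) |>
    dplyr::mutate(friction = .data$weight * .data$new_deaths *
                    friction_death_cost(pack, country, .data$age)) |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(friction = sum(.data$friction), .groups = "drop")

  dplyr::left_join(disease, deaths, by = "cycle") |>
    dplyr::mutate(friction = tidyr::replace_na(.data$friction, 0))
}

#' Discounted costs from a cohort trace
#'
#' Discounts the per-cycle cost stream at the cost rate and returns the
#' breakdown.  Under the payer perspective indirect disease costs and
#' friction costs are dropped.
#'
#' @inheritParams cost_stream
#' @param rate Cost discount rate; default from the manifest (3%).
#' @param lead Lead-time years.
#' @param perspective `"societal"` (default) or `"payer"`.
#' @return One-row tibble `disease_direct`, `disease_indirect`, `friction`,
#'   `total`, per cohort member.
#' @export
costs_from_trace <- function(trace, pack, country, rate = NULL, lead = 0,
                             perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  rate <- rate %||% pack$manifest$discount_costs
  stream <- cost_stream(trace, pack, country)
  d <- discount_factor(rate, stream$cycle, lead)
  direct <- sum(stream$direct * d)
  indirect <- if (perspective == "societal") sum(stream$indirect * d) else 0
  frict <- if (perspective == "societal") sum(stream$friction * d) else 0
  tibble::tibble(
    disease_direct = direct, disease_indirect = indirect, friction = frict,
    total = direct + indirect + frict
  )
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' `ICER = (C_int - C_ctrl) / (Q_int - Q_ctrl)`.  When the intervention
#' gains QALYs at no extra cost it is `dominant`; when it loses QALYs at no
#' saving it is `dominated`; when the QALY difference is zero the ratio is
#' undefined and flagged rather than divided.
#'
#' @param cost_int,cost_ctrl Discounted costs per arm.
#' @param qaly_int,qaly_ctrl Discounted QALYs per arm.
#' @return One-row tibble `delta_cost`, `delta_qaly`, `icer`, `status`
#'   (`"tradeoff"`, `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
#' @examples
#' icer(1000, 0, 0.5, 0) # 2000 EUR/QALY
icer <- function(cost_int, cost_ctrl, qaly_int, qaly_ctrl) {
  dc <- cost_int - cost_ctrl
  dq <- qaly_int - qaly_ctrl
  status <- dplyr::case_when(
    dq == 0 ~ "undefined",
    dq > 0 & dc <= 0 ~ "dominant",
    dq < 0 & dc >= 0 ~ "dominated",
    TRUE ~ "tradeoff"
  )
  tibble::tibble(
    delta_cost = dc, delta_qaly = dq,
    icer = ifelse(dq == 0, NA_real_, dc / dq),
    status = status
  )
}

#' Rescale outcomes to a standard cohort of 1000 targeted children
#'
#' QALYs and costs are linear in cohort size, so reporting per 1000 targeted
#' boys or girls is a rescaling by `1000 / cohort_size`.
#'
#' @param x Value(s) observed for `cohort_size` members.
#' @param cohort_size Number of members the values refer to (> 0).
#' @return Value(s) per 1000.
#' @export
scale_per_1000 <- function(x, cohort_size) {
  if (any(cohort_size <= 0)) stop("cohort size must be > 0")
  x * 1000 / cohort_size
}
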