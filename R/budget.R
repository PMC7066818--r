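#' Implementation years within a budget-impact horizon
#'
#' The intervention is re-implemented every `period` years (default 3)
#' starting in year 1: years `1, 1 + period, 1 + 2 period, ...` up to the
#' horizon.
#'
#' @param horizon Horizon in years (1-30 in the published design).
#' @param period Re-implementation period in years (>= 1).
#' @return Integer vector of implementation years.
#' @export
#' @examples
#' implementation_schedule(30) # 10 implementations
implementation_schedule <- function(horizon, period = 3) {
  stopifnot(horizon >= 1, period >= 1)
  seq(1L, as.integer(horizon), by = as.integer(period))
}

#' Budget impact analysis from the payer perspective
#'
#' Undiscounted annual net cost to the healthcare budget holder of rolling
#' the intervention out to a stable target population, re-implemented every
#' three years.  Only ledger items borne by the healthcare budget holder
#' count (families' transport and time costs are excluded).  Cost offsets
#' are the avoided direct healthcare costs in the *parents* of each
#' implementation cohort, accruing from that cohort's own first year and
#' stacking across successive implementations; children's avoided costs
#' fall beyond the horizon (their benefits only start at adult age) and
#' contribute zero.
#'
#' @param pack A `parameter_pack`.
#' @param country Country to evaluate.
#' @param horizon Horizon in years (1-30).
#' @param period Re-implementation period (default 3 years).
#' @param n_families Target population per implementation (default: the
#'   pack's cohort definition; constant over time).
#' @return A `bia_result` tibble: `year`, `intervention_cost`, `offset`,
#'   `net`, `cumulative`.
#' @export
run_bia <- function(pack, country, horizon = 30, period = 3,
                    n_families = NULL) {
  stopifnot(horizon >= 1, horizon <= 30)
  coh <- pack$cohorts[pack$cohorts$country == country, ]
  if (nrow(coh) != 1) stop("no cohort definition for ", country)
  n_families <- n_families %||% coh$n_families
  payer_cost <- sum(intervention_cost_totals(pack, country, "payer"))
  years <- seq_len(as.integer(horizon))
  impl <- implementation_schedule(horizon, period)

  # avoided direct healthcare costs per parent pair per year since their
  # implementation (undiscounted, payer perspective: direct costs only)
  ppf <- pack$manifest$parents_per_family %||% 2
  offset_stream <- numeric(horizon)
  for (sx in c("male", "female")) {
    dists <- arm_distributions(pack, country, sx, "adult")
    sched <- parent_entry_schedule(pack$age_groups[pack$age_groups$sex == sx, ])
    stream_of <- function(dist) {
      tr <- run_cohort(pack, country, sx, dist, sched, n_cycles = min(horizon, 70))
      cost_stream(tr, pack, country)$direct
    }
    avoided <- stream_of(dists$control) - stream_of(dists$intervention)
    k <- seq_len(min(horizon, length(avoided)))
    offset_stream[k] <- offset_stream[k] + ppf / 2 * n_families * avoided[k]
  }

  offsets <- numeric(horizon)
  for (y0 in impl) {
    k <- y0:horizon
    offsets[k] <- offsets[k] + offset_stream[seq_along(k)]
  }

  out <- tibble::tibble(
    year = years,
    intervention_cost = ifelse(years %in% impl, payer_cost, 0),
    offset = offsets,
    net = intervention_cost - offsets
  )
  out$cumulative <- cumsum(out$net)
  class(out) <- c("bia_result", class(out))
  out
}
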