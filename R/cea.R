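#' Intervention cost totals per component
#'
#' Sums the intervention cost ledger by component (school-based versus
#' high-risk-family) for one country.  Under the payer perspective only
#' items borne by the healthcare budget holder count (families' transport
#' and time costs drop out).
#'
#' @param pack A `parameter_pack`.
#' @param country Country.
#' @param perspective `"societal"` or `"payer"`.
#' @return Named numeric vector `c(school = , hrf = )` (EUR 2016, per
#'   implementation, for the country's targeted cohort).
#' @export
intervention_cost_totals <- function(pack, country,
                                     perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  led <- pack$intervention_costs[pack$intervention_costs$country == country, ]
  if (nrow(led) == 0) stop("no intervention cost ledger for ", country)
  if (perspective == "payer") led <- led[led$payer == "healthcare", ]
  out <- c(school = 0, hrf = 0)
  agg <- tapply(led$amount, led$component, sum)
  out[names(agg)] <- agg
  out
}

# Per-person discounted outcomes for one cohort (population x sex x arm).
cohort_outcomes <- function(pack, country, sex, arm_dist, entry_schedule,
                            lead, perspective) {
  tr <- run_cohort(pack, country, sex, arm_dist, entry_schedule)
  q <- qalys_from_trace(tr, pack, lead = lead)
  cc <- costs_from_trace(tr, pack, country, lead = lead, perspective = perspective)
  list(qalys = q, costs = cc, trace = tr)
}

#' Run the base-case cost-effectiveness analysis for one country
#'
#' Full pipeline: resolves per-arm weight-status distributions (children
#' through the tracking matrix, parents through the age-group entry
#' schedule), runs the 70-cycle Markov cohort per arm, discounts QALYs
#' (1.50%) and costs (3%) with childhood lead-time discounting for the
#' child cohorts, adds intervention costs, and reports outcomes per 1000
#' targeted boys and per 1000 targeted girls, stratified by component:
#' `all_families` (school-based costs spread over all families) and `hrf`
#' (high-risk families, carrying both the school-based and the HRF
#' component costs per HRF family).  Each targeted child brings
#' `parents_per_family` parents (one mother, one father by default) into
#' the model.
#'
#' @param pack A `parameter_pack`.
#' @param country Country to evaluate.
#' @param perspective `"societal"` (default) or `"payer"`.
#' @return A `cea_result`: list with `arms` (per report/sex/arm outcome
#'   tibble) and `summary` (per report/sex tibble with `delta_cost`,
#'   `delta_qaly`, `icer`, `status`).
#' @export
#' @examples
#' \donttest{
#' pack <- synthetic_pack(1)
#' res <- run_cea(pack, "Belgium")
#' glance(res)
#' }
run_cea <- function(pack, country, perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  man <- pack$manifest
  sexes <- c(male = "male", female = "female")
  arms <- c(control = "control", intervention = "intervention")

  # per-person discounted outcomes for every population x sex x arm
  per_person <- list()
  for (sx in sexes) {
    dists_child <- arm_distributions(pack, country, sx, "child")
    dists_adult <- arm_distributions(pack, country, sx, "adult")
    sched <- parent_entry_schedule(pack$age_groups[pack$age_groups$sex == sx, ])
    for (arm in arms) {
      per_person[[paste("child", sx, arm, sep = ".")]] <-
        cohort_outcomes(pack, country, sx, dists_child[[arm]], NULL,
                        man$child_lead_years, perspective)
      per_person[[paste("adult", sx, arm, sep = ".")]] <-
        cohort_outcomes(pack, country, sx, dists_adult[[arm]], sched,
                        0, perspective)
    }
  }

  coh <- pack$cohorts[pack$cohorts$country == country, ]
  if (nrow(coh) != 1) stop("no cohort definition for ", country)
  ic <- intervention_cost_totals(pack, country, perspective)
  ppf <- man$parents_per_family %||% 2
  # intervention cost per 1000 targeted children, by component report
  cost_per_1000 <- c(
    all_families = scale_per_1000(ic[["school"]], coh$n_families),
    hrf = scale_per_1000(ic[["school"]], coh$n_families) +
      scale_per_1000(ic[["hrf"]], coh$n_families * coh$hrf_fraction)
  )

  rows <- list()
  for (report in c("all_families", "hrf")) {
    for (sx in sexes) {
      for (arm in arms) {
        child <- per_person[[paste("child", sx, arm, sep = ".")]]
        mum <- per_person[[paste("adult", "female", arm, sep = ".")]]
        dad <- per_person[[paste("adult", "male", arm, sep = ".")]]
        # 1000 targeted children of this sex, each with ppf parents
        q <- 1000 * (child$qalys + ppf / 2 * (mum$qalys + dad$qalys))
        cdis <- 1000 * (child$costs$disease_direct + child$costs$disease_indirect +
          ppf / 2 * (mum$costs$disease_direct + mum$costs$disease_indirect +
                     dad$costs$disease_direct + dad$costs$disease_indirect))
        cfr <- 1000 * (child$costs$friction +
          ppf / 2 * (mum$costs$friction + dad$costs$friction))
        cint <- if (arm == "intervention") cost_per_1000[[report]] else 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          report = report, sex = sx, arm = arm,
          qalys = q, cost_disease = cdis, cost_productivity = cfr,
          cost_intervention = cint, cost_total = cdis + cfr + cint
        )
      }
    }
  }
  arms_tbl <- dplyr::bind_rows(rows)

  summary_tbl <- arms_tbl |>
    dplyr::select("report", "sex", "arm", "qalys", "cost_total") |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("qalys", "cost_total")) |>
    dplyr::rowwise() |>
    dplyr::mutate(icer(.data$cost_total_intervention, .data$cost_total_control,
                       .data$qalys_intervention, .data$qalys_control)) |>
    dplyr::ungroup() |>
    dplyr::select("report", "sex", "delta_cost", "delta_qaly", "icer", "status")

  structure(
    list(arms = arms_tbl, summary = summary_tbl, country = country,
         perspective = perspective),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>", x$country, "-", x$perspective, "perspective\n")
  cat("  per 1000 targeted children (EUR 2016, QALYs discounted at 1.5%)\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost-effectiveness result
#'
#' One row per report stratum, sex and arm with discounted QALYs and the
#' cost breakdown per 1000 targeted children.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @export
tidy.cea_result <- function(x, ...) x$arms

#' Summarise a cost-effectiveness result
#'
#' One row per report stratum and sex with the incremental cost, QALY gain,
#' ICER and dominance status.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @export
glance.cea_result <- function(x, ...) {
  dplyr::mutate(x$summary, country = x$country, perspective = x$perspective)
}
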