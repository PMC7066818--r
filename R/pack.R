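#' Parameter pack: the validated container of all model inputs
#'
#' A `parameter_pack` bundles every input the evaluation engine needs:
#' relative-risk tables, SES adjustment factors, behaviour (EBRB) effects,
#' weight-status prevalence, epidemiology (incidence, all-cause mortality,
#' disease case fatality), utilities, annual disease costs, the intervention
#' cost ledger, the child-to-adult weight tracking matrix, parent age-group
#' proportions, cohort definitions, friction-cost labour parameters and a
#' manifest of scalar settings (discount rates, Markov settings, comorbidity
#' fractions, indirect multipliers, health-expenditure ratios).  All monetary
#' values are EUR at 2016 value.
#'
#' @param tables Named list of the component tibbles (see [synthetic_pack()]
#'   for the canonical construction).
#' @param manifest Named list of scalar settings.
#' @return An object of class `parameter_pack`.
#' @seealso [synthetic_pack()], [validate_pack()], [read_pack()],
#'   [write_pack()]
#' @export
new_parameter_pack <- function(tables, manifest) {
  stopifnot(is.list(tables), is.list(manifest))
  pack <- c(tables, list(manifest = manifest))
  pack$states <- health_states()
  structure(pack, class = "parameter_pack")
}

pack_table_names <- function() {
  c(
    "rr_table", "ses_adjust", "ebrb_effects", "weight_prevalence",
    "epidemiology", "utility_baseline", "utility_decrements", "costs",
    "intervention_costs", "tracking", "age_groups", "cohorts", "friction"
  )
}

#' @export
print.parameter_pack <- function(x, ...) {
  cat("<parameter_pack>", x$manifest$currency, "\n")
  cat("  countries:", paste(sort(unique(x$costs$country)), collapse = ", "), "\n")
  cat("  states:", nrow(x$states), " cycles:", x$manifest$n_cycles,
      " entry age:", x$manifest$entry_age, "\n")
  for (nm in pack_table_names()) {
    cat(sprintf("  %-20s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Validate a parameter pack
#'
#' Checks every structural invariant of the pack and returns a report of
#' violations rather than raising conditions: an empty report means the pack
#' is valid.  Checks include: exactly 11 health states; weight-status
#' distributions sum to 1 within 1e-9 with entries in \[0,1\]; all relative
#' risks strictly positive; SES adjustments defined only for overweight and
#' obese; probabilities in \[0,1\]; zero male breast-cancer incidence;
#' utilities in \[0,1\] with first-year utility not above follow-up utility;
#' non-negative costs and ledger amounts; each ledger item carrying exactly
#' one component tag; row-stochastic tracking matrix; comorbidity fractions
#' in \[0,1\]; labour-time elasticity in (0,1\]; non-negative discount rates;
#' Belgium present (reference country) with expenditure ratio 1.
#'
#' @param pack A `parameter_pack`.
#' @return A tibble with columns `table` and `message`, one row per
#'   violation; zero rows when the pack is valid.
#' @export
validate_pack <- function(pack) {
  v <- list()
  flag <- function(table, message) {
    v[[length(v) + 1]] <<- tibble::tibble(table = table, message = message)
  }
  man <- pack$manifest

  if (nrow(pack$states) != 11) {
    flag("states", sprintf("expected 11 health states, found %d", nrow(pack$states)))
  }

  wp <- pack$weight_prevalence
  bad <- abs(wp$p_normal + wp$p_overweight + wp$p_obese - 1) > 1e-9
  if (any(bad)) {
    flag("weight_prevalence", sprintf(
      "%d weight distribution(s) do not sum to 1 (e.g. %s %s %s)",
      sum(bad), wp$country[bad][1], wp$sex[bad][1], wp$population[bad][1]
    ))
  }
  if (any(c(wp$p_normal, wp$p_overweight, wp$p_obese) < 0 |
          c(wp$p_normal, wp$p_overweight, wp$p_obese) > 1)) {
    flag("weight_prevalence", "proportions outside [0, 1]")
  }

  if (any(pack$rr_table$rr <= 0 | !is.finite(pack$rr_table$rr))) {
    flag("rr_table", "relative risks must be finite and > 0")
  }
  if (any(pack$ses_adjust$rr <= 0)) {
    flag("ses_adjust", "SES relative risks must be > 0")
  }
  if (!all(pack$ses_adjust$weight_status %in% c("overweight", "obese"))) {
    flag("ses_adjust", "SES adjustment defined only for overweight and obese")
  }

  eb <- pack$ebrb_effects
  incl <- eb[eb$included, , drop = FALSE]
  if (any(is.na(incl$rr_overweight) | is.na(incl$rr_obese))) {
    flag("ebrb_effects", "included behaviour missing an RR")
  }
  pcols <- c(incl$p_control, incl$p_intervention)
  if (any(is.na(pcols) | pcols < 0 | pcols > 1)) {
    flag("ebrb_effects", "exposure prevalences must lie in [0, 1]")
  }

  ep <- pack$epidemiology
  if (any(is.na(ep$value) | ep$value < 0 | ep$value > 1)) {
    flag("epidemiology", "rates/probabilities must lie in [0, 1]")
  }
  male_bc <- ep$measure == "incidence" & ep$disease == "bc" & ep$sex == "male"
  if (any(ep$value[male_bc & !is.na(ep$disease)] > 0, na.rm = TRUE)) {
    flag("epidemiology", "male breast-cancer incidence must be zero")
  }

  ub <- pack$utility_baseline
  if (any(ub$utility < 0 | ub$utility > 1)) {
    flag("utility_baseline", "baseline utilities must lie in [0, 1]")
  }
  ud <- pack$utility_decrements
  if (any(ud$dec_first < 0 | ud$dec_followup < 0)) {
    flag("utility_decrements", "decrements must be non-negative")
  }
  if (any(ud$dec_first < ud$dec_followup)) {
    flag("utility_decrements",
         "first-year decrement below follow-up decrement (first-year utility must not exceed follow-up utility)")
  }
  if (any(ud$relapse < 0 | ud$relapse > 1)) {
    flag("utility_decrements", "relapse probabilities must lie in [0, 1]")
  }
  if (max(ud$dec_first) > min(ub$utility)) {
    # resulting utilities could dip below 0 for some age band
    worst <- min(ub$utility) - max(ud$dec_first)
    if (worst < 0) flag("utility_decrements", "a decrement exceeds the lowest baseline utility")
  }

  if (any(pack$costs$direct < 0, na.rm = TRUE)) {
    flag("costs", "direct costs must be non-negative")
  }

  ic <- pack$intervention_costs
  if (any(ic$amount < 0)) flag("intervention_costs", "amounts must be non-negative")
  if (!all(ic$component %in% c("school", "hrf"))) {
    flag("intervention_costs", "each item needs exactly one component tag ('school' or 'hrf')")
  }
  if (!all(ic$payer %in% c("healthcare", "societal"))) {
    flag("intervention_costs", "payer tag must be 'healthcare' or 'societal'")
  }

  tr <- as.matrix(pack$tracking[, c("normal", "overweight", "obese")])
  if (any(tr < 0 | tr > 1) || any(abs(rowSums(tr) - 1) > 1e-9)) {
    flag("tracking", "tracking matrix must be row-stochastic with entries in [0, 1]")
  }

  ag <- pack$age_groups
  sums <- tapply(ag$proportion, ag$sex, sum)
  if (any(ag$proportion < 0) || any(abs(sums - 1) > 1e-9)) {
    flag("age_groups", "age-group proportions must be non-negative and sum to 1 per sex")
  }

  fr <- pack$friction
  if (any(fr$unemployment < 0 | fr$unemployment > 1)) {
    flag("friction", "unemployment rates must lie in [0, 1]")
  }
  if (any(fr$hours <= 0 | fr$cost_per_hour < 0)) {
    flag("friction", "hours must be > 0 and hourly productivity cost >= 0")
  }

  cf <- unlist(man$comorbidity_fractions)
  if (any(cf < 0 | cf > 1)) flag("manifest", "comorbidity fractions must lie in [0, 1]")
  if (man$friction_elasticity <= 0 || man$friction_elasticity > 1) {
    flag("manifest", "labour-time elasticity must lie in (0, 1]")
  }
  if (man$friction_period_days <= 0) flag("manifest", "friction period must be > 0")
  if (man$discount_effects < 0 || man$discount_costs < 0) {
    flag("manifest", "discount rates must be non-negative")
  }
  he <- unlist(man$he_ratio)
  if (!"Belgium" %in% names(he) || abs(he[["Belgium"]] - 1) > 1e-12) {
    flag("manifest", "Belgium must be present as reference country with expenditure ratio 1")
  }

  if (length(v) == 0) {
    tibble::tibble(table = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Write a parameter pack to a directory
#'
#' Serializes each component table to a CSV file and the scalar manifest to
#' `manifest.yaml` so packs are inspectable and diff-able.
#'
#' @param pack A `parameter_pack`.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_pack <- function(pack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in pack_table_names()) {
    readr::write_csv(pack[[nm]], file.path(path, paste0(nm, ".csv")), na = "")
  }
  yaml::write_yaml(pack$manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Read a parameter pack from a directory
#'
#' Inverse of [write_pack()].  Fails with an informative error naming the
#' first missing table; validates the result unless `validate = FALSE`.
#'
#' @param path Directory written by [write_pack()].
#' @param validate Run [validate_pack()] and abort on violations?
#' @return A `parameter_pack`.
#' @export
read_pack <- function(path, validate = TRUE) {
  if (!dir.exists(path)) stop("pack directory does not exist: ", path)
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) stop("pack is missing manifest.yaml")
  tables <- list()
  for (nm in pack_table_names()) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("pack is missing table: ", nm)
    tables[[nm]] <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  }
  # logical column round-trip
  tables$ebrb_effects$included <- as.logical(tables$ebrb_effects$included)
  pack <- new_parameter_pack(tables, yaml::read_yaml(mf))
  if (validate) {
    rep <- validate_pack(pack)
    if (nrow(rep) > 0) {
      stop("invalid parameter pack:\n", paste0("  [", rep$table, "] ", rep$message, collapse = "\n"))
    }
  }
  pack
}

#' Impute missing country costs from Belgian reference costs
#'
#' Missing direct-cost cells for `target_country` are filled with the
#' Belgian cost for the same disease/phase/age stratum multiplied by the
#' ratio of the target country's health expenditure per capita to Belgium's.
#' Cells already present are untouched.
#'
#' @param pack A `parameter_pack` whose manifest carries `he_ratio`.
#' @param target_country Country to impute.
#' @return The pack's cost table with the target country's cells filled.
#' @export
impute_cost <- function(pack, target_country) {
  he <- unlist(pack$manifest$he_ratio)
  if (!target_country %in% names(he)) {
    stop("no health-expenditure ratio available for ", target_country)
  }
  r <- he[[target_country]]
  be <- pack$costs |>
    dplyr::filter(.data$country == "Belgium") |>
    dplyr::select("disease", "phase", "age_lo", be_direct = "direct")
  if (nrow(be) == 0) stop("Belgian reference costs are missing from the pack")

  tgt <- pack$costs |> dplyr::filter(.data$country == target_country)
  # cells the target lacks entirely
  missing_cells <- dplyr::anti_join(be, tgt, by = c("disease", "phase", "age_lo")) |>
    dplyr::mutate(country = target_country, direct = .data$be_direct * r) |>
    dplyr::select("country", "disease", "phase", "age_lo", "direct")

  filled <- pack$costs |>
    dplyr::left_join(be, by = c("disease", "phase", "age_lo")) |>
    dplyr::mutate(direct = dplyr::if_else(
      .data$country == target_country & is.na(.data$direct),
      .data$be_direct * r, .data$direct
    )) |>
    dplyr::select(-"be_direct")

  dplyr::bind_rows(filled, missing_cells) |>
    dplyr::arrange(.data$country, .data$disease, .data$phase, .data$age_lo)
}

#' Impute missing country epidemiology by Belgium-referenced incidence ratios
#'
#' For each disease, the ratio of the target country's total rate to
#' Belgium's total (summed over cells present in both) scales the Belgian
#' cells to fill the target's missing (`NA`) cells.
#'
#' @param pack A `parameter_pack`.
#' @param target_country Country to impute.
#' @param quantity `"incidence"` or `"mortality"` (all-cause mortality and
#'   case-fatality measures).
#' @return The pack's epidemiology table with `NA` cells of the target
#'   country filled.
#' @export
impute_epidemiology <- function(pack, target_country,
                                quantity = c("incidence", "mortality")) {
  quantity <- match.arg(quantity)
  measures <- if (quantity == "incidence") {
    "incidence"
  } else {
    c("all_cause_mortality", "case_fatality_first", "case_fatality_followup")
  }
  ep <- pack$epidemiology
  sel <- ep$measure %in% measures
  key <- c("sex", "age_lo", "measure", "disease")

  be <- ep[sel & ep$country == "Belgium", ] |>
    dplyr::select(dplyr::all_of(key), be_value = "value")
  tgt <- ep[sel & ep$country == target_country, ]

  ratios <- tgt |>
    dplyr::left_join(be, by = key) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$be_value)) |>
    dplyr::group_by(.data$measure, .data$disease) |>
    dplyr::summarise(
      ratio = sum(.data$value) / sum(.data$be_value), .groups = "drop"
    )
  if (any(!is.finite(ratios$ratio))) {
    stop("Belgian totals are zero for at least one disease; cannot impute")
  }

  ep |>
    dplyr::left_join(be, by = key) |>
    dplyr::left_join(ratios, by = c("measure", "disease")) |>
    dplyr::mutate(value = dplyr::if_else(
      .data$country == target_country & is.na(.data$value) &
        !is.na(.data$be_value) & !is.na(.data$ratio),
      .data$be_value * .data$ratio, .data$value
    )) |>
    dplyr::select(-"be_value", -"ratio")
}
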