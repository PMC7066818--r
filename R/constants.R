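#' Published relative-risk table for weight status and diabetes
#'
#' Relative risks of all-cause mortality and of developing diabetes, CHD,
#' stroke, CRC and BC, for overweight and obese adults relative to
#' normal-weight adults (`population = "at_risk"`), and for diabetic adults
#' relative to healthy counterparts (`population = "diabetic"`).  Age bands
#' are closed-open `[age_lo, age_hi)` and partition 30-100 per outcome.
#' BC applies to women only; the diabetic block carries no diabetes
#' outcome (its members already have diabetes).
#'
#' @return Tibble with columns `population`, `sex`, `weight_status`
#'   (`NA` in the diabetic block), `outcome`, `age_lo`, `age_hi`, `rr`.
#' @export
rr_reference <- function() {
  band <- function(outcome, lo, hi) tibble::tibble(outcome = outcome, age_lo = lo, age_hi = hi)
  bands <- dplyr::bind_rows(
    band("all_cause_mortality", c(30, 50, 60, 70), c(50, 60, 70, 100)),
    band("chd", c(30, 55, 65), c(55, 65, 100)),
    band("stroke", c(30, 65), c(65, 100)),
    band("diabetes", c(30, 60, 75), c(60, 75, 100)),
    band("bc", c(30, 50), c(50, 100)),
    band("crc", c(30, 45), c(45, 100))
  )

  # values per (population, sex, weight_status), in band order above
  vals <- list(
    at_risk.male.overweight   = c(1.20, 1.20, 1.19, 1.18,  1.35, 1.35, 1.25,  1.20, 1.15,  2.25, 2.15, 2.13,  NA, NA,    1.20, 1.18),
    at_risk.male.obese        = c(1.55, 1.54, 1.52, 1.50,  2.00, 2.00, 1.70,  1.50, 1.38,  5.50, 5.14, 5.05,  NA, NA,    1.40, 1.36),
    at_risk.female.overweight = c(1.15, 1.15, 1.14, 1.14,  1.35, 1.35, 1.25,  1.20, 1.15,  2.30, 2.20, 2.17,  1.00, 1.12, 1.08, 1.07),
    at_risk.female.obese      = c(1.50, 1.49, 1.48, 1.45,  2.00, 2.00, 1.70,  1.55, 1.41,  7.00, 6.52, 6.40,  1.00, 1.12, 1.10, 1.09),
    diabetic.male.NA          = c(1.57, 1.57, 1.57, 1.57,  2.19, 1.43, 1.33,  1.83, 1.83,  NA, NA, NA,        1.23, 1.23, 1.26, 1.26),
    diabetic.female.NA        = c(2.00, 2.00, 2.00, 2.00,  2.19, 1.43, 1.33,  2.28, 2.28,  NA, NA, NA,        1.23, 1.23, 1.26, 1.26)
  )

  purrr::imap_dfr(vals, function(v, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ws <- if (parts[3] == "NA") NA_character_ else parts[3]
    dplyr::mutate(bands,
      population = parts[1], sex = parts[2], weight_status = ws, rr = v,
      .before = 1
    )
  }) |>
    dplyr::filter(!is.na(.data$rr)) |>
    # men cannot develop breast cancer: at-risk male BC rows are absent and
    # the diabetic male BC rows are never used in transitions
    dplyr::filter(!(.data$sex == "male" & .data$outcome == "bc" &
      .data$population == "at_risk"))
}

#' Published socio-economic-status adjustment factors for excess weight
#'
#' Relative risk of being overweight or obese in the lower-educated half of
#' the adult population compared with the total adult population, for the
#' four countries where the study regions are low-SES pockets of a wider
#' population.  Bulgaria and Hungary enter with RR = 1 (all their regions
#' are classified low-SES, so national prevalence needs no adjustment).
#' Finland is the one population where excess weight is *less* prevalent in
#' the lower-educated half (obese women RR = 0.89).
#'
#' @return Tibble with columns `country`, `sex`, `weight_status`, `rr`.
#' @export
ses_reference <- function() {
  grid <- tidyr::expand_grid(
    country = c("Belgium", "Finland", "Greece", "Spain"),
    sex = c("male", "female"),
    weight_status = c("overweight", "obese")
  )
  # order: BE m ow, BE m ob, BE f ow, BE f ob, FI ..., GR ..., ES ...
  grid$rr <- c(
    1.05, 1.12, 1.24, 1.39, # Belgium
    0.97, 1.03, 1.04, 0.89, # Finland
    1.07, 1.30, 1.33, 1.46, # Greece
    1.07, 1.30, 1.33, 1.46  # Spain
  )
  dplyr::bind_rows(
    grid,
    tidyr::expand_grid(
      country = c("Bulgaria", "Hungary"),
      sex = c("male", "female"),
      weight_status = c("overweight", "obese")
    ) |> dplyr::mutate(rr = 1)
  )
}

#' Published energy balance-related behaviour (EBRB) effects on weight status
#'
#' Relative risks of overweight/obesity associated with each targeted
#' behaviour, for children and adults.  Behaviours with inconclusive
#' literature carry `included = FALSE` and no RR (children: fruits and
#' berries, vegetables, sweets; adults: water, sweets).  Where a single RR
#' is published it applies to both overweight and obesity.
#'
#' @return Tibble with columns `population` (`"child"`/`"adult"`),
#'   `behaviour`, `rr_overweight`, `rr_obese`, `included`.
#' @export
ebrb_reference <- function() {
  tibble::tribble(
    ~population, ~behaviour,                  ~rr_overweight, ~rr_obese, ~included,
    "child", "water",                          1.33, 1.33, TRUE,
    "child", "fruits_berries",                 NA,   NA,   FALSE,
    "child", "vegetables",                     NA,   NA,   FALSE,
    "child", "screen_time",                    2.00, 2.00, TRUE,
    "child", "sweets",                         NA,   NA,   FALSE,
    "child", "sugar_sweetened_beverages",      1.22, 1.22, TRUE,
    "child", "physical_activity",              1.35, 1.35, TRUE,
    "child", "breakfast",                      3.03, 2.13, TRUE,
    "adult", "water",                          NA,   NA,   FALSE,
    "adult", "fruits_berries",                 1.23, 1.25, TRUE,
    "adult", "vegetables",                     1.19, 1.15, TRUE,
    "adult", "screen_time",                    1.38, 1.38, TRUE,
    "adult", "sweets",                         NA,   NA,   FALSE,
    "adult", "soft_drinks",                    1.30, 1.30, TRUE,
    "adult", "physical_activity",              1.07, 1.07, TRUE,
    "adult", "breakfast",                      1.19, 1.19, TRUE
  )
}

#' Diabetes comorbidity cost fractions
#'
#' Fractions of the annual diabetes cost added to the annual cost of each
#' other disease state to account for diabetes as a comorbidity.
#'
#' @return Named numeric vector over `chd`, `stroke`, `bc`, `crc`.
#' @export
comorbidity_cost_fractions <- function() {
  c(chd = 0.1791, stroke = 0.1980, bc = 0.2375, crc = 0.3824)
}

#' Indirect-cost multipliers per disease
#'
#' Indirect (productivity-loss) costs of the chronic disease states are
#' derived from direct costs: diabetes x 0.91, BC x 0.71, CHD x 0.80;
#' the indirect cost of stroke equals its direct cost.  CRC has no published
#' multiplier; its direct/indirect ratio is a configurable pack scalar.
#'
#' @return Named numeric vector over `diabetes`, `stroke`, `chd`, `bc`.
#' @export
indirect_cost_multipliers <- function() {
  c(diabetes = 0.91, stroke = 1.00, chd = 0.80, bc = 0.71)
}
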