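#' Weight-status distributions
#'
#' A weight-status distribution is a named numeric vector over
#' `normal`, `overweight`, `obese` with entries in \[0,1\] summing to 1
#' (tolerance 1e-9).  `weight_dist()` constructs and checks one.
#'
#' @param normal,overweight,obese Proportions.
#' @return Named numeric vector of length 3.
#' @export
#' @examples
#' weight_dist(0.5, 0.3, 0.2)
weight_dist <- function(normal, overweight, obese) {
  d <- c(normal = normal, overweight = overweight, obese = obese)
  check_weight_dist(d)
  d
}

check_weight_dist <- function(d) {
  if (length(d) != 3 || any(is.na(d))) {
    stop("a weight distribution needs 3 finite proportions")
  }
  if (any(d < -1e-12 | d > 1 + 1e-12)) {
    stop("weight-status proportions must lie in [0, 1]")
  }
  if (abs(sum(d) - 1) > 1e-9) {
    stop(sprintf("weight-status proportions must sum to 1 (got %.12f)", sum(d)))
  }
  invisible(d)
}

#' Convert an odds ratio to a relative risk
#'
#' Conservative conversion of an odds ratio to a risk ratio given the
#' baseline (control-group) outcome risk:
#' `RR = OR / (1 - p0 + p0 * OR)`.  For `OR > 1` the result never exceeds
#' the OR, equals the OR in the rare-outcome limit `p0 -> 0`, and shrinks
#' toward 1 as `p0` grows.
#'
#' @param or Odds ratio (> 0).
#' @param p0 Baseline risk in \[0, 1).
#' @return Relative risk.
#' @export
#' @examples
#' rr_from_or(2, 0.5) # 4/3
rr_from_or <- function(or, p0) {
  if (any(or <= 0)) stop("odds ratio must be > 0")
  if (any(p0 < 0 | p0 >= 1)) stop("baseline risk must lie in [0, 1)")
  or / (1 - p0 + p0 * or)
}

#' Adjust a weight-status distribution for socio-economic status
#'
#' Scales the overweight and obese proportions by the country- and
#' sex-specific relative risks of excess weight in the lower-educated half
#' of the population, assigning the complement to normal weight.
#'
#' @param dist Weight distribution (see [weight_dist()]).
#' @param ses SES adjustment table (`country`, `sex`, `weight_status`, `rr`),
#'   e.g. `pack$ses_adjust`.
#' @param country,sex Stratum selectors.
#' @return Adjusted weight distribution.
#' @export
ses_adjust <- function(dist, ses, country, sex) {
  check_weight_dist(dist)
  rows <- ses[ses$country == country & ses$sex == sex, ]
  rr_of <- function(ws) {
    r <- rows$rr[rows$weight_status == ws]
    if (length(r) != 1) stop("missing SES adjustment for ", country, "/", sex, "/", ws)
    r
  }
  ow <- dist[["overweight"]] * rr_of("overweight")
  ob <- dist[["obese"]] * rr_of("obese")
  if (ow + ob > 1 + 1e-12) {
    stop("SES-adjusted excess-weight mass exceeds 1")
  }
  weight_dist(1 - ow - ob, ow, ob)
}

#' Combine behaviour effects into weight-status relative risk reductions
#'
#' Translates arm differences in exposure to energy balance-related
#' behaviours into a relative risk reduction (RRR) for overweight and for
#' obesity.  For each included behaviour `b` with relative risk `RR_b` on
#' the weight outcome and exposure prevalences `p_ctrl`, `p_int`, the
#' attributable change is
#' `delta_b = (p_ctrl - p_int) (RR_b - 1) / (1 + p_ctrl (RR_b - 1))`
#' and behaviours combine multiplicatively on the survival scale:
#' `RRR = 1 - prod_b(1 - delta_b)` (independence across behaviours).
#'
#' @param effects Behaviour-effect table (`pack$ebrb_effects` schema).
#' @param population `"child"` or `"adult"`.
#' @return Named numeric vector `c(overweight = , obese = )`.
#' @export
ebrb_weight_rrr <- function(effects, population = c("child", "adult")) {
  population <- match.arg(population)
  eff <- effects[effects$population == population & effects$included, , drop = FALSE]
  if (nrow(eff) == 0) stop("no included behaviours for population ", population)
  one <- function(rr, p0, p1) {
    if (any(is.na(rr))) stop("missing RR for an included behaviour")
    if (any(is.na(p0) | is.na(p1))) stop("missing exposure prevalence for an included behaviour")
    d <- (p0 - p1) * (rr - 1) / (1 + p0 * (rr - 1))
    1 - prod(1 - d)
  }
  c(
    overweight = one(eff$rr_overweight, eff$p_control, eff$p_intervention),
    obese = one(eff$rr_obese, eff$p_control, eff$p_intervention)
  )
}

#' Apply weight-status relative risk reductions to a distribution
#'
#' Shrinks the overweight and obese proportions by their RRRs and returns
#' the freed probability mass to normal weight.
#'
#' @param dist Weight distribution.
#' @param rrr_overweight,rrr_obese Relative risk reductions in \[0, 1\].
#' @return Adjusted weight distribution.
#' @export
apply_weight_rrr <- function(dist, rrr_overweight, rrr_obese) {
  check_weight_dist(dist)
  if (any(c(rrr_overweight, rrr_obese) < 0 | c(rrr_overweight, rrr_obese) > 1)) {
    stop("RRRs must lie in [0, 1]")
  }
  ow <- dist[["overweight"]] * (1 - rrr_overweight)
  ob <- dist[["obese"]] * (1 - rrr_obese)
  weight_dist(1 - ow - ob, ow, ob)
}

#' Extrapolate a child weight-status distribution to adulthood
#'
#' Multiplies the child distribution by the row-stochastic tracking matrix
#' (child status in rows, adult status in columns).
#'
#' @param dist Child weight distribution.
#' @param tracking Tracking matrix as the pack stores it (tibble with
#'   `child_status`, `normal`, `overweight`, `obese`) or a plain 3x3 matrix.
#' @return Adult weight distribution.
#' @export
child_to_adult <- function(dist, tracking) {
  check_weight_dist(dist)
  T <- if (is.data.frame(tracking)) {
    m <- as.matrix(tracking[match(weight_statuses(), tracking$child_status),
                            weight_statuses()])
    rownames(m) <- weight_statuses()
    m
  } else {
    tracking
  }
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-9)) {
    stop("tracking matrix must be row-stochastic")
  }
  out <- as.numeric(dist %*% T)
  weight_dist(out[1], out[2], out[3])
}

#' Spread parent age-group proportions into per-age entry weights
#'
#' Parents younger than 30 enter the model at age 30 and parents older than
#' 50 at age 50; each five-year group's mass is split evenly over its five
#' ages.
#'
#' @param age_groups Tibble with `age_group` in
#'   `c("<30","30-34","35-39","40-44","45-49",">50")` and `proportion`
#'   summing to 1 (one sex at a time).
#' @return Tibble with columns `age` (30..50) and `weight` summing to 1.
#' @export
parent_entry_schedule <- function(age_groups) {
  if (any(age_groups$proportion < 0)) stop("age-group proportions must be non-negative")
  if (abs(sum(age_groups$proportion) - 1) > 1e-9) {
    stop("age-group proportions must sum to 1")
  }
  prop <- function(g) {
    p <- age_groups$proportion[age_groups$age_group == g]
    if (length(p) == 0) 0 else sum(p)
  }
  w <- stats::setNames(numeric(21), 30:50)
  w["30"] <- prop("<30")
  w["50"] <- prop(">50")
  for (g in list(c("30-34", 30), c("35-39", 35), c("40-44", 40), c("45-49", 45))) {
    ages <- as.character(seq(as.numeric(g[2]), length.out = 5))
    w[ages] <- w[ages] + prop(g[1]) / 5
  }
  tibble::tibble(age = 30:50, weight = as.numeric(w)) |>
    dplyr::filter(.data$weight > 0)
}

#' Per-arm weight-status distributions at Markov entry
#'
#' Resolves the pack's intervention-effect settings into the control and
#' intervention weight-status distributions a cohort carries into the Markov
#' model.  Two effect modes exist; direct weight-status effects take
#' priority over behaviour-mediated effects when both are supplied:
#' * `"bmi"`: the manifest supplies per-population RRRs in overweight and
#'   obesity directly (`manifest$bmi_effect$child / $adult`).
#' * `"ebrb"`: RRRs are derived from the arm exposure prevalences of the
#'   included behaviours via [ebrb_weight_rrr()].
#'
#' Control distributions start from the national prevalence, SES-adjusted
#' for adults (study regions are low-SES).  Child distributions are mapped
#' to adulthood through the tracking matrix after the effect is applied.
#'
#' @param pack A `parameter_pack`.
#' @param country Country name.
#' @param sex `"male"` or `"female"`.
#' @param population `"adult"` or `"child"`.
#' @return List with elements `control` and `intervention`, each a weight
#'   distribution at Markov entry (adult age).
#' @export
arm_distributions <- function(pack, country, sex, population = c("adult", "child")) {
  population <- match.arg(population)
  wp <- pack$weight_prevalence
  row <- wp[wp$population == population & wp$country == country & wp$sex == sex, ]
  if (nrow(row) != 1) stop("no weight prevalence for ", country, "/", sex, "/", population)
  base <- weight_dist(row$p_normal, row$p_overweight, row$p_obese)
  if (population == "adult") {
    base <- ses_adjust(base, pack$ses_adjust, country, sex)
  }

  mode <- pack$manifest$effect_mode %||% "ebrb"
  bmi <- pack$manifest$bmi_effect[[population]]
  rrr <- if (mode == "bmi" || (!is.null(bmi) && mode != "ebrb")) {
    if (is.null(bmi)) stop("effect_mode is 'bmi' but manifest$bmi_effect$", population, " is missing")
    c(overweight = bmi$rrr_overweight, obese = bmi$rrr_obese)
  } else {
    ebrb_weight_rrr(pack$ebrb_effects, population)
  }
  rrr <- pmin(pmax(rrr * (pack$manifest$effect_scale %||% 1), 0), 1)

  ctrl <- base
  int <- apply_weight_rrr(base, rrr[["overweight"]], rrr[["obese"]])
  if (population == "child") {
    ctrl <- child_to_adult(ctrl, pack$tracking)
    int <- child_to_adult(int, pack$tracking)
  }
  list(control = ctrl, intervention = int)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
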