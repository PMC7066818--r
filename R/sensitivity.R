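#' Named model parameters for sensitivity analyses
#'
#' The sensitivity analyses vary whole parameter classes, mirroring the
#' quantities the evaluation treats as uncertain: annual health-state
#' costs, state utilities (decrements), disease incidence, mortality
#' (all-cause and case fatality), the intervention cost, and the
#' intervention effect (the relative risk reduction).  Each parameter is a
#' modifier that rescales its class by a factor; probabilities are clipped
#' to \[0, 1\] with a warning when a perturbation would exceed the support.
#'
#' @return Character vector of parameter names understood by [tornado()].
#' @export
sensitivity_parameters <- function() {
  c("state_costs", "utilities", "incidence", "mortality",
    "intervention_cost", "effect_rrr")
}

clip_prob <- function(x, what) {
  if (any(x > 1 | x < 0, na.rm = TRUE)) {
    warning(what, " perturbed outside [0, 1]; clipped")
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

perturb_pack <- function(pack, parameter, factor) {
  switch(parameter,
    state_costs = {
      pack$costs$direct <- pack$costs$direct * factor
      pack
    },
    utilities = {
      ud <- pack$utility_decrements
      ud$dec_first <- clip_prob(ud$dec_first * factor, "utility decrement")
      ud$dec_followup <- pmin(clip_prob(ud$dec_followup * factor, "utility decrement"),
                              ud$dec_first)
      pack$utility_decrements <- ud
      pack
    },
    incidence = {
      sel <- pack$epidemiology$measure == "incidence"
      pack$epidemiology$value[sel] <-
        clip_prob(pack$epidemiology$value[sel] * factor, "incidence")
      pack
    },
    mortality = {
      sel <- pack$epidemiology$measure %in%
        c("all_cause_mortality", "case_fatality_first", "case_fatality_followup")
      pack$epidemiology$value[sel] <-
        clip_prob(pack$epidemiology$value[sel] * factor, "mortality")
      pack
    },
    intervention_cost = {
      pack$intervention_costs$amount <- pack$intervention_costs$amount * factor
      pack
    },
    effect_rrr = {
      pack$manifest$effect_scale <- (pack$manifest$effect_scale %||% 1) * factor
      pack
    },
    stop("unknown sensitivity parameter: ", parameter)
  )
}

# Pool a cea_result over sexes for one report stratum and express it as a
# single output value.
cea_value <- function(res, output = c("icer", "nmb"), wtp = 20000,
                      report = "all_families") {
  output <- match.arg(output)
  s <- res$summary[res$summary$report == report, ]
  dc <- sum(s$delta_cost)
  dq <- sum(s$delta_qaly)
  if (output == "icer") {
    if (dq == 0) NA_real_ else dc / dq
  } else {
    wtp * dq - dc
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Perturbs each parameter class by `+/- span` (default 30%), reruns the
#' base-case analysis at the low and high value, and ranks the parameters
#' by the width of the resulting output interval (widest first), ready for
#' a tornado diagram.  A model failure at an extreme is recorded and the
#' parameter flagged rather than aborting the analysis.
#'
#' @param pack A `parameter_pack`.
#' @param country Country to evaluate.
#' @param parameters Parameter names (subset of [sensitivity_parameters()]).
#' @param span Fractional perturbation (default 0.30).
#' @param output `"icer"` or `"nmb"` (net monetary benefit at `wtp`).
#' @param wtp Willingness-to-pay threshold (EUR/QALY) for `"nmb"`.
#' @param report Component stratum to evaluate (`"all_families"` or `"hrf"`).
#' @param perspective Passed to [run_cea()].
#' @return A `tornado_result` tibble: `parameter`, `low`, `high`, `base`,
#'   `width`, `failed`, sorted by decreasing width.
#' @export
tornado <- function(pack, country, parameters = sensitivity_parameters(),
                    span = 0.30, output = c("nmb", "icer"), wtp = 20000,
                    report = "all_families",
                    perspective = c("societal", "payer")) {
  output <- match.arg(output)
  perspective <- match.arg(perspective)
  base <- cea_value(run_cea(pack, country, perspective), output, wtp, report)
  rows <- purrr::map_dfr(parameters, function(p) {
    vals <- purrr::map(c(1 - span, 1 + span), function(f) {
      tryCatch(
        cea_value(run_cea(perturb_pack(pack, p, f), country, perspective),
                  output, wtp, report),
        error = function(e) NA_real_
      )
    })
    lo <- vals[[1]]; hi <- vals[[2]]
    tibble::tibble(
      parameter = p, low = lo, high = hi, base = base,
      width = abs(hi - lo), failed = is.na(lo) || is.na(hi)
    )
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$width))
  class(out) <- c("tornado_result", class(out))
  out
}

#' Probabilistic sensitivity analysis configuration
#'
#' Distribution families follow the conventional assignment: costs are
#' gamma, probabilities and utilities beta, relative risks (and the
#' intervention effect) lognormal.  Dispersion defaults to a standard error
#' of 30% of the base value for every parameter, overridable via `se_frac`.
#'
#' @param n_draws Number of second-order Monte Carlo draws (>= 1).
#' @param seed Integer seed; draw `i` is deterministic given `(seed, i)`.
#' @param se_frac Standard error as a fraction of the base value (> 0).
#' @return A `psa_config` list.
#' @export
psa_config <- function(n_draws = 100, seed = 1, se_frac = 0.30) {
  stopifnot(n_draws >= 1, se_frac >= 0)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 se_frac = se_frac),
            class = "psa_config")
}

# method-of-moments draws, vectorised over cells; base values with
# infeasible moments are held fixed
draw_gamma <- function(x, cv) {
  if (cv == 0) return(x)
  ok <- !is.na(x) & x > 0
  if (any(ok)) {
    shape <- 1 / cv^2
    x[ok] <- stats::rgamma(sum(ok), shape = shape, rate = shape / x[ok])
  }
  x
}

draw_beta <- function(x, cv) {
  if (cv == 0) return(x)
  ok <- !is.na(x) & x > 0 & x < 1
  if (any(ok)) {
    m <- x[ok]
    v <- pmin((cv * m)^2, 0.95 * m * (1 - m)) # keep moments feasible
    nu <- m * (1 - m) / v - 1
    x[ok] <- stats::rbeta(sum(ok), m * nu, (1 - m) * nu)
  }
  x
}

draw_lognormal <- function(x, cv) {
  if (cv == 0) return(x)
  ok <- !is.na(x) & x > 0
  if (any(ok)) {
    sdlog <- sqrt(log(1 + cv^2))
    # median-preserving: log-space normal centred at log(base)
    x[ok] <- stats::rlnorm(sum(ok), meanlog = log(x[ok]), sdlog = sdlog)
  }
  x
}

#' Draw a perturbed parameter pack for one PSA iteration
#'
#' Costs (annual disease costs, intervention ledger) are drawn from gamma
#' distributions, probabilities (incidence, mortality, case fatality,
#' baseline utilities, utility decrements) from beta distributions, and the
#' intervention effect multiplier from a median-preserving lognormal, each
#' parameterised by method of moments around the base value with the
#' configured dispersion.  Deterministic given `(config$seed, draw)`.
#'
#' @param pack A `parameter_pack`.
#' @param config A [psa_config()].
#' @param draw Draw index (1-based).
#' @return A perturbed `parameter_pack`.
#' @export
draw_parameters <- function(pack, config, draw) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((config$seed + 97 * as.integer(draw)) %% .Machine$integer.max)
  cv <- config$se_frac

  pack$costs$direct <- draw_gamma(pack$costs$direct, cv)
  pack$intervention_costs$amount <- draw_gamma(pack$intervention_costs$amount, cv)
  pack$epidemiology$value <- draw_beta(pack$epidemiology$value, cv)
  pack$utility_baseline$utility <- draw_beta(pack$utility_baseline$utility, cv)
  ud <- pack$utility_decrements
  ud$dec_first <- draw_beta(ud$dec_first, cv)
  ud$dec_followup <- pmin(draw_beta(ud$dec_followup, cv), ud$dec_first)
  pack$utility_decrements <- ud
  pack$manifest$effect_scale <-
    draw_lognormal(pack$manifest$effect_scale %||% 1, cv)
  pack
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws `config$n_draws` parameter packs via [draw_parameters()], reruns
#' the base-case analysis for each, and collects the incremental cost and
#' QALY pairs (pooled over boys and girls for the chosen component
#' stratum).  The cost-effectiveness acceptability curve (CEAC) is the
#' fraction of draws with non-negative net monetary benefit over a grid of
#' willingness-to-pay thresholds.
#'
#' @inheritParams tornado
#' @param config A [psa_config()].
#' @param wtp_grid Thresholds (EUR/QALY) for the CEAC.
#' @return A `psa_result`: list with `draws` (tibble `draw`, `delta_cost`,
#'   `delta_qaly`), `ceac` (tibble `threshold`, `probability`), `base`
#'   (deterministic `delta_cost`/`delta_qaly`) and `config`.
#' @export
run_psa <- function(pack, country, config = psa_config(),
                    wtp_grid = seq(0, 1e5, by = 2500),
                    report = "all_families",
                    perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  base_res <- run_cea(pack, country, perspective)
  s <- base_res$summary[base_res$summary$report == report, ]
  base <- tibble::tibble(delta_cost = sum(s$delta_cost),
                         delta_qaly = sum(s$delta_qaly))

  draws <- purrr::map_dfr(seq_len(config$n_draws), function(i) {
    res <- run_cea(draw_parameters(pack, config, i), country, perspective)
    si <- res$summary[res$summary$report == report, ]
    tibble::tibble(draw = i, delta_cost = sum(si$delta_cost),
                   delta_qaly = sum(si$delta_qaly))
  })

  ceac <- tibble::tibble(
    threshold = wtp_grid,
    probability = vapply(wtp_grid, function(l) {
      mean(l * draws$delta_qaly - draws$delta_cost >= 0)
    }, numeric(1))
  )
  structure(list(draws = draws, ceac = ceac, base = base, config = config,
                 country = country, report = report),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$country, "-", nrow(x$draws), "draws,",
      x$report, "stratum\n")
  cat(sprintf("  mean dQ = %.3f, mean dC = %.0f EUR per 1000 children\n",
              mean(x$draws$delta_qaly), mean(x$draws$delta_cost)))
  invisible(x)
}

#' @rdname tidy.cea_result
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @rdname glance.cea_result
#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(
    country = x$country, report = x$report, n_draws = nrow(x$draws),
    mean_delta_cost = mean(x$draws$delta_cost),
    mean_delta_qaly = mean(x$draws$delta_qaly),
    p_ce_at_20000 = mean(2e4 * x$draws$delta_qaly - x$draws$delta_cost >= 0)
  )
}

#' Discount-rate scenario presets
#'
#' Scenario analyses bound the discount rates: `"min"` sets both rates to
#' 0%, `"max"` to 5%; `"base"` restores the reference rates (effects 1.50%,
#' costs 3%).
#'
#' @param pack A `parameter_pack`.
#' @param preset `"base"`, `"min"` or `"max"`.
#' @return The pack with discount rates set.
#' @export
discount_scenario <- function(pack, preset = c("base", "min", "max")) {
  preset <- match.arg(preset)
  rates <- switch(preset,
    base = c(0.015, 0.03), min = c(0, 0), max = c(0.05, 0.05))
  pack$manifest$discount_effects <- rates[1]
  pack$manifest$discount_costs <- rates[2]
  pack
}
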