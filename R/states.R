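#' Health-state registry
#'
#' The model follows a cohort of at-risk adults through eleven health states:
#' the entry state (`AtRisk`), a chronic diabetes state (`Diabetes`),
#' first-year / follow-up tunnel pairs for stroke, coronary heart disease
#' (CHD), colorectal cancer (CRC) and breast cancer (BC), and an absorbing
#' `Death` state.  First-year and follow-up years after diagnosis carry
#' different utilities and costs, hence the tunnel split.
#'
#' @return A tibble with one row per state: `state`, `disease` (`NA` for
#'   `AtRisk`/`Death`), `phase` (one of `"entry"`, `"chronic"`, `"first"`,
#'   `"followup"`, `"absorbing"`) and `partner` (the follow-up partner of a
#'   first-year state, and vice versa).
#' @export
#' @examples
#' health_states()
health_states <- function() {
  .states_cache
}

.states_cache <- local({
  tibble::tibble(
    state = c(
      "AtRisk", "Diabetes",
      "Stroke1", "Stroke1plus",
      "CHD1", "CHD1plus",
      "CRC1", "CRC1plus",
      "BC1", "BC1plus",
      "Death"
    ),
    disease = c(
      NA, "diabetes",
      "stroke", "stroke",
      "chd", "chd",
      "crc", "crc",
      "bc", "bc",
      NA
    ),
    phase = c(
      "entry", "chronic",
      "first", "followup",
      "first", "followup",
      "first", "followup",
      "first", "followup",
      "absorbing"
    ),
    partner = c(
      NA, NA,
      "Stroke1plus", "Stroke1",
      "CHD1plus", "CHD1",
      "CRC1plus", "CRC1",
      "BC1plus", "BC1",
      NA
    )
  )
})

# Canonical orderings used throughout the package
state_names <- function() .states_cache$state

disease_names <- function() c("diabetes", "stroke", "chd", "crc", "bc")

weight_statuses <- function() c("normal", "overweight", "obese")

model_countries <- function() {
  c("Belgium", "Bulgaria", "Finland", "Greece", "Hungary", "Spain")
}
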