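# trace stub: constant occupancy in one state over 70 cycles
stub_trace <- function(state_name, sex = "female", n_cycles = 70,
                       entry_age = 30, occupancy = 1) {
  sn <- c("AtRisk", "Diabetes", "Stroke1", "Stroke1plus", "CHD1", "CHD1plus",
          "CRC1", "CRC1plus", "BC1", "BC1plus", "Death")
  occ_val <- occupancy
  by_entry <- tidyr::expand_grid(cycle = 0:n_cycles, state = sn) |>
    dplyr::mutate(
      entry_age = entry_age, weight = 1,
      age = pmin(entry_age + cycle, 99),
      occupancy = ifelse(state == state_name, occ_val, 0)
    )
  structure(list(by_entry = by_entry,
                 trace = dplyr::select(by_entry, cycle, state, occupancy),
                 sex = sex, n_cycles = n_cycles),
            class = "cohort_trace")
}

test_that("relapse adjustment is the probability-weighted mean", {
  expect_equal(relapse_adjust(0.7, 0.9, 0), 0.9)
  expect_equal(relapse_adjust(0.7, 0.9, 1), 0.7)
  expect_equal(relapse_adjust(0.7, 0.9, 0.1), 0.88, tolerance = 1e-12)
  expect_error(relapse_adjust(0.7, 0.9, 1.5), "relapse")
})

test_that("discount factors follow (1 + r)^-(t + lead)", {
  expect_equal(discount_factor(0, 0:70), rep(1, 71))
  expect_equal(discount_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  # childhood lead time shrinks all effects by a constant factor
  ratio <- discount_factor(0.015, 5, lead = 22) / discount_factor(0.015, 5)
  expect_equal(ratio, 1.015^-22, tolerance = 1e-12)
  expect_error(discount_factor(-0.01, 1), "non-negative")
})

test_that("QALYs integrate utility x occupancy x discount over the trace", {
  pack <- test_pack()
  # perfect health, no death, no discounting: 70 QALYs over 70 cycles
  perfect <- pack
  perfect$utility_baseline$utility <- 1
  tr <- stub_trace("AtRisk")
  expect_equal(qalys_from_trace(tr, perfect, rate = 0), 70)

  # constant occupancy at rate r matches the geometric series
  r <- 0.03
  expect_equal(qalys_from_trace(tr, perfect, rate = r),
               sum((1 + r)^-(1:70)), tolerance = 1e-9)

  # a utility decrement cuts the contribution by decrement x person-years
  dec <- pack
  dec$utility_baseline$utility <- 1
  dec$utility_decrements$dec_first[dec$utility_decrements$disease == "diabetes"] <- 0.1
  dec$utility_decrements$dec_followup[dec$utility_decrements$disease == "diabetes"] <- 0.1
  trd <- stub_trace("Diabetes")
  expect_equal(qalys_from_trace(trd, dec, rate = 0), 70 * 0.9, tolerance = 1e-9)

  # death contributes nothing
  expect_equal(qalys_from_trace(stub_trace("Death"), perfect, rate = 0), 0)
})

test_that("state costs combine direct, indirect and diabetes-comorbidity components", {
  pack <- test_pack()
  # engineered cells: CHD first-year direct 2000, total diabetes cost 1000
  # (direct 1000/1.91 so that direct + 0.91 x direct = 1000)
  cs <- pack$costs
  cs$direct[cs$country == "Belgium" & cs$disease == "chd" & cs$phase == "first"] <- 2000
  cs$direct[cs$country == "Belgium" & cs$disease == "diabetes"] <- 1000 / 1.91
  pack$costs <- cs

  cost_of <- heeprev:::state_cost_fun(pack, "Belgium", "societal")
  # direct x (1 + 0.8) + 0.1791 x diabetes cost
  expect_equal(cost_of("CHD1", 40), 2000 * 1.8 + 0.1791 * 1000, tolerance = 1e-9)
  expect_equal(cost_of("CHD1", 40), 3779.1, tolerance = 1e-9)

  # stroke indirect equals direct: total = 2 x direct + comorbidity add-on
  s_dir <- cs$direct[cs$country == "Belgium" & cs$disease == "stroke" &
                       cs$phase == "first" & cs$age_lo == 30]
  expect_equal(cost_of("Stroke1", 40), 2 * s_dir + 0.1980 * 1000, tolerance = 1e-9)

  # payer perspective drops indirect components but keeps the add-on's
  # direct share
  payer <- heeprev:::state_cost_fun(pack, "Belgium", "payer")
  expect_equal(payer("CHD1", 40), 2000 + 0.1791 * 1000 / 1.91, tolerance = 1e-9)

  # age stratification: diabetes splits at 55
  d_young <- cost_of("Diabetes", 54)
  cs$direct[cs$country == "Belgium" & cs$disease == "diabetes" & cs$age_lo == 55] <- 3000
  pack$costs <- cs
  cost_of2 <- heeprev:::state_cost_fun(pack, "Belgium", "societal")
  expect_equal(cost_of2("Diabetes", 55), 3000 * 1.91, tolerance = 1e-9)
  expect_equal(cost_of2("Diabetes", 54), d_young)

  # follow-up states are relapse-adjusted between first-year and follow-up
  p_rel <- pack$utility_decrements$relapse[pack$utility_decrements$disease == "stroke"]
  fu_dir <- cs$direct[cs$country == "Belgium" & cs$disease == "stroke" &
                        cs$phase == "followup" & cs$age_lo == 30]
  expect_equal(
    cost_of2("Stroke1plus", 40),
    relapse_adjust(2 * s_dir + 0.1980 * 1000, 2 * fu_dir + 0.1980 * 1000, p_rel),
    tolerance = 1e-9
  )

  # the at-risk and death states are costless
  expect_equal(cost_of("AtRisk", 40), 0)
  expect_equal(cost_of("Death", 40), 0)

  # missing cells are named
  gone <- pack
  gone$costs <- gone$costs[!(gone$costs$country == "Belgium" &
                               gone$costs$disease == "crc"), ]
  expect_error(heeprev:::state_cost_fun(gone, "Belgium")("CRC1", 40),
               "Belgium/crc")
})

test_that("friction costs apply only at working age with labour-time elasticity", {
  pack <- test_pack()
  fr <- pack$friction
  fr[fr$country == "Belgium", c("hours", "cost_per_hour", "unemployment")] <-
    list(800, 30, 0.10)
  pack$friction <- fr
  expect_equal(friction_death_cost(pack, "Belgium", 40),
               800 * 30 * 0.9 * 0.8, tolerance = 1e-12)
  expect_equal(friction_death_cost(pack, "Belgium", 40), 17280)
  expect_equal(friction_death_cost(pack, "Belgium", 70), 0)
  expect_equal(friction_death_cost(pack, "Belgium", 29), 0)
  expect_equal(friction_death_cost(pack, "Belgium", 64), 17280)

  # a 10% labour-time reduction yields an 8% production loss
  expect_equal(production_loss(0.10), 0.08, tolerance = 1e-12)
  expect_error(production_loss(0.1, elasticity = 1.5), "elasticity")
})

test_that("discounted costs from a trace scale linearly and respect perspective", {
  pack <- test_pack()
  # only at-risk occupancy and zero state costs: nothing accrues while the
  # whole cohort is alive and at risk
  tr <- stub_trace("AtRisk")
  cc <- costs_from_trace(tr, pack, "Belgium")
  expect_equal(cc$total, 0)

  # one person-year pattern: constant diabetes occupancy at rate 0 gives
  # 70 x annual cost
  trd <- stub_trace("Diabetes", entry_age = 30)
  cost_of <- heeprev:::state_cost_fun(pack, "Belgium", "societal")
  cc0 <- costs_from_trace(trd, pack, "Belgium", rate = 0)
  expect_equal(cc0$total,
               sum(cost_of("Diabetes", pmin(30 + 1:70, 99))), tolerance = 1e-9)

  # discounting can only reduce the total; linearity in occupancy
  cc3 <- costs_from_trace(trd, pack, "Belgium", rate = 0.03)
  expect_lt(cc3$total, cc0$total)
  half <- stub_trace("Diabetes", occupancy = 0.5)
  expect_equal(costs_from_trace(half, pack, "Belgium", rate = 0.03)$total,
               cc3$total / 2, tolerance = 1e-9)

  # payer perspective drops indirect and friction components
  d <- weight_dist(0.5, 0.3, 0.2)
  real <- run_cohort(pack, "Belgium", "male", d)
  soc <- costs_from_trace(real, pack, "Belgium")
  pay <- costs_from_trace(real, pack, "Belgium", perspective = "payer")
  expect_gt(soc$friction, 0)
  expect_equal(pay$friction, 0)
  expect_equal(pay$disease_indirect, 0)
  expect_lt(pay$total, soc$total)
})

test_that("ICERs carry the correct dominance flags in all four quadrants", {
  expect_equal(icer(1000, 0, 0.5, 0)$icer, 2000)
  expect_equal(icer(1000, 0, 0.5, 0)$status, "tradeoff")
  expect_equal(icer(-10, 0, 0.1, 0)$status, "dominant")
  expect_equal(icer(10, 0, -0.1, 0)$status, "dominated")
  sw <- icer(-10, 0, -0.1, 0) # saves money, loses QALYs: a genuine trade-off
  expect_equal(sw$status, "tradeoff")
  expect_equal(sw$icer, 100)
  und <- icer(5, 0, 0.3, 0.3)
  expect_equal(und$status, "undefined")
  expect_true(is.na(und$icer))
})

test_that("per-1000 scaling is proportional and components split correctly", {
  expect_equal(scale_per_1000(10, 1000), 10)
  expect_equal(scale_per_1000(10, 500), 20)
  expect_error(scale_per_1000(10, 0), "cohort size")

  pack <- test_pack()
  # payer ledger excludes the societal-only items (family transport/time)
  soc <- intervention_cost_totals(pack, "Greece", "societal")
  pay <- intervention_cost_totals(pack, "Greece", "payer")
  expect_lt(pay[["hrf"]], soc[["hrf"]])
  led <- pack$intervention_costs
  fam <- sum(led$amount[led$country == "Greece" & led$payer == "societal"])
  expect_equal(sum(soc) - sum(pay), fam, tolerance = 1e-9)

  res <- run_cea(pack, "Greece")
  tt <- tidy(res)
  # HRF stratum carries the HRF component cost on top of the school cost;
  # control arms carry no intervention cost
  int_all <- tt$cost_intervention[tt$report == "all_families" &
                                    tt$arm == "intervention"][1]
  int_hrf <- tt$cost_intervention[tt$report == "hrf" &
                                    tt$arm == "intervention"][1]
  expect_gt(int_hrf, int_all)
  expect_equal(tt$cost_intervention[tt$arm == "control"], rep(0, 4))
  coh <- pack$cohorts[pack$cohorts$country == "Greece", ]
  expect_equal(int_all, sum(soc[["school"]]) * 1000 / coh$n_families,
               tolerance = 1e-9)
})
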