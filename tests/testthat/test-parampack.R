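test_that("the state registry has 11 states with paired tunnel states", {
  st <- health_states()
  expect_equal(nrow(st), 11)
  expect_equal(st$phase[st$state == "Death"], "absorbing")
  first <- st[st$phase == "first", ]
  expect_equal(nrow(first), 4)
  # each first-year state has exactly one follow-up partner, and the
  # partnership is symmetric
  for (i in seq_len(4)) {
    p <- st[st$state == first$partner[i], ]
    expect_equal(p$phase, "followup")
    expect_equal(p$partner, first$state[i])
  }
})

test_that("synthetic packs are deterministic, valid, and embed the published constants", {
  p1 <- synthetic_pack(1)
  p2 <- synthetic_pack(1)
  expect_equal(p1$epidemiology, p2$epidemiology)
  expect_equal(p1$costs, p2$costs)
  expect_equal(p1$intervention_costs, p2$intervention_costs)
  expect_identical(p1$manifest, p2$manifest)
  expect_equal(nrow(validate_pack(p1)), 0)

  # published RR table cells
  rr <- p1$rr_table
  pick <- function(pop, sx, ws, out, age) {
    rows <- rr[rr$population == pop & rr$sex == sx & rr$outcome == out &
                 (if (is.na(ws)) is.na(rr$weight_status) else
                    !is.na(rr$weight_status) & rr$weight_status == ws), ]
    rows$rr[rows$age_lo <= age & age < rows$age_hi]
  }
  expect_equal(pick("at_risk", "male", "obese", "diabetes", 45), 5.50)
  expect_equal(pick("at_risk", "male", "overweight", "diabetes", 45), 2.25)
  expect_equal(pick("at_risk", "female", "obese", "diabetes", 76), 6.40)
  expect_equal(pick("diabetic", "male", NA, "chd", 50), 2.19)
  expect_equal(pick("diabetic", "female", NA, "all_cause_mortality", 65), 2.00)
  # no at-risk breast-cancer rows for men
  expect_equal(nrow(rr[rr$population == "at_risk" & rr$sex == "male" &
                         rr$outcome == "bc", ]), 0)

  # comorbidity cost fractions and indirect multipliers
  expect_equal(p1$manifest$comorbidity_fractions$stroke, 0.1980)
  expect_equal(p1$manifest$comorbidity_fractions$crc, 0.3824)
  expect_equal(p1$manifest$indirect_multipliers$diabetes, 0.91)
  expect_equal(p1$manifest$indirect_multipliers$stroke, 1.00)

  # discount and friction defaults
  expect_equal(p1$manifest$discount_effects, 0.015)
  expect_equal(p1$manifest$discount_costs, 0.03)
  expect_equal(p1$manifest$friction_period_days, 160)
  expect_equal(p1$manifest$friction_elasticity, 0.8)

  # different seeds differ in the synthetic (unpublished) cells
  p3 <- synthetic_pack(2)
  expect_false(isTRUE(all.equal(p1$epidemiology$value, p3$epidemiology$value)))
  # ... but not in the published constants
  expect_equal(p3$rr_table, p1$rr_table)
})

test_that("synthetic packs validate across consecutive seeds", {
  for (s in 1:25) {
    expect_equal(nrow(validate_pack(synthetic_pack(s))), 0)
  }
})

test_that("write_pack / read_pack round-trips a pack field by field", {
  pack <- test_pack()
  dir <- withr::local_tempdir()
  write_pack(pack, dir)
  back <- read_pack(dir)
  for (nm in heeprev:::pack_table_names()) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(pack[[nm]]),
                 tolerance = 1e-12, label = nm)
  }
  expect_equal(back$manifest$discount_costs, pack$manifest$discount_costs)
  expect_equal(back$manifest$he_ratio, pack$manifest$he_ratio)
})

test_that("read_pack names the missing table", {
  pack <- test_pack()
  dir <- withr::local_tempdir()
  write_pack(pack, dir)
  file.remove(file.path(dir, "epidemiology.csv"))
  expect_error(read_pack(dir), "epidemiology")
})

test_that("each validation rule trips on the fixture that violates it", {
  pack <- test_pack()
  expect_equal(nrow(validate_pack(pack)), 0)

  # negative relative risk
  bad <- pack
  bad$rr_table$rr[5] <- -1
  rep <- validate_pack(bad)
  expect_equal(rep$table, "rr_table")

  # weight distribution summing to 0.9
  bad <- pack
  bad$weight_prevalence$p_obese[1] <- bad$weight_prevalence$p_obese[1] - 0.1
  rep <- validate_pack(bad)
  expect_true("weight_prevalence" %in% rep$table)

  # male breast-cancer incidence
  bad <- pack
  i <- which(bad$epidemiology$sex == "male" & bad$epidemiology$measure == "incidence" &
               !is.na(bad$epidemiology$disease) & bad$epidemiology$disease == "bc")[1]
  bad$epidemiology$value[i] <- 0.01
  rep <- validate_pack(bad)
  expect_match(rep$message, "breast-cancer")

  # non-stochastic tracking matrix
  bad <- pack
  bad$tracking$normal[1] <- 0.9
  expect_true("tracking" %in% validate_pack(bad)$table)

  # first-year utility above follow-up utility
  bad <- pack
  bad$utility_decrements$dec_followup[2] <- bad$utility_decrements$dec_first[2] + 0.1
  expect_true("utility_decrements" %in% validate_pack(bad)$table)

  # invalid labour-time elasticity
  bad <- pack
  bad$manifest$friction_elasticity <- 1.5
  expect_true("manifest" %in% validate_pack(bad)$table)

  # read_pack aborts on an invalid pack
  dir <- withr::local_tempdir()
  bad <- pack
  bad$weight_prevalence$p_obese[1] <- bad$weight_prevalence$p_obese[1] - 0.1
  write_pack(bad, dir)
  expect_error(read_pack(dir), "invalid parameter pack")
})

test_that("cost imputation scales Belgian costs by the expenditure ratio", {
  pack <- test_pack()
  pack$manifest$he_ratio$Greece <- 0.5
  # blank out one Greek cell and drop another entirely
  i <- which(pack$costs$country == "Greece" & pack$costs$disease == "diabetes" &
               pack$costs$age_lo == 30)
  pack$costs$direct[i] <- NA
  j <- which(pack$costs$country == "Greece" & pack$costs$disease == "stroke" &
               pack$costs$phase == "first" & pack$costs$age_lo == 30)
  pack$costs <- pack$costs[-j, ]

  be <- function(cs, dis, ph, a) {
    cs$direct[cs$country == "Belgium" & cs$disease == dis & cs$phase == ph &
                cs$age_lo == a]
  }
  filled <- impute_cost(pack, "Greece")
  gr <- function(dis, ph, a) {
    filled$direct[filled$country == "Greece" & filled$disease == dis &
                    filled$phase == ph & filled$age_lo == a]
  }
  expect_equal(gr("diabetes", "chronic", 30), be(pack$costs, "diabetes", "chronic", 30) * 0.5)
  expect_equal(gr("stroke", "first", 30), be(pack$costs, "stroke", "first", 30) * 0.5)
  # present cells untouched
  expect_equal(gr("crc", "first", 30),
               pack$costs$direct[pack$costs$country == "Greece" &
                                   pack$costs$disease == "crc" &
                                   pack$costs$phase == "first" &
                                   pack$costs$age_lo == 30])

  # ratio 1 copies Belgian values; imputing Belgium itself is the identity
  pack$manifest$he_ratio$Greece <- 1
  filled1 <- impute_cost(pack, "Greece")
  expect_equal(
    filled1$direct[filled1$country == "Greece" & filled1$disease == "diabetes" &
                     filled1$age_lo == 30],
    be(pack$costs, "diabetes", "chronic", 30)
  )
  same <- impute_cost(test_pack(), "Belgium")
  expect_equal(
    dplyr::arrange(same, country, disease, phase, age_lo)$direct,
    dplyr::arrange(test_pack()$costs, country, disease, phase, age_lo)$direct
  )
  expect_error(impute_cost(test_pack(), "Narnia"), "ratio")
})

test_that("epidemiology imputation uses Belgium-referenced incidence ratios", {
  pack <- test_pack()
  ep <- pack$epidemiology
  # make Hungary's diabetes incidence exactly twice Belgium's, then blank
  # two of its cells: they must come back at twice the Belgian cell
  hu <- ep$country == "Hungary" & ep$measure == "incidence" &
    !is.na(ep$disease) & ep$disease == "diabetes"
  be <- ep$country == "Belgium" & ep$measure == "incidence" &
    !is.na(ep$disease) & ep$disease == "diabetes"
  ep$value[hu] <- 2 * ep$value[be]
  blank <- which(hu)[c(2, 5)]
  kept <- ep$value[blank]
  ep$value[blank] <- NA
  pack$epidemiology <- ep

  out <- impute_epidemiology(pack, "Hungary", "incidence")
  expect_equal(out$value[blank], kept, tolerance = 1e-9)
  # untouched cells identical
  expect_equal(out$value[-blank], ep$value[-blank])

  # equal totals copy the Belgian values
  ep$value[hu] <- ep$value[be]
  ep$value[blank] <- NA
  pack$epidemiology <- ep
  out <- impute_epidemiology(pack, "Hungary", "incidence")
  expect_equal(out$value[blank], ep$value[which(be)[c(2, 5)]])

  # no missing cells: identity
  out <- impute_epidemiology(test_pack(), "Hungary", "incidence")
  expect_equal(out$value, test_pack()$epidemiology$value)
})
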