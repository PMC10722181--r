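test_that("direct costs annualise by 12 with admissions counted once", {
  r <- make_record(monthly_medicine = 0, monthly_diagnostic = 10000)
  d <- annualize_direct(r)
  expect_identical(d$direct_medicine, 0)
  expect_identical(d$direct_diagnostic, 120000)

  # hand summation: 1e5 * 12 + 2e6 admission = 3.2e6
  r <- make_record(monthly_treatment_nonhospital = 1e5,
                   hospitalized_last_year = TRUE, admission_cost = 2e6)
  expect_equal(annualize_direct(r)$direct_treatment, 1e5 * 12 + 2e6)

  # annualisation is linear in the monthly amount
  r2 <- make_record(monthly_medicine = 123.45)
  r3 <- make_record(monthly_medicine = 246.90)
  expect_equal(annualize_direct(r3)$direct_medicine,
               2 * annualize_direct(r2)$direct_medicine)

  # the admission contribution ignores follow-up duration
  for (fu in c(2L, 4L, 6L)) {
    r <- make_record(follow_up_months = fu, hospitalized_last_year = TRUE,
                     admission_cost = 5e6)
    expect_equal(annualize_direct(r)$direct_treatment, 5e6)
  }

  bad <- make_record()
  bad$monthly_medicine <- -1
  expect_error(annualize_direct(bad), class = "hfcoi_data_error")
})

test_that("human-capital components value lost time at the configured wages", {
  w <- wage_config(monthly_wage = 2.2e6, working_days_per_month = 22,
                   unpaid_hourly_value = 50000)
  # employed, 2 absent days/month at daily wage 100,000
  r <- make_record(employment_status = "employed", absenteeism_days = 2)
  expect_equal(human_capital_indirect(r, w)$indirect_absenteeism, 2400000)

  # housewife: unpaid work valued, absenteeism/presenteeism gated off
  r <- make_record(employment_status = "housewife", absenteeism_days = 5,
                   presenteeism_days = 4, presenteeism_efficiency = 0.5,
                   unpaid_work_hours_lost = 30)
  i <- human_capital_indirect(r, w)
  expect_equal(i$indirect_unpaid_work, 18000000)
  expect_identical(i$indirect_absenteeism, 0)
  expect_identical(i$indirect_presenteeism, 0)

  # presenteeism scales with lost efficiency
  r <- make_record(presenteeism_days = 4, presenteeism_efficiency = 0.75)
  expect_equal(human_capital_indirect(r, w)$indirect_presenteeism,
               4 * 0.25 * 1e5 * 12)

  # job change uses the configured wage differential
  wjc <- wage_config(job_change_monthly_loss = 3e5)
  r <- make_record(changed_job = TRUE)
  expect_equal(human_capital_indirect(r, wjc)$indirect_job_change, 3.6e6)
  expect_identical(human_capital_indirect(r, wage_config())$indirect_job_change, 0)
})

test_that("premature-death cost is the PV of wages to retirement", {
  w0 <- wage_config(monthly_wage = 1e7, retirement_age = 65,
                    productivity_discount_rate = 0)
  r <- make_record(died_in_year = TRUE, age_at_death = 60, age = 60)
  expect_equal(human_capital_indirect(r, w0)$indirect_premature_death,
               120e6 * 5)

  # discounted: matches an explicit term-by-term loop
  w3 <- wage_config(monthly_wage = 1e7, retirement_age = 65,
                    productivity_discount_rate = 0.03)
  loop <- sum(120e6 * (1.03)^-(1:5))
  expect_equal(human_capital_indirect(r, w3)$indirect_premature_death, loop,
               tolerance = 1e-12)

  # fractional horizon: final part-year contributes proportionally
  r2 <- make_record(died_in_year = TRUE, age_at_death = 62.5, age = 62.5)
  loop2 <- 120e6 * ((1.03)^-1 + (1.03)^-2 + 0.5 * (1.03)^-3)
  expect_equal(human_capital_indirect(r2, w3)$indirect_premature_death, loop2,
               tolerance = 1e-12)

  # at or past retirement: nothing to lose
  r3 <- make_record(died_in_year = TRUE, age_at_death = 70, age = 70)
  expect_identical(human_capital_indirect(r3, w0)$indirect_premature_death, 0)

  # deceased without an age at death is a data error
  bad <- make_record(died_in_year = TRUE, age_at_death = NA_real_)
  expect_error(human_capital_indirect(bad, w0), class = "hfcoi_data_error")
})

test_that("per-patient totals are exactly additive and wage-scale equivariant", {
  co <- generate_cohort(default_cohort_config(300L, seed = 13L))
  costs <- annual_patient_costs(co, wage_config())
  expect_identical(costs$grand_total, costs$direct_total + costs$indirect_total)
  expect_identical(costs$direct_total,
                   costs$direct_medicine + costs$direct_treatment +
                     costs$direct_diagnostic + costs$direct_non_medical)
  expect_identical(costs$indirect_total,
                   costs$indirect_absenteeism + costs$indirect_presenteeism +
                     costs$indirect_unpaid_work + costs$indirect_job_change +
                     costs$indirect_premature_death)
  # mean/total commutation
  expect_equal(mean(costs$grand_total),
               mean(costs$direct_total) + mean(costs$indirect_total))

  k <- 3.7
  w1 <- wage_config()
  wk <- wage_config(monthly_wage = w1$monthly_wage * k,
                    unpaid_hourly_value = w1$unpaid_hourly_value * k,
                    job_change_monthly_loss = 0)
  i1 <- human_capital_indirect(co, w1)
  ik <- human_capital_indirect(co, wk)
  for (cc in setdiff(names(i1), "id")) {
    expect_equal(ik[[cc]], k * i1[[cc]], tolerance = 1e-12)
  }
})

test_that("cohort aggregation reports means, n-1 SDs and reconciled shares", {
  co <- generate_cohort(default_cohort_config(150L, seed = 17L))
  costs <- annual_patient_costs(co)
  bd <- aggregate_breakdown(costs, co$nyha_class)
  cs <- bd$component_stats
  expect_equal(cs$mean[cs$component == "grand_total"], mean(costs$grand_total))
  expect_equal(cs$sd[cs$component == "grand_total"], stats::sd(costs$grand_total))
  di <- bd$shares$direct_indirect
  expect_equal(sum(di$share_raw), 100, tolerance = 1e-12)
  expect_true(all(di$share_raw >= 0 & di$share_raw <= 100))
  expect_equal(sum(bd$shares$by_class$share_raw), 100, tolerance = 1e-12)

  # single patient: degenerate SDs flagged, reported as zero
  one <- annual_patient_costs(co[1, ])
  expect_warning(bd1 <- aggregate_breakdown(one, co$nyha_class[1]),
                 "degenerate")
  expect_true(bd1$degenerate_sd)
  expect_true(all(bd1$component_stats$sd == 0))
  expect_equal(bd1$component_stats$mean[bd1$component_stats$component == "grand_total"],
               one$grand_total)

  expect_error(aggregate_breakdown(one[0, ], integer(0)), class = "hfcoi_data_error")
  expect_error(aggregate_breakdown(one, 5L), class = "hfcoi_data_error")
})

test_that("PPP conversion divides by the factor and shares round half-up", {
  expect_equal(convert_to_ppp(123.456, 1), 123.46)
  expect_identical(convert_to_ppp(0, 11900), 0)
  expect_equal(convert_to_ppp(261409854.9, 11900), 21967.21)
  expect_error(convert_to_ppp(1, 0), class = "hfcoi_config_error")

  expect_identical(round_half_up(c(20.5, 79.5, -2.5)), c(21, 80, -3))
  sh <- percentage_shares(c(a = 1, b = 3))
  expect_equal(sh$share_raw, c(25, 75))
  expect_error(percentage_shares(c(0, 0)), class = "hfcoi_data_error")
})
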