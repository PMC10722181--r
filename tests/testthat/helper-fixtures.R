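# Shared fixtures: all built in code at test time.

# one-row cohort record with every field explicit, for arithmetic checks
make_record <- function(id = 1L, age = 60, gender = "male", nyha_class = 2L,
                        basic_insurance = TRUE, complementary_insurance = FALSE,
                        comorbidity = FALSE, household_head = TRUE,
                        employment_status = "employed", follow_up_months = 4L,
                        monthly_medicine = 0, monthly_treatment_nonhospital = 0,
                        monthly_diagnostic = 0, monthly_non_medical = 0,
                        hospitalized_last_year = FALSE, admission_cost = 0,
                        absenteeism_days = 0, presenteeism_days = 0,
                        presenteeism_efficiency = 1, unpaid_work_hours_lost = 0,
                        changed_job = FALSE, died_in_year = FALSE,
                        age_at_death = NA_real_) {
  data.frame(id = id, age = age, gender = gender, nyha_class = nyha_class,
             basic_insurance = basic_insurance,
             complementary_insurance = complementary_insurance,
             comorbidity = comorbidity, household_head = household_head,
             employment_status = employment_status,
             follow_up_months = follow_up_months,
             monthly_medicine = monthly_medicine,
             monthly_treatment_nonhospital = monthly_treatment_nonhospital,
             monthly_diagnostic = monthly_diagnostic,
             monthly_non_medical = monthly_non_medical,
             hospitalized_last_year = hospitalized_last_year,
             admission_cost = admission_cost,
             absenteeism_days = absenteeism_days,
             presenteeism_days = presenteeism_days,
             presenteeism_efficiency = presenteeism_efficiency,
             unpaid_work_hours_lost = unpaid_work_hours_lost,
             changed_job = changed_job, died_in_year = died_in_year,
             age_at_death = age_at_death, stringsAsFactors = FALSE)
}

# random but valid six-state spec: alive rows renormalised runif mass,
# absorbing death rows, random costs, random initial mix over alive states
random_markov_spec <- function(seed, horizon = 10L, discount = 0,
                               half_cycle = FALSE) {
  set.seed(seed)
  P <- matrix(0, 6, 6)
  for (i in 1:4) {
    w <- stats::runif(6)
    P[i, ] <- w / sum(w)
  }
  P[5, ] <- c(0, 0, 0, 0, 1, 0)
  P[6, ] <- c(0, 0, 0, 0, 0, 1)
  init <- stats::runif(4)
  markov_spec(
    transition_matrix = P,
    initial_distribution = c(init / sum(init), 0, 0),
    state_annual_cost = stats::runif(4, 1e6, 5e8),
    death_hf_entry_cost = stats::runif(1, 0, 2e9),
    horizon_cycles = horizon,
    discount_rate = discount,
    half_cycle_correction = half_cycle
  )
}

# single alive state that stays with probability 1 - q and otherwise dies
# (split between the two death states), with unit mass starting there
chain_spec <- function(q, to_hf = 0.5, cost = 1, entry = 0, horizon = 25L,
                       discount = 0, half_cycle = FALSE) {
  P <- diag(6)
  P[1, 1] <- 1 - q
  P[1, 5] <- q * to_hf
  P[1, 6] <- q * (1 - to_hf)
  markov_spec(P, c(1, 0, 0, 0, 0, 0), c(cost, 0, 0, 0),
              death_hf_entry_cost = entry, horizon_cycles = horizon,
              discount_rate = discount, half_cycle_correction = half_cycle)
}

# independent probit log-likelihood, written from the definition so probit
# fits can be checked against brute force without touching the fit path
oracle_probit_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * stats::pnorm(eta, log.p = TRUE) +
        (1 - y) * stats::pnorm(-eta, log.p = TRUE))
}
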