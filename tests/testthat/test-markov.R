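test_that("spec validation reports every violation, not just the first", {
  # identity matrix with alive self-loops is degenerate but legal
  sp <- markov_spec(diag(6), c(0.25, 0.25, 0.25, 0.25, 0, 0),
                    c(1, 2, 3, 4))
  expect_s3_class(sp, "markov_spec")

  P <- diag(6)
  P[2, 2] <- 0.9             # row sums to 0.9
  P[5, 5] <- 0.9             # DeathHF leaks 0.1
  P[5, 1] <- 0.1
  err <- tryCatch(
    markov_spec(P, c(1, 0, 0, 0, 0, 0), c(1, 1, 1, 1)),
    error = function(e) conditionMessage(e))
  expect_match(err, "row 2")
  expect_match(err, "DeathHF")

  expect_error(markov_spec(diag(6), c(0.5, 0, 0, 0, 0.5, 0), c(1, 1, 1, 1)),
               "death states", class = "hfcoi_config_error")
})

test_that("closed-form chains reproduce exact lifetime costs and life-years", {
  # immortal self-loop: T cycles at cost c, all attributed to NYHA1
  res <- run_markov_cohort(chain_spec(q = 0, cost = 123, horizon = 25L))
  expect_equal(res$lifetime_total, 25 * 123, tolerance = 1e-12)
  expect_equal(unname(res$per_state["NYHA1"]), 25 * 123, tolerance = 1e-12)
  expect_equal(unname(res$per_state[2:5]), rep(0, 4))
  expect_equal(life_years(res), 25)

  # zero costs: zero total whatever the matrix
  sp <- random_markov_spec(3, horizon = 12L)
  sp$state_annual_cost[] <- 0
  sp$death_hf_entry_cost <- 0
  expect_identical(run_markov_cohort(sp)$lifetime_total, 0)

  # geometric survival: life-years = sum_{t=0}^{T-1} (1-q)^t
  q <- 0.23
  res <- run_markov_cohort(chain_spec(q = q, horizon = 25L))
  expect_equal(life_years(res), sum((1 - q)^(0:24)), tolerance = 1e-9)

  # entry-cost accounting: mass entering DeathHF each cycle is q*to_hf*(1-q)^t
  entry <- 1e6
  res <- run_markov_cohort(chain_spec(q = q, to_hf = 0.4, cost = 0,
                                      entry = entry, horizon = 25L))
  expect_equal(unname(res$per_state["DeathHF"]),
               entry * 0.4 * q * sum((1 - q)^(0:24)), tolerance = 1e-9)
})

test_that("cohort recursion agrees with independent microsimulation", {
  for (seed in c(2, 7)) {
    sp <- random_markov_spec(seed, horizon = 10L,
                             discount = if (seed == 7) 0.03 else 0)
    res <- run_markov_cohort(sp)
    sim <- microsimulate_markov(sp, n_paths = 3e4, seed = seed + 100)
    expect_lt(abs(res$lifetime_total - sim$mean_cost), 3 * sim$se)
    expect_equal(res$p_death_hf, sim$p_death_hf, tolerance = 0.02)
    expect_equal(res$life_years, sim$mean_life_years, tolerance = 0.05)
  }
  # half-cycle corrected variant agrees too
  sp <- random_markov_spec(5, horizon = 8L, half_cycle = TRUE)
  res <- run_markov_cohort(sp)
  sim <- microsimulate_markov(sp, n_paths = 3e4, seed = 55)
  expect_lt(abs(res$lifetime_total - sim$mean_cost), 3 * sim$se)
})

test_that("occupancy conserves probability and absorbing mass is monotone", {
  for (seed in 1:5) {
    sp <- random_markov_spec(seed, horizon = 15L)
    res <- run_markov_cohort(sp)
    expect_true(all(abs(rowSums(res$trace) - 1) < 1e-9))
    expect_true(all(diff(res$trace[, "DeathHF"]) >= -1e-12))
    expect_true(all(diff(res$trace[, "DeathOther"]) >= -1e-12))
    # attribution completeness at machine precision
    expect_equal(sum(res$per_state), res$lifetime_total,
                 tolerance = 1e-12)
  }
})

test_that("lifetime cost is monotone in costs and antitone in discounting", {
  sp <- random_markov_spec(9, horizon = 12L)
  base <- run_markov_cohort(sp)$lifetime_total
  up <- sp
  up$state_annual_cost[2] <- up$state_annual_cost[2] * 2
  expect_gte(run_markov_cohort(up)$lifetime_total, base)
  up <- sp
  up$death_hf_entry_cost <- up$death_hf_entry_cost + 1e8
  expect_gte(run_markov_cohort(up)$lifetime_total, base)
  disc <- sp
  disc$discount_rate <- 0.05
  expect_lte(run_markov_cohort(disc)$lifetime_total, base)
})

test_that("a horizon splits into head plus discounted continuation", {
  for (seed in c(4, 12)) {
    sp <- random_markov_spec(seed, horizon = 20L, discount = 0.03)
    full <- run_markov_cohort(sp)$lifetime_total
    t1 <- 8L
    head_spec <- sp
    head_spec$horizon_cycles <- t1
    head_res <- run_markov_cohort(head_spec)
    tail_spec <- sp
    tail_spec$horizon_cycles <- sp$horizon_cycles - t1
    tail_spec$initial_distribution[] <- head_res$trace[t1 + 1L, ]
    tail_res <- run_markov_cohort(tail_spec, validate = FALSE)
    combined <- head_res$lifetime_total +
      (1 + sp$discount_rate)^(-t1) * tail_res$lifetime_total
    expect_equal(combined, full, tolerance = 1e-9)
  }
})

test_that("state shares are scale-invariant percentages of the total", {
  v <- c(NYHA1 = 10, NYHA2 = 0, NYHA3 = 0, NYHA4 = 0, DeathHF = 0)
  sh <- state_shares(v)
  expect_equal(sh$share_raw, c(100, 0, 0, 0, 0))
  v2 <- c(NYHA1 = 1, NYHA2 = 2, NYHA3 = 3, NYHA4 = 4, DeathHF = 5)
  expect_equal(state_shares(v2)$share_raw, state_shares(v2 * 17)$share_raw)
  expect_error(state_shares(v2 * 0), class = "hfcoi_data_error")
})

test_that("markov specs round-trip through YAML and JSON", {
  sp <- random_markov_spec(6, horizon = 9L, discount = 0.03)
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_markov_spec(sp, p)
    back <- read_markov_spec(p)
    expect_equal(back$transition_matrix, sp$transition_matrix,
                 tolerance = 1e-12)
    expect_equal(back$initial_distribution, sp$initial_distribution,
                 tolerance = 1e-12)
    expect_equal(back$state_annual_cost, sp$state_annual_cost,
                 tolerance = 1e-12)
    expect_identical(back$horizon_cycles, sp$horizon_cycles)
  }
})

test_that("transition-matrix calibration moves per-state costs toward targets", {
  # truth lies inside the searchable family: next-class progression + HF death
  # + fixed 0.05 background mortality
  bg <- 0.05
  prog <- c(0.20, 0.18, 0.15, 0)
  dhf <- c(0.06, 0.08, 0.12, 0.20)
  P <- matrix(0, 6, 6)
  for (i in 1:4) {
    P[i, 6] <- bg
    P[i, 5] <- dhf[i]
    if (i < 4) P[i, i + 1] <- prog[i]
    P[i, i] <- 1 - bg - dhf[i] - prog[i]
  }
  P[5, 5] <- 1
  P[6, 6] <- 1
  truth <- markov_spec(P, c(0.25, 0.25, 0.25, 0.25, 0, 0),
                       c(1e8, 2e8, 3e8, 4e8), death_hf_entry_cost = 1e9,
                       horizon_cycles = 15L)
  target <- run_markov_cohort(truth)$per_state

  start <- truth
  start$transition_matrix <- default_markov_spec(horizon_cycles = 15L)$transition_matrix
  denom <- pmax(target, 1)
  start_obj <- sum(((run_markov_cohort(start)$per_state - target) / denom)^2)
  cal <- calibrate_transition_matrix(target, start, maxit = 500L)
  expect_s3_class(cal$spec, "markov_spec")
  expect_lt(cal$objective, start_obj)
})
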