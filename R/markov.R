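markov_states <- function() {
  c("NYHA1", "NYHA2", "NYHA3", "NYHA4", "DeathHF", "DeathOther")
}

#' Six-state Markov cohort model specification
#'
#' States are NYHA classes I-IV plus two absorbing death states: death from
#' heart failure (DeathHF) and death from other causes (DeathOther). Costs
#' accrue annually in the four alive states; DeathHF additionally charges a
#' one-time entry cost (the present value of earnings lost at death), which is
#' the only reading under which a death state can carry a large share of
#' lifetime cost. DeathOther accrues nothing.
#'
#' @param transition_matrix 6x6 per-cycle transition probabilities, rows
#'   ordered NYHA1..NYHA4, DeathHF, DeathOther; each row sums to 1 and both
#'   death rows are absorbing.
#' @param initial_distribution probability 6-vector over states at cycle 0;
#'   must put no mass on the death states.
#' @param state_annual_cost Toman/year for the four alive states.
#' @param death_hf_entry_cost Toman charged once on entry into DeathHF.
#' @param horizon_cycles number of one-year cycles (default 25).
#' @param discount_rate annual discount rate in `[0, 1)` (default 0).
#' @param half_cycle_correction if TRUE, occupancy costs (and life-years) use
#'   the average of adjacent cycle-start occupancies.
#' @return an object of class `markov_spec`.
#' @export
markov_spec <- function(transition_matrix,
                        initial_distribution,
                        state_annual_cost,
                        death_hf_entry_cost = 0,
                        horizon_cycles = 25L,
                        discount_rate = 0,
                        half_cycle_correction = FALSE) {
  P <- as.matrix(transition_matrix)
  dimnames(P) <- list(markov_states(), markov_states())
  spec <- structure(
    list(transition_matrix = P,
         initial_distribution = stats::setNames(as.numeric(initial_distribution),
                                                markov_states()),
         state_annual_cost = stats::setNames(as.numeric(state_annual_cost),
                                             markov_states()[1:4]),
         death_hf_entry_cost = death_hf_entry_cost,
         horizon_cycles = as.integer(horizon_cycles),
         cycle_length = 1,
         discount_rate = discount_rate,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "markov_spec"
  )
  validate_markov_spec(spec)
}

#' Validate a Markov specification
#'
#' Checks every structural invariant and, on failure, raises a configuration
#' error whose message enumerates all violations (never just the first):
#' row sums within 1e-9 of 1, entries in `[0, 1]`, both death states
#' absorbing, initial distribution a probability vector with zero death mass,
#' non-negative costs, horizon >= 1, discount rate in `[0, 1)`.
#'
#' @param spec a `markov_spec`.
#' @return the spec if valid; otherwise an error listing all violations.
#' @export
validate_markov_spec <- function(spec) {
  if (!inherits(spec, "markov_spec")) stop_config("not a markov_spec object")
  errs <- character(0)
  P <- spec$transition_matrix
  if (!is.numeric(P) || !all(dim(P) == c(6L, 6L))) {
    errs <- c(errs, "transition_matrix must be a numeric 6x6 matrix")
  } else {
    if (any(P < 0 | P > 1)) {
      bad <- which(P < 0 | P > 1, arr.ind = TRUE)
      errs <- c(errs, sprintf("transition probability out of [0,1] at (%s)",
                              paste(apply(bad, 1, paste, collapse = ","),
                                    collapse = "; ")))
    }
    rs <- rowSums(P)
    off <- which(abs(rs - 1) > 1e-9)
    for (i in off) {
      errs <- c(errs, sprintf("row %d (%s) sums to %.12g, not 1",
                              i, markov_states()[i], rs[i]))
    }
    for (i in 5:6) {
      if (abs(P[i, i] - 1) > 1e-9 || any(abs(P[i, -i]) > 1e-9)) {
        errs <- c(errs, sprintf("state %s must be absorbing (self-transition 1)",
                                markov_states()[i]))
      }
    }
  }
  pi0 <- spec$initial_distribution
  if (length(pi0) != 6L || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-9) {
    errs <- c(errs, "initial_distribution must be a probability 6-vector summing to 1")
  } else if (any(pi0[5:6] > 0)) {
    errs <- c(errs, "initial_distribution must put zero mass on the death states")
  }
  if (length(spec$state_annual_cost) != 4L || any(is.na(spec$state_annual_cost)) ||
      any(spec$state_annual_cost < 0)) {
    errs <- c(errs, "state_annual_cost must be four non-negative values")
  }
  if (!is_nonneg_num(spec$death_hf_entry_cost)) {
    errs <- c(errs, "death_hf_entry_cost must be >= 0")
  }
  if (!is_count(spec$horizon_cycles) || spec$horizon_cycles < 1L) {
    errs <- c(errs, "horizon_cycles must be an integer >= 1")
  }
  if (!is.numeric(spec$discount_rate) || spec$discount_rate < 0 ||
      spec$discount_rate >= 1) {
    errs <- c(errs, "discount_rate must lie in [0, 1)")
  }
  if (length(errs)) {
    stop_config("invalid markov_spec:\n  - ", paste(errs, collapse = "\n  - "))
  }
  spec
}

#' @export
print.markov_spec <- function(x, ...) {
  cat("<markov_spec> horizon", x$horizon_cycles, "one-year cycles, discount",
      x$discount_rate, if (x$half_cycle_correction) "(half-cycle corrected)",
      "\n")
  cat("  initial:", paste(sprintf("%s %.3f", markov_states(),
                                  x$initial_distribution), collapse = ", "), "\n")
  invisible(x)
}

#' Run the Markov cohort model
#'
#' Propagates the occupancy distribution through the transition matrix
#' (`pi_{t+1} = pi_t P`) for `horizon_cycles` one-year cycles, accruing in
#' cycle `t` (discounted by `(1+r)^-t`): each alive state's occupancy times
#' its annual cost, plus the probability mass newly entering DeathHF times
#' the one-time entry cost. With half-cycle correction, occupancy costs and
#' life-years use the average of the cycle-start and cycle-end occupancies;
#' the entry cost is unaffected (entry mass is already an increment).
#'
#' @param spec a validated [markov_spec()].
#' @param validate set FALSE only to restart the recursion from a saved
#'   occupancy row (which may carry death-state mass, normally rejected).
#' @return an object of class `markov_result`: list with `trace`
#'   ((horizon+1) x 6 occupancy matrix), `lifetime_total` (Toman),
#'   `per_state` (attributed cost, NYHA1..4 + DeathHF), `shares`
#'   (via [percentage_shares()], NULL if the total is 0), `life_years`,
#'   `p_death_hf` (DeathHF occupancy at the horizon), and the `spec`.
#' @export
run_markov_cohort <- function(spec, validate = TRUE) {
  if (validate) validate_markov_spec(spec)
  P <- spec$transition_matrix
  T_ <- spec$horizon_cycles
  trace <- matrix(0, nrow = T_ + 1L, ncol = 6L,
                  dimnames = list(cycle = 0:T_, state = markov_states()))
  trace[1L, ] <- spec$initial_distribution
  for (t in seq_len(T_)) {
    trace[t + 1L, ] <- drop(trace[t, ] %*% P)
  }
  disc <- (1 + spec$discount_rate)^(-(0:(T_ - 1L)))
  occ_alive <- trace[1:T_, 1:4, drop = FALSE]
  if (spec$half_cycle_correction) {
    occ_alive <- (occ_alive + trace[2:(T_ + 1L), 1:4, drop = FALSE]) / 2
  }
  # per-cycle, per-state occupancy cost
  state_cost <- sweep(occ_alive, 2, spec$state_annual_cost, `*`) * disc
  entry_mass <- diff(trace[, "DeathHF"])
  entry_cost <- entry_mass * spec$death_hf_entry_cost * disc
  per_state <- c(colSums(state_cost), DeathHF = sum(entry_cost))
  lifetime_total <- sum(per_state)
  ly <- sum(rowSums(occ_alive)) * spec$cycle_length
  structure(
    list(trace = trace,
         lifetime_total = lifetime_total,
         per_state = per_state,
         shares = if (lifetime_total > 0) percentage_shares(per_state) else NULL,
         life_years = ly,
         p_death_hf = trace[T_ + 1L, "DeathHF"],
         spec = spec),
    class = "markov_result"
  )
}

#' @export
print.markov_result <- function(x, ...) {
  cat("<markov_result> lifetime cost:", fmt_toman(x$lifetime_total, 0),
      "Toman over", x$spec$horizon_cycles, "cycles\n")
  cat("  life-years:", sprintf("%.3f", x$life_years),
      "| P(death from HF):", sprintf("%.3f", x$p_death_hf), "\n")
  if (!is.null(x$shares)) {
    cat("  shares (%):", paste(sprintf("%s %d", x$shares$component,
                                       x$shares$share_rounded),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-state lifetime-cost shares
#'
#' @param result a `markov_result`, or a named non-negative vector of
#'   per-state attributed costs.
#' @return data.frame from [percentage_shares()] (raw and integer-rounded).
#' @export
state_shares <- function(result) {
  v <- if (inherits(result, "markov_result")) result$per_state else result
  if (sum(v) <= 0) stop_data("state shares are undefined for a zero lifetime total")
  percentage_shares(v)
}

#' Expected (undiscounted-by-default) life-years of a Markov result
#'
#' Sum over cycles of alive-state occupancy mass times the cycle length,
#' using the same half-cycle option as the costs.
#'
#' @param result a `markov_result`.
#' @return expected life-years over the model horizon.
#' @export
life_years <- function(result) {
  stopifnot(inherits(result, "markov_result"))
  result$life_years
}

#' Microsimulation cross-check of the cohort model
#'
#' Samples `n_paths` individual state trajectories from the transition matrix
#' and accrues, per path, exactly the costs the cohort recursion accrues in
#' expectation: the annual cost of the occupied alive state each cycle and
#' the one-time DeathHF entry cost at the entry cycle, both discounted at the
#' cycle index. Implemented by path sampling, independently of the matrix
#' recursion, so the two can validate each other.
#'
#' @param spec a validated [markov_spec()].
#' @param n_paths number of simulated trajectories.
#' @param seed RNG seed.
#' @return list with `mean_cost`, `se` (Monte-Carlo standard error),
#'   `per_state` (mean attributed cost), `mean_life_years`, `p_death_hf`.
#' @export
microsimulate_markov <- function(spec, n_paths = 1e5, seed = 1L) {
  validate_markov_spec(spec)
  n <- as.integer(n_paths)
  T_ <- spec$horizon_cycles
  with_seed(seed, {
    cumP <- t(apply(spec$transition_matrix, 1, cumsum))
    state <- sample.int(6L, n, replace = TRUE,
                        prob = spec$initial_distribution)
    disc <- (1 + spec$discount_rate)^(-(0:(T_ - 1L)))
    cost6 <- c(spec$state_annual_cost, 0, 0)
    total <- numeric(n)
    per_state <- stats::setNames(numeric(5), markov_states()[1:5])
    alive_years <- numeric(n)
    hcc <- spec$half_cycle_correction
    for (t in seq_len(T_)) {
      u <- stats::runif(n)
      nxt <- 1L + rowSums(u > cumP[state, 1:5, drop = FALSE])
      alive_now <- state <= 4L
      alive_next <- nxt <= 4L
      occ_w <- if (hcc) (alive_now + alive_next) / 2 else as.numeric(alive_now)
      # occupancy cost: with hcc, average the start- and end-of-cycle state costs
      if (hcc) {
        cyc_cost <- (cost6[state] + cost6[nxt]) / 2 * disc[t]
        for (s in 1:4) {
          per_state[s] <- per_state[s] +
            (sum(cost6[s] * (state == s)) + sum(cost6[s] * (nxt == s))) / 2 *
            disc[t] / n
        }
      } else {
        cyc_cost <- cost6[state] * disc[t]
        for (s in 1:4) {
          per_state[s] <- per_state[s] + cost6[s] * sum(state == s) * disc[t] / n
        }
      }
      entered_hf <- state != 5L & nxt == 5L
      cyc_cost <- cyc_cost + entered_hf * spec$death_hf_entry_cost * disc[t]
      per_state["DeathHF"] <- per_state["DeathHF"] +
        sum(entered_hf) * spec$death_hf_entry_cost * disc[t] / n
      total <- total + cyc_cost
      alive_years <- alive_years + occ_w * spec$cycle_length
      state <- nxt
    }
    list(mean_cost = mean(total),
         se = stats::sd(total) / sqrt(n),
         per_state = per_state,
         mean_life_years = mean(alive_years),
         p_death_hf = mean(state == 5L))
  })
}

#' Default six-state model specification
#'
#' Ships a clearly synthetic placeholder transition matrix (the transition
#' probabilities used in the source study are not published), the published
#' NYHA class mix as the initial distribution, the published per-class annual
#' cost means as state costs, and a DeathHF entry cost equal to the present
#' value of annual wages from the cohort's mean age to retirement. Intended
#' as a runnable starting point; substantive analyses must supply their own
#' evidence-based matrix, e.g. via [read_markov_spec()] or
#' [calibrate_transition_matrix()].
#'
#' @param wages a [wage_config()] used for the DeathHF entry cost.
#' @param horizon_cycles,discount_rate,half_cycle_correction passed to
#'   [markov_spec()].
#' @return a validated `markov_spec`.
#' @export
default_markov_spec <- function(wages = wage_config(),
                                horizon_cycles = 25L,
                                discount_rate = 0,
                                half_cycle_correction = FALSE) {
  P <- matrix(c(
    0.70, 0.15, 0.04, 0.01, 0.03, 0.07,
    0.05, 0.65, 0.15, 0.05, 0.04, 0.06,
    0.00, 0.05, 0.60, 0.20, 0.08, 0.07,
    0.00, 0.00, 0.05, 0.55, 0.25, 0.15,
    0.00, 0.00, 0.00, 0.00, 1.00, 0.00,
    0.00, 0.00, 0.00, 0.00, 0.00, 1.00
  ), nrow = 6, byrow = TRUE)
  ref <- hf_reference_costs()
  class_means <- ref$mean[match(paste0("class_", 1:4), ref$component)]
  entry <- present_value_annuity(wages$monthly_wage * 12,
                                 max(0, wages$retirement_age - 63.46),
                                 wages$productivity_discount_rate)
  markov_spec(
    transition_matrix = P,
    initial_distribution = c(c(106, 189, 88, 119) / 502, 0, 0),
    state_annual_cost = class_means,
    death_hf_entry_cost = entry,
    horizon_cycles = horizon_cycles,
    discount_rate = discount_rate,
    half_cycle_correction = half_cycle_correction
  )
}

#' Calibrate a transition matrix to target per-state costs
#'
#' Convenience least-squares search (not a published method): parameterises
#' each alive state's one-step progression probability and HF-death
#' probability (death from other causes fixed at `background_mortality`),
#' then minimises the relative squared error between the model's per-state
#' attributed costs and `target_per_state` using Nelder-Mead on
#' logit-transformed parameters.
#'
#' @param target_per_state named 5-vector (NYHA1..4, DeathHF) of target
#'   attributed lifetime costs, Toman.
#' @param spec a `markov_spec` providing costs, horizon, discounting and the
#'   initial distribution; the search itself starts from a fixed interior
#'   parameter point.
#' @param background_mortality per-cycle death probability from other causes,
#'   applied to every alive state.
#' @param maxit optimiser iteration cap.
#' @return list with `spec` (calibrated), `objective` (final relative SSE),
#'   and `convergence` (optim code).
#' @export
calibrate_transition_matrix <- function(target_per_state, spec,
                                        background_mortality = 0.05,
                                        maxit = 500L) {
  validate_markov_spec(spec)
  if (length(target_per_state) != 5L || any(target_per_state < 0)) {
    stop_config("'target_per_state' must be five non-negative costs")
  }
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  build <- function(theta) {
    prog <- inv_logit(theta[1:3]) * (1 - background_mortality)
    dhf <- inv_logit(theta[4:7]) * (1 - background_mortality)
    P <- matrix(0, 6, 6)
    for (i in 1:4) {
      p_up <- if (i < 4) min(prog[i], 1 - background_mortality - dhf[i]) else 0
      p_dhf <- min(dhf[i], 1 - background_mortality - p_up)
      P[i, 6] <- background_mortality
      P[i, 5] <- p_dhf
      if (i < 4) P[i, i + 1] <- p_up
      P[i, i] <- 1 - background_mortality - p_dhf - p_up
    }
    P[5, 5] <- 1
    P[6, 6] <- 1
    P
  }
  obj <- function(theta) {
    P <- build(theta)
    s <- spec
    s$transition_matrix <- P
    dimnames(s$transition_matrix) <- list(markov_states(), markov_states())
    res <- run_markov_cohort(s)
    denom <- pmax(target_per_state, 1)
    sum(((res$per_state - target_per_state) / denom)^2)
  }
  theta0 <- c(logit(rep(0.15, 3)), logit(rep(0.08, 4)))
  fit <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  out <- spec
  out$transition_matrix <- build(fit$par)
  dimnames(out$transition_matrix) <- list(markov_states(), markov_states())
  list(spec = validate_markov_spec(out), objective = fit$value,
       convergence = fit$convergence)
}

#' Write / read a Markov specification
#'
#' YAML or JSON serialisation (by file extension); the transition matrix is
#' stored as a row-major list of rows.
#'
#' @param spec a validated [markov_spec()].
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `write_markov_spec()` returns `path` invisibly;
#'   `read_markov_spec()` a validated `markov_spec`.
#' @export
write_markov_spec <- function(spec, path) {
  validate_markov_spec(spec)
  x <- list(
    states = markov_states(),
    transition_matrix = lapply(seq_len(6), function(i)
      as.numeric(spec$transition_matrix[i, ])),
    initial_distribution = as.numeric(spec$initial_distribution),
    state_annual_cost = as.numeric(spec$state_annual_cost),
    death_hf_entry_cost = spec$death_hf_entry_cost,
    horizon_cycles = spec$horizon_cycles,
    discount_rate = spec$discount_rate,
    half_cycle_correction = spec$half_cycle_correction
  )
  write_config_file(x, path)
  invisible(path)
}

#' @rdname write_markov_spec
#' @export
read_markov_spec <- function(path) {
  x <- read_config_file(path)
  need <- c("transition_matrix", "initial_distribution", "state_annual_cost")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_config("markov spec file is missing fields: ",
                paste(miss, collapse = ", "))
  }
  P <- if (is.matrix(x$transition_matrix)) {
    x$transition_matrix
  } else {
    do.call(rbind, lapply(x$transition_matrix, as.numeric))
  }
  markov_spec(
    transition_matrix = P,
    initial_distribution = as.numeric(x$initial_distribution),
    state_annual_cost = as.numeric(x$state_annual_cost),
    death_hf_entry_cost = x$death_hf_entry_cost %||% 0,
    horizon_cycles = x$horizon_cycles %||% 25L,
    discount_rate = x$discount_rate %||% 0,
    half_cycle_correction = isTRUE(x$half_cycle_correction)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
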