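#' Wage configuration for human-capital valuation
#'
#' Parameters used to turn lost time into Toman: the gross market wage for
#' absenteeism/presenteeism/premature death, a replacement (shadow) hourly
#' wage for unpaid work, the retirement age bounding the premature-death
#' earnings horizon, and an annual discount rate for the present value of
#' future lost earnings (default 0, i.e. simple summation).
#'
#' @param monthly_wage gross monthly wage, Toman.
#' @param working_days_per_month days; daily wage = monthly_wage / this.
#' @param unpaid_hourly_value replacement wage for unpaid work, Toman/hour.
#' @param retirement_age years.
#' @param productivity_discount_rate annual rate in `[0, 1)`.
#' @param job_change_monthly_loss monthly wage differential after a
#'   disease-driven job change, Toman (default 0).
#' @return an object of class `wage_config`.
#' @export
wage_config <- function(monthly_wage = 10e6,
                        working_days_per_month = 22,
                        unpaid_hourly_value = 50e3,
                        retirement_age = 65,
                        productivity_discount_rate = 0,
                        job_change_monthly_loss = 0) {
  for (f in c("monthly_wage", "working_days_per_month", "unpaid_hourly_value",
              "retirement_age")) {
    if (!is_pos_num(get(f))) stop_config("'", f, "' must be positive")
  }
  if (!is.numeric(productivity_discount_rate) ||
      productivity_discount_rate < 0 || productivity_discount_rate >= 1) {
    stop_config("'productivity_discount_rate' must lie in [0, 1)")
  }
  if (!is_nonneg_num(job_change_monthly_loss)) {
    stop_config("'job_change_monthly_loss' must be >= 0")
  }
  structure(
    list(monthly_wage = monthly_wage,
         working_days_per_month = working_days_per_month,
         unpaid_hourly_value = unpaid_hourly_value,
         retirement_age = retirement_age,
         productivity_discount_rate = productivity_discount_rate,
         job_change_monthly_loss = job_change_monthly_loss),
    class = "wage_config"
  )
}

#' Annualise direct cost components
#'
#' Person-month measure: each observed monthly cost is multiplied by 12.
#' The exception is inpatient cost — the admission cost already covers the
#' last year, so it enters the treatment component once, not times 12, and is
#' invariant to the follow-up duration.
#'
#' @param records cohort data.frame ([validate_patient_records()] contract).
#' @return data.frame with `id` and annual `direct_medicine`,
#'   `direct_treatment`, `direct_diagnostic`, `direct_non_medical`
#'   (Toman/year).
#' @export
annualize_direct <- function(records) {
  validate_patient_records(records)
  if (nrow(records) > 0 && any(records$follow_up_months <= 0)) {
    stop_data("'follow_up_months' must be positive")
  }
  data.frame(
    id = records$id,
    direct_medicine = records$monthly_medicine * 12,
    direct_treatment = records$monthly_treatment_nonhospital * 12 +
      ifelse(records$hospitalized_last_year, records$admission_cost, 0),
    direct_diagnostic = records$monthly_diagnostic * 12,
    direct_non_medical = records$monthly_non_medical * 12
  )
}

#' Present value of an annual amount lost over future years
#'
#' Year-end convention: an annual loss `a` over `years` full years discounted
#' at rate `r` is `a * sum_{t=1..years} (1+r)^(-t)`; fractional final years
#' contribute proportionally. With `r = 0` this is `a * years`.
#'
#' @param annual_amount Toman/year.
#' @param years non-negative horizon (may be fractional).
#' @param rate annual discount rate in `[0, 1)`.
#' @return present value, Toman.
#' @export
present_value_annuity <- function(annual_amount, years, rate = 0) {
  if (any(years < 0)) stop_data("'years' must be non-negative")
  full <- floor(years)
  frac <- years - full
  pv_full <- if (rate == 0) full else (1 - (1 + rate)^(-full)) / rate
  pv_frac <- frac * (1 + rate)^(-(full + 1))
  annual_amount * (pv_full + pv_frac)
}

#' Human-capital indirect cost components
#'
#' Values the five productivity losses at wages:
#' * absenteeism: days absent/month x daily wage x 12 (employed only);
#' * presenteeism: days at reduced productivity/month x (1 - residual
#'   efficiency) x daily wage x 12 (employed only);
#' * unpaid work: hours lost/month x replacement hourly wage x 12 (all
#'   patients — housework, care-giving and voluntary activity have value
#'   regardless of employment);
#' * job change: 12 x configured monthly wage differential if the patient
#'   changed jobs because of the disease;
#' * premature death: for deceased patients, the discounted present value of
#'   a year's wages over the years from death to retirement age
#'   ([present_value_annuity()]); zero at or past retirement.
#'
#' @param records cohort data.frame.
#' @param wages a [wage_config()].
#' @return data.frame with `id` and annual `indirect_absenteeism`,
#'   `indirect_presenteeism`, `indirect_unpaid_work`, `indirect_job_change`,
#'   `indirect_premature_death` (Toman/year).
#' @export
human_capital_indirect <- function(records, wages) {
  validate_patient_records(records)
  stopifnot(inherits(wages, "wage_config"))
  n <- nrow(records)
  employed <- records$employment_status == "employed"
  daily_wage <- wages$monthly_wage / wages$working_days_per_month
  absenteeism <- ifelse(employed,
                        records$absenteeism_days * daily_wage * 12, 0)
  presenteeism <- ifelse(
    employed,
    records$presenteeism_days * (1 - records$presenteeism_efficiency) *
      daily_wage * 12, 0)
  unpaid <- records$unpaid_work_hours_lost * wages$unpaid_hourly_value * 12
  job_change <- ifelse(records$changed_job,
                       wages$job_change_monthly_loss * 12, 0)
  dead <- records$died_in_year
  if (any(dead & is.na(records$age_at_death))) {
    stop_data("'age_at_death' missing for a deceased record")
  }
  years_lost <- pmax(0, wages$retirement_age - records$age_at_death)
  premature <- numeric(n)
  if (any(dead)) {
    premature[dead] <- present_value_annuity(
      wages$monthly_wage * 12, years_lost[dead],
      wages$productivity_discount_rate)
  }
  data.frame(
    id = records$id,
    indirect_absenteeism = absenteeism,
    indirect_presenteeism = presenteeism,
    indirect_unpaid_work = unpaid,
    indirect_job_change = job_change,
    indirect_premature_death = premature
  )
}

#' Per-patient annual cost table
#'
#' Joins the annualised direct components and the human-capital indirect
#' components and adds the exact subtotal columns `direct_total`,
#' `indirect_total` and `grand_total`.
#'
#' @inheritParams human_capital_indirect
#' @return data.frame, one row per patient, of class `annual_patient_costs`.
#' @export
annual_patient_costs <- function(records, wages = wage_config()) {
  d <- annualize_direct(records)
  i <- human_capital_indirect(records, wages)
  stopifnot(identical(d$id, i$id))
  out <- cbind(d, i[, -1, drop = FALSE])
  out$direct_total <- out$direct_medicine + out$direct_treatment +
    out$direct_diagnostic + out$direct_non_medical
  out$indirect_total <- out$indirect_absenteeism + out$indirect_presenteeism +
    out$indirect_unpaid_work + out$indirect_job_change +
    out$indirect_premature_death
  out$grand_total <- out$direct_total + out$indirect_total
  class(out) <- c("annual_patient_costs", "data.frame")
  out
}

direct_cols <- function() {
  c("direct_medicine", "direct_treatment", "direct_diagnostic",
    "direct_non_medical")
}

indirect_cols <- function() {
  c("indirect_absenteeism", "indirect_presenteeism", "indirect_unpaid_work",
    "indirect_job_change", "indirect_premature_death")
}

#' Cohort-level annual cost breakdown
#'
#' Aggregates per-patient annual costs into the published table shape:
#' per-component means and sample SDs (n-1 denominator), direct / indirect /
#' grand totals of means (computed before any rounding), percentage shares
#' (direct vs indirect of the grand total; medicine / treatment / diagnostic
#' of direct medical; per-NYHA-class means and their shares of the class-mean
#' sum). Shares are reported raw and rounded half-up to integers.
#'
#' @param costs an [annual_patient_costs()] table.
#' @param classes integer vector of NYHA classes (1-4), one per patient.
#' @return an object of class `annual_cost_breakdown`: list with
#'   `component_stats` (mean/sd per component), `totals`, `shares`
#'   (`direct_indirect`, `direct_medical`, `by_class`, each with raw and
#'   rounded columns), `class_stats`, `n`, and `degenerate_sd` flag (TRUE for
#'   a single-patient cohort, whose SDs are reported as 0).
#' @export
aggregate_breakdown <- function(costs, classes) {
  if (!inherits(costs, "annual_patient_costs")) {
    stop_data("'costs' must come from annual_patient_costs()")
  }
  n <- nrow(costs)
  if (n == 0L) stop_data("cannot aggregate an empty cohort")
  if (length(classes) != n) stop_data("'classes' must have one entry per patient")
  if (!all(classes %in% 1:4)) stop_data("NYHA class labels must lie in 1..4")

  degenerate <- n == 1L
  if (degenerate) {
    warning("single-patient cohort: SDs reported as 0 (degenerate sample)")
  }
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  comp <- c(direct_cols(), indirect_cols(), "direct_total", "indirect_total",
            "grand_total")
  component_stats <- data.frame(
    component = comp,
    mean = vapply(comp, function(cc) mean(costs[[cc]]), 0),
    sd = vapply(comp, function(cc) sd0(costs[[cc]]), 0),
    row.names = NULL
  )
  m <- function(cc) component_stats$mean[component_stats$component == cc]
  direct_mean <- m("direct_total")
  indirect_mean <- m("indirect_total")
  grand_mean <- m("grand_total")

  share_tab <- function(values, labels) percentage_shares(values, labels)
  medical <- vapply(c("direct_medicine", "direct_treatment",
                      "direct_diagnostic"), m, 0)
  class_means <- vapply(1:4, function(k) {
    if (any(classes == k)) mean(costs$grand_total[classes == k]) else NA_real_
  }, 0)
  class_sds <- vapply(1:4, function(k) {
    if (any(classes == k)) sd0(costs$grand_total[classes == k]) else NA_real_
  }, 0)
  present <- !is.na(class_means)

  structure(
    list(
      component_stats = component_stats,
      totals = c(direct = direct_mean, indirect = indirect_mean,
                 grand = grand_mean),
      shares = list(
        direct_indirect = share_tab(c(direct_mean, indirect_mean),
                                    c("direct", "indirect")),
        direct_medical = share_tab(medical,
                                   c("medicine", "treatment", "diagnostic")),
        by_class = share_tab(class_means[present],
                             paste0("class_", (1:4)[present]))
      ),
      class_stats = data.frame(nyha_class = 1:4, mean = class_means,
                               sd = class_sds,
                               n = vapply(1:4, function(k) sum(classes == k), 0L)),
      n = n,
      degenerate_sd = degenerate
    ),
    class = "annual_cost_breakdown"
  )
}

#' @export
print.annual_cost_breakdown <- function(x, ...) {
  cat("<annual_cost_breakdown>", x$n, "patients\n")
  cat(sprintf("  grand total mean: %s Toman/year\n",
              fmt_toman(x$totals[["grand"]])))
  di <- x$shares$direct_indirect
  cat(sprintf("  direct %s (%d%%) + indirect %s (%d%%)\n",
              fmt_toman(x$totals[["direct"]]), di$share_rounded[1],
              fmt_toman(x$totals[["indirect"]]), di$share_rounded[2]))
  invisible(x)
}

#' Percentage shares of a total
#'
#' Shares of each value in the sum of all values, reported raw and rounded
#' half-up to integers (the convention used in the published tables).
#'
#' @param values non-negative numeric vector with a positive sum.
#' @param labels component labels (default `names(values)`).
#' @return data.frame with `component`, `share_raw`, `share_rounded`.
#' @export
#' @examples
#' percentage_shares(c(direct = 54262049.09, indirect = 207147805.8))
percentage_shares <- function(values, labels = names(values)) {
  if (any(values < 0)) stop_data("shares require non-negative values")
  total <- sum(values)
  if (!is.finite(total) || total <= 0) {
    stop_data("shares are undefined for a non-positive total")
  }
  if (is.null(labels)) labels <- paste0("component_", seq_along(values))
  raw <- 100 * values / total
  data.frame(component = labels, share_raw = unname(raw),
             share_rounded = unname(round_half_up(raw)), row.names = NULL)
}

#' Convert Toman amounts to PPP dollars
#'
#' @param amount Toman amounts.
#' @param toman_per_ppp Toman per international (purchasing-power-parity)
#'   dollar; default from [hf_reference_ppp_factor()].
#' @return PPP dollars, rounded to 2 decimals.
#' @export
#' @examples
#' convert_to_ppp(261409854.9)  # ~21,967 PPP dollars
convert_to_ppp <- function(amount, toman_per_ppp = hf_reference_ppp_factor()) {
  if (!is_pos_num(toman_per_ppp)) {
    stop_config("'toman_per_ppp' must be a positive number")
  }
  round(amount / toman_per_ppp, 2)
}

#' Breakdown computed from the published reference components
#'
#' Runs the aggregation arithmetic (component sums, direct/indirect split,
#' shares) on the published per-component annual means treated as a frozen
#' one-patient input, reproducing the source's printed totals and share
#' percentages without any data generation.
#'
#' @return an `annual_cost_breakdown` (with `degenerate_sd = TRUE`).
#' @export
reference_breakdown <- function() {
  ref <- hf_reference_costs()
  g <- function(cc) ref$mean[ref$component == cc]
  costs <- data.frame(
    id = 1L,
    direct_medicine = g("medicine"),
    direct_treatment = g("treatment"),
    direct_diagnostic = g("diagnostic"),
    direct_non_medical = g("non_medical_direct"),
    indirect_absenteeism = g("absenteeism"),
    indirect_presenteeism = g("presenteeism"),
    indirect_unpaid_work = g("unpaid_work"),
    indirect_job_change = g("job_change"),
    indirect_premature_death = g("premature_death")
  )
  costs$direct_total <- sum(costs[, direct_cols()])
  costs$indirect_total <- sum(costs[, indirect_cols()])
  costs$grand_total <- costs$direct_total + costs$indirect_total
  class(costs) <- c("annual_patient_costs", "data.frame")
  suppressWarnings(aggregate_breakdown(costs, classes = 1L))
}
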