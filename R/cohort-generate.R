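#' Generate a synthetic heart-failure cohort
#'
#' Draws `n_patients` patient records from the marginal distributions in the
#' config. Covariates are sampled independently (no correlation structure
#' unless `class_cost_multipliers` links class to direct-cost means). The same
#' config, including its seed, reproduces the cohort bit-for-bit; the caller's
#' RNG state is left untouched.
#'
#' @param config a validated [cohort_config()].
#' @return a data.frame of patient records, one row per patient, with the
#'   columns documented in [validate_patient_records()].
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(n_patients = 50, seed = 7))
#' table(cohort$nyha_class)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_patients)
  if (n == 0L) {
    return(empty_cohort())
  }
  with_seed(config$seed, {
    nyha <- sample.int(4L, n, replace = TRUE, prob = config$class_probs)
    age <- rtruncnorm(n, config$age_mean, config$age_sd,
                      config$age_min, config$age_max)
    gender <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    employment <- sample(names(config$employment_probs), n, replace = TRUE,
                         prob = config$employment_probs)
    follow_up <- sample(config$follow_up_choices, n, replace = TRUE,
                        prob = config$follow_up_probs)
    mult <- config$class_cost_multipliers[nyha]
    draw <- function(spec) sample_cost_component(spec, n)
    hospitalized <- stats::runif(n) < config$p_hospitalized_year
    admission <- draw(config$admission_cost) * hospitalized
    died <- stats::runif(n) < config$p_death_in_year
    eff <- stats::runif(n, config$presenteeism_efficiency_range[1],
                        config$presenteeism_efficiency_range[2])
    rec <- data.frame(
      id = seq_len(n),
      age = age,
      gender = gender,
      nyha_class = nyha,
      basic_insurance = stats::runif(n) < config$p_basic_insurance,
      complementary_insurance = stats::runif(n) < config$p_complementary,
      comorbidity = stats::runif(n) < config$p_comorbidity,
      household_head = stats::runif(n) < config$p_household_head,
      employment_status = employment,
      follow_up_months = as.integer(follow_up),
      monthly_medicine = draw(config$components$medicine) * mult,
      monthly_treatment_nonhospital =
        draw(config$components$treatment_nonhospital) * mult,
      monthly_diagnostic = draw(config$components$diagnostic) * mult,
      monthly_non_medical = draw(config$components$non_medical_direct) * mult,
      hospitalized_last_year = hospitalized,
      admission_cost = admission,
      absenteeism_days = draw(config$absenteeism_days),
      presenteeism_days = draw(config$presenteeism_days),
      presenteeism_efficiency = eff,
      unpaid_work_hours_lost = draw(config$unpaid_hours),
      changed_job = stats::runif(n) < config$p_changed_job,
      died_in_year = died,
      age_at_death = ifelse(died, age, NA_real_),
      stringsAsFactors = FALSE
    )
    # zero-cost patients: no care contact and no productivity loss at all —
    # the zero part of the semicontinuous outcome the two-part model targets
    zero_all <- stats::runif(n) < config$p_zero_cost_patient
    if (any(zero_all)) {
      zero_cols <- c("monthly_medicine", "monthly_treatment_nonhospital",
                     "monthly_diagnostic", "monthly_non_medical",
                     "admission_cost", "absenteeism_days", "presenteeism_days",
                     "unpaid_work_hours_lost")
      rec[zero_all, zero_cols] <- 0
      rec$hospitalized_last_year[zero_all] <- FALSE
      rec$changed_job[zero_all] <- FALSE
      rec$died_in_year[zero_all] <- FALSE
      rec$age_at_death[zero_all] <- NA_real_
    }
    validate_patient_records(rec)
  })
}

empty_cohort <- function() {
  validate_patient_records(data.frame(
    id = integer(0), age = numeric(0), gender = character(0),
    nyha_class = integer(0), basic_insurance = logical(0),
    complementary_insurance = logical(0), comorbidity = logical(0),
    household_head = logical(0), employment_status = character(0),
    follow_up_months = integer(0), monthly_medicine = numeric(0),
    monthly_treatment_nonhospital = numeric(0), monthly_diagnostic = numeric(0),
    monthly_non_medical = numeric(0), hospitalized_last_year = logical(0),
    admission_cost = numeric(0), absenteeism_days = numeric(0),
    presenteeism_days = numeric(0), presenteeism_efficiency = numeric(0),
    unpaid_work_hours_lost = numeric(0), changed_job = logical(0),
    died_in_year = logical(0), age_at_death = numeric(0),
    stringsAsFactors = FALSE
  ))
}

# normal truncated to [lo, hi] by rejection; fine for the mild truncation used
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

cohort_columns <- function() {
  c(id = "integer", age = "numeric", gender = "character",
    nyha_class = "integer", basic_insurance = "logical",
    complementary_insurance = "logical", comorbidity = "logical",
    household_head = "logical", employment_status = "character",
    follow_up_months = "integer", monthly_medicine = "numeric",
    monthly_treatment_nonhospital = "numeric", monthly_diagnostic = "numeric",
    monthly_non_medical = "numeric", hospitalized_last_year = "logical",
    admission_cost = "numeric", absenteeism_days = "numeric",
    presenteeism_days = "numeric", presenteeism_efficiency = "numeric",
    unpaid_work_hours_lost = "numeric", changed_job = "logical",
    died_in_year = "logical", age_at_death = "numeric")
}

#' Validate patient records
#'
#' Checks the cohort data.frame contract: one row per patient with columns
#' `id`, `age`, `gender` (male/female), `nyha_class` (1-4),
#' `basic_insurance`, `complementary_insurance`, `comorbidity`,
#' `household_head`, `employment_status`
#' (employed/housewife/retired/unemployed), `follow_up_months` (2/4/6),
#' monthly direct costs (`monthly_medicine`, `monthly_treatment_nonhospital`,
#' `monthly_diagnostic`, `monthly_non_medical`, Toman/month),
#' `hospitalized_last_year`, `admission_cost` (Toman/year),
#' `absenteeism_days`, `presenteeism_days` (days/month),
#' `presenteeism_efficiency` (fraction), `unpaid_work_hours_lost`
#' (hours/month), `changed_job`, `died_in_year`, `age_at_death` (years; NA
#' iff alive). All cost fields must be non-negative.
#'
#' @param records a data.frame.
#' @return the records (invisibly valid) or a data error.
#' @export
validate_patient_records <- function(records) {
  if (!is.data.frame(records)) stop_data("cohort must be a data.frame")
  miss <- setdiff(names(cohort_columns()), names(records))
  if (length(miss)) {
    stop_data("cohort is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0L) return(records)
  if (!all(records$gender %in% c("male", "female"))) {
    stop_data("'gender' must be male or female")
  }
  if (!all(records$nyha_class %in% 1:4)) stop_data("'nyha_class' must be in 1..4")
  if (!all(records$employment_status %in%
           c("employed", "housewife", "retired", "unemployed"))) {
    stop_data("unknown 'employment_status' value")
  }
  if (!all(records$follow_up_months %in% c(2L, 4L, 6L))) {
    stop_data("'follow_up_months' must be 2, 4 or 6")
  }
  cost_cols <- c("monthly_medicine", "monthly_treatment_nonhospital",
                 "monthly_diagnostic", "monthly_non_medical", "admission_cost",
                 "absenteeism_days", "presenteeism_days",
                 "unpaid_work_hours_lost")
  for (cc in cost_cols) {
    if (any(is.na(records[[cc]])) || any(records[[cc]] < 0)) {
      stop_data("'", cc, "' must be non-negative and non-missing")
    }
  }
  if (any(records$presenteeism_efficiency < 0 |
          records$presenteeism_efficiency > 1)) {
    stop_data("'presenteeism_efficiency' must lie in [0, 1]")
  }
  if (!identical(is.na(records$age_at_death), !records$died_in_year)) {
    stop_data("'age_at_death' must be present exactly for deceased records")
  }
  records
}

#' Write / read a cohort as CSV
#'
#' Plain-CSV serialisation of the cohort with a fixed documented header.
#' Numeric fields are written with 17 significant digits so the round-trip is
#' exact for every field.
#'
#' @param records cohort data.frame ([validate_patient_records()] contract).
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the validated cohort.
#' @export
write_cohort_csv <- function(records, path) {
  validate_patient_records(records)
  out <- records[, names(cohort_columns()), drop = FALSE]
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- "NA"
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_data("cohort file not found: ", path)
  cols <- cohort_columns()
  rec <- utils::read.csv(path, colClasses = unname(cols), check.names = TRUE)
  miss <- setdiff(names(cols), names(rec))
  if (length(miss)) {
    stop_data("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  validate_patient_records(rec[, names(cols), drop = FALSE])
}
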