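#' Synthetic-cohort configuration
#'
#' Bundles every distributional parameter the cohort generator uses: sample
#' size, NYHA class mix, demographic marginals, follow-up scheme, per-component
#' monthly cost specs, indirect-cost drivers, and wage parameters. Defaults
#' (see [default_cohort_config()]) emulate a published 502-patient Iranian
#' heart-failure sample.
#'
#' @param n_patients number of patients to generate (>= 0).
#' @param class_probs probability 4-vector over NYHA classes I-IV; must sum
#'   to 1 within 1e-9.
#' @param p_male,p_basic_insurance,p_complementary,p_comorbidity,p_household_head
#'   marginal probabilities for the binary covariates.
#' @param age_mean,age_sd,age_min,age_max age distribution (normal truncated
#'   to `[age_min, age_max]`), in years.
#' @param follow_up_choices integer months of follow-up offered (default 2/4/6).
#' @param follow_up_probs probabilities over `follow_up_choices`.
#' @param p_hospitalized_year probability of at least one HF admission in the
#'   last year.
#' @param p_death_in_year probability of death within the costing year.
#' @param p_zero_cost_patient probability that a patient incurs no cost at
#'   all during follow-up (no care contact, no productivity loss, alive).
#'   This is the zero part the two-part regression models; published counts
#'   are consistent with roughly 7% of patients having zero annual cost.
#' @param p_changed_job probability of a disease-driven job change.
#' @param employment_probs named probabilities over
#'   employed/housewife/retired/unemployed.
#' @param components named list of monthly direct-cost component specs
#'   ([cost_component_spec()]); names must be `medicine`,
#'   `treatment_nonhospital`, `diagnostic`, `non_medical_direct`.
#' @param admission_cost spec for the cost of one year's admissions, given
#'   hospitalisation (Toman).
#' @param absenteeism_days,presenteeism_days specs for work days lost / worked
#'   at reduced productivity per month.
#' @param unpaid_hours spec for unpaid-work hours lost per month.
#' @param presenteeism_efficiency_range length-2 vector; residual on-the-job
#'   efficiency is drawn uniformly from it.
#' @param class_cost_multipliers optional multiplier per NYHA class applied to
#'   the direct-cost component means (default all 1: components independent of
#'   class).
#' @param monthly_wage gross monthly market wage (Toman).
#' @param unpaid_hourly_value replacement (shadow) wage for unpaid work
#'   (Toman/hour).
#' @param retirement_age years.
#' @param seed integer RNG seed; same config (incl. seed) reproduces the
#'   cohort bit-for-bit.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          class_probs,
                          p_male,
                          p_basic_insurance,
                          p_complementary,
                          p_comorbidity,
                          p_household_head,
                          age_mean, age_sd, age_min, age_max,
                          follow_up_choices = c(2L, 4L, 6L),
                          follow_up_probs = rep(1 / 3, 3),
                          p_hospitalized_year,
                          p_death_in_year,
                          p_zero_cost_patient = 0,
                          p_changed_job = 0.02,
                          employment_probs = c(employed = 0.35, housewife = 0.40,
                                               retired = 0.25, unemployed = 0),
                          components,
                          admission_cost,
                          absenteeism_days,
                          presenteeism_days,
                          unpaid_hours,
                          presenteeism_efficiency_range = c(0.5, 0.9),
                          class_cost_multipliers = rep(1, 4),
                          monthly_wage,
                          unpaid_hourly_value,
                          retirement_age = 65,
                          seed = 1L) {
  cfg <- structure(
    list(n_patients = n_patients, class_probs = class_probs, p_male = p_male,
         p_basic_insurance = p_basic_insurance, p_complementary = p_complementary,
         p_comorbidity = p_comorbidity, p_household_head = p_household_head,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         age_max = age_max, follow_up_choices = as.integer(follow_up_choices),
         follow_up_probs = follow_up_probs,
         p_hospitalized_year = p_hospitalized_year,
         p_death_in_year = p_death_in_year,
         p_zero_cost_patient = p_zero_cost_patient,
         p_changed_job = p_changed_job,
         employment_probs = employment_probs, components = components,
         admission_cost = admission_cost, absenteeism_days = absenteeism_days,
         presenteeism_days = presenteeism_days, unpaid_hours = unpaid_hours,
         presenteeism_efficiency_range = presenteeism_efficiency_range,
         class_cost_multipliers = class_cost_multipliers,
         monthly_wage = monthly_wage, unpaid_hourly_value = unpaid_hourly_value,
         retirement_age = retirement_age, seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

direct_component_names <- function() {
  c("medicine", "treatment_nonhospital", "diagnostic", "non_medical_direct")
}

#' Validate a cohort configuration
#'
#' Checks every invariant and raises a configuration error naming the first
#' offending field.
#'
#' @param cfg a `cohort_config`.
#' @return the config, invisibly usable, if valid.
#' @export
validate_cohort_config <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stop_config("not a cohort_config object")
  if (!is_count(cfg$n_patients)) stop_config("'n_patients' must be a count >= 0")
  if (length(cfg$class_probs) != 4L || any(!vapply(cfg$class_probs, is_prob, TRUE))) {
    stop_config("'class_probs' must be four probabilities in [0, 1]")
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-9) {
    stop_config("'class_probs' must sum to 1 (got ",
                format(sum(cfg$class_probs), digits = 12), ")")
  }
  for (f in c("p_male", "p_basic_insurance", "p_complementary", "p_comorbidity",
              "p_household_head", "p_hospitalized_year", "p_death_in_year",
              "p_zero_cost_patient", "p_changed_job")) {
    if (!is_prob(cfg[[f]])) stop_config("'", f, "' must be a probability in [0, 1]")
  }
  if (!is_pos_num(cfg$age_sd)) stop_config("'age_sd' must be positive")
  if (!(cfg$age_min <= cfg$age_mean && cfg$age_mean <= cfg$age_max)) {
    stop_config("ages must satisfy age_min <= age_mean <= age_max")
  }
  if (length(cfg$follow_up_choices) != length(cfg$follow_up_probs)) {
    stop_config("'follow_up_probs' must match 'follow_up_choices' in length")
  }
  if (any(!vapply(cfg$follow_up_probs, is_prob, TRUE)) ||
      abs(sum(cfg$follow_up_probs) - 1) > 1e-9) {
    stop_config("'follow_up_probs' must be probabilities summing to 1")
  }
  ep <- cfg$employment_probs
  need <- c("employed", "housewife", "retired", "unemployed")
  if (!all(need %in% names(ep)) || abs(sum(ep) - 1) > 1e-9 ||
      any(!vapply(ep, is_prob, TRUE))) {
    stop_config("'employment_probs' must be probabilities over ",
                paste(need, collapse = "/"), " summing to 1")
  }
  miss <- setdiff(direct_component_names(), names(cfg$components))
  if (length(miss)) {
    stop_config("'components' is missing specs for: ", paste(miss, collapse = ", "))
  }
  for (nm in names(cfg$components)) {
    if (!inherits(cfg$components[[nm]], "cost_component_spec")) {
      stop_config("components$", nm, " is not a cost_component_spec")
    }
  }
  for (nm in c("admission_cost", "absenteeism_days", "presenteeism_days",
               "unpaid_hours")) {
    if (!inherits(cfg[[nm]], "cost_component_spec")) {
      stop_config("'", nm, "' must be a cost_component_spec")
    }
  }
  er <- cfg$presenteeism_efficiency_range
  if (length(er) != 2L || !all(vapply(er, is_prob, TRUE)) || er[1] > er[2]) {
    stop_config("'presenteeism_efficiency_range' must be an ordered pair in [0, 1]")
  }
  if (length(cfg$class_cost_multipliers) != 4L ||
      any(cfg$class_cost_multipliers <= 0)) {
    stop_config("'class_cost_multipliers' must be four positive numbers")
  }
  for (f in c("monthly_wage", "unpaid_hourly_value")) {
    if (!is_nonneg_num(cfg[[f]])) stop_config("'", f, "' must be >= 0")
  }
  if (!is_pos_num(cfg$retirement_age)) stop_config("'retirement_age' must be positive")
  if (!is_count(abs(cfg$seed))) stop_config("'seed' must be an integer")
  cfg
}

#' Default cohort configuration
#'
#' Marginals follow the published 502-patient sample: NYHA class mix
#' 106/189/88/119, 61.1% male, 91.2% basic insurance, 42.4% complementary,
#' 61% comorbidity, 72% household heads, age 63.46 (SD 14.27) truncated to
#' the observed 8-95 range, follow-up 2/4/6 months equiprobable, 60%
#' hospitalised in the past year. Direct-cost components are calibrated by
#' moment inversion so their annualised marginal mean/SD match the published
#' cost table; the admission-cost mean is set so hospitalisation contributes
#' about 20% of direct medical cost. Zero-cost prevalences per component are
#' assumptions (not published) and are exposed here for configuration.
#'
#' @param n_patients cohort size (default 502).
#' @param seed RNG seed.
#' @return a validated [cohort_config()].
#' @export
default_cohort_config <- function(n_patients = 502L, seed = 1L) {
  ref <- hf_reference_costs()
  annual <- function(component) {
    ref[ref$component == component, c("mean", "sd")]
  }
  # monthly spec whose x12 annualisation matches the published annual moments
  monthly_spec <- function(component, zero_prob) {
    a <- annual(component)
    calibrate_component_to_marginal(a$mean / 12, a$sd / 12, zero_prob = zero_prob)
  }
  p_hosp <- 0.60
  # hospitalisation ~20% of direct medical cost, spread over the 60% admitted
  medical_sum <- sum(ref$mean[ref$component %in% c("medicine", "treatment", "diagnostic")])
  admission_mean <- 0.20 * medical_sum / p_hosp
  treat <- annual("treatment")
  nonhosp_mean <- (treat$mean - p_hosp * admission_mean) / 12
  nonhosp_sd <- treat$sd * (nonhosp_mean * 12 / treat$mean) / 12

  cohort_config(
    n_patients = n_patients,
    class_probs = c(106, 189, 88, 119) / 502,
    p_male = 0.611,
    p_basic_insurance = 0.912,
    p_complementary = 0.424,
    p_comorbidity = 0.61,
    p_household_head = 0.72,
    age_mean = 63.46, age_sd = 14.27, age_min = 8, age_max = 95,
    follow_up_choices = c(2L, 4L, 6L),
    follow_up_probs = rep(1 / 3, 3),
    p_hospitalized_year = p_hosp,
    p_death_in_year = 0.10,
    p_zero_cost_patient = 0.07,
    p_changed_job = 0.02,
    components = list(
      medicine = monthly_spec("medicine", zero_prob = 0.05),
      treatment_nonhospital = calibrate_component_to_marginal(
        nonhosp_mean, nonhosp_sd, zero_prob = 0.15),
      diagnostic = monthly_spec("diagnostic", zero_prob = 0.30),
      non_medical_direct = monthly_spec("non_medical_direct", zero_prob = 0.20)
    ),
    admission_cost = cost_component_spec(admission_mean, positive_cv = 1.2),
    absenteeism_days = cost_component_spec(7.6, positive_cv = 1.0, zero_prob = 0.35),
    presenteeism_days = cost_component_spec(1.85, positive_cv = 1.0, zero_prob = 0.70),
    unpaid_hours = cost_component_spec(330, positive_cv = 1.2, zero_prob = 0.15),
    monthly_wage = 10e6,
    unpaid_hourly_value = 50e3,
    retirement_age = 65,
    seed = seed
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_patients, "patients, seed", x$seed, "\n")
  cat(sprintf("  NYHA class probs: %s\n",
              paste(sprintf("%.3f", x$class_probs), collapse = " ")))
  cat(sprintf("  age %0.2f (SD %0.2f) in [%g, %g]; male %.1f%%; basic ins. %.1f%%\n",
              x$age_mean, x$age_sd, x$age_min, x$age_max,
              100 * x$p_male, 100 * x$p_basic_insurance))
  cat("  components:", paste(names(x$components), collapse = ", "), "\n")
  invisible(x)
}

# ---- config serialisation (YAML / JSON) ------------------------------------

spec_to_list <- function(sp) {
  list(positive_mean = sp$positive_mean, positive_cv = sp$positive_cv,
       zero_prob = sp$zero_prob, family = sp$family)
}

spec_from_list <- function(l, field) {
  need <- c("positive_mean", "positive_cv", "zero_prob", "family")
  miss <- setdiff(need, names(l))
  if (length(miss)) {
    stop_config("component spec '", field, "' is missing fields: ",
                paste(miss, collapse = ", "))
  }
  cost_component_spec(l$positive_mean, l$positive_cv, l$zero_prob, l$family)
}

#' Write / read a cohort configuration
#'
#' Serialises the full configuration to YAML (`.yaml`/`.yml`) or JSON
#' (`.json`), chosen by file extension, and reads it back with schema
#' validation. Round-trips exactly.
#'
#' @param cfg a [cohort_config()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(cfg, path) {
  validate_cohort_config(cfg)
  x <- unclass(cfg)
  for (nm in names(x$components)) x$components[[nm]] <- spec_to_list(x$components[[nm]])
  for (nm in c("admission_cost", "absenteeism_days", "presenteeism_days",
               "unpaid_hours")) {
    x[[nm]] <- spec_to_list(x[[nm]])
  }
  x$employment_probs <- as.list(x$employment_probs)
  write_config_file(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- read_config_file(path)
  need <- c("n_patients", "class_probs", "components", "monthly_wage",
            "unpaid_hourly_value")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_config("cohort config file is missing fields: ",
                paste(miss, collapse = ", "))
  }
  for (nm in names(x$components)) {
    x$components[[nm]] <- spec_from_list(x$components[[nm]],
                                         paste0("components$", nm))
  }
  for (nm in c("admission_cost", "absenteeism_days", "presenteeism_days",
               "unpaid_hours")) {
    x[[nm]] <- spec_from_list(x[[nm]], nm)
  }
  x$class_probs <- as.numeric(x$class_probs)
  x$follow_up_probs <- as.numeric(x$follow_up_probs)
  x$employment_probs <- unlist(x$employment_probs)
  x$presenteeism_efficiency_range <- as.numeric(x$presenteeism_efficiency_range)
  x$class_cost_multipliers <- as.numeric(x$class_cost_multipliers)
  do.call(cohort_config, x)
}

write_config_file <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop_config("config file must end in .yaml, .yml or .json: ", path)
  }
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_config("config file must end in .yaml, .yml or .json: ", path)
  }
}
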