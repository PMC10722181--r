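#' Published reference cost table (annual, per patient)
#'
#' Annual per-patient cost components (mean and SD, Toman) from a published
#' prevalence-based cost-of-illness study of 502 Iranian heart-failure
#' patients (NYHA I-IV, societal perspective, human-capital indirect costs).
#' These figures serve two purposes: they are the calibration targets for
#' [default_cohort_config()], and they are a frozen input set on which the
#' package's aggregation arithmetic can be exercised without generating data
#' (see [reference_breakdown()]).
#'
#' Note: the source table also prints a direct-medical subtotal
#' (52,260,051.17) that differs from the sum of its three printed components
#' (52,217,441.611) by about 42,610 Toman, an internal rounding inconsistency
#' of the source. This package always reports component sums.
#'
#' @return a data.frame with columns `component`, `category`
#'   (`direct_medical`, `direct_non_medical`, `indirect`, `class`, `total`),
#'   `mean`, `sd`.
#' @export
hf_reference_costs <- function() {
  data.frame(
    component = c("medicine", "treatment", "diagnostic", "non_medical_direct",
                  "premature_death", "absenteeism", "presenteeism",
                  "job_change", "unpaid_work",
                  "class_1", "class_2", "class_3", "class_4",
                  "direct_total", "indirect_total", "grand_total"),
    category = c(rep("direct_medical", 3), "direct_non_medical",
                 rep("indirect", 5), rep("class", 4), rep("total", 3)),
    mean = c(5053339.627, 44979659.96, 2184442.024, 2001997.923,
             29403824.7, 9390793.338, 316600.2596, 0, 168036587.5,
             284221375.3, 184586207.1, 302719797.7, 332555849,
             54262049.09, 207147805.8, 261409854.9),
    sd = c(31551902.47, 100769273.6, 6206215.425, 5283430.999,
           158145195.4, 28323561.66, 2292269.639, 0, 315918806,
           484971996.5, 309046776.5, 345431304.9, 331530122.6,
           NA, NA, 369357786.7),
    stringsAsFactors = FALSE
  )
}

#' Published reference lifetime costs by Markov state
#'
#' Per-state lifetime cost attribution (Toman) reported by the same study's
#' incidence-based six-state Markov analysis, plus its printed total. The
#' five states are NYHA I-IV and death from heart failure (death from other
#' causes accrues no cost).
#'
#' @return list with `per_state` (named 5-vector) and `printed_total`.
#' @export
hf_reference_lifetime <- function() {
  list(
    per_state = c(NYHA1 = 471146883, NYHA2 = 88460400, NYHA3 = 51001097,
                  NYHA4 = 517348089, DeathHF = 1046004708),
    printed_total = 2173961178
  )
}

#' Reference Toman-per-PPP-dollar conversion factor
#'
#' The study prints three Toman/PPP-dollar pairs (total, indirect, direct
#' annual cost). Their ratios agree to within about 1e-6 relative and imply a
#' conversion factor of 11,900 Toman per international dollar, shipped here
#' as the default for [convert_to_ppp()].
#'
#' @return implied factor (Toman per PPP dollar).
#' @export
hf_reference_ppp_factor <- function() {
  11900
}
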