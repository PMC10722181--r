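#' End-to-end run configuration
#'
#' Bundles the stage configurations for [run_pipeline()]: the cohort
#' generator config, wage parameters, the PPP conversion factor, the Markov
#' specification, regression options, and an output directory.
#'
#' @param output_dir directory for all artifacts (created if absent).
#' @param cohort a [cohort_config()].
#' @param wages a [wage_config()].
#' @param toman_per_ppp PPP conversion factor.
#' @param markov a [markov_spec()].
#' @param covariates,gender_coding,family,link regression options, passed to
#'   [fit_two_part()].
#' @param cohort_path optional path to an existing cohort CSV, used when the
#'   `generate` stage is not run.
#' @param verbose emit stage-tagged progress messages to stderr.
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       cohort = default_cohort_config(),
                       wages = wage_config(),
                       toman_per_ppp = hf_reference_ppp_factor(),
                       markov = default_markov_spec(wages),
                       covariates = default_covariates(),
                       gender_coding = "female1",
                       family = "gamma", link = "log",
                       cohort_path = NULL,
                       verbose = FALSE) {
  validate_cohort_config(cohort)
  validate_markov_spec(markov)
  stopifnot(inherits(wages, "wage_config"))
  if (!is_pos_num(toman_per_ppp)) stop_config("'toman_per_ppp' must be positive")
  structure(
    list(output_dir = output_dir, cohort = cohort, wages = wages,
         toman_per_ppp = toman_per_ppp, markov = markov,
         covariates = covariates, gender_coding = gender_coding,
         family = family, link = link, cohort_path = cohort_path,
         verbose = verbose),
    class = "run_config"
  )
}

pipeline_stages <- function() c("generate", "prevalence", "markov", "regress")

log_stage <- function(config, stage, ...) {
  if (isTRUE(config$verbose)) message("[", stage, "] ", ...)
}

#' Run the cost-of-illness pipeline
#'
#' Executes the requested stages in dependency order (`generate` ->
#' `prevalence` -> `regress`, with `markov` independent of the cohort),
#' writes every artifact as CSV plus a combined markdown report, and returns
#' a manifest listing each written file with its MD5 hash. Runs are
#' deterministic: the same config (including its seed) reproduces
#' byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @param stages subset of `generate`, `prevalence`, `markov`, `regress`.
#' @return object of class `pipeline_result`: list with `manifest`
#'   (data.frame stage/file/md5), `status` (0 for success), and the stage
#'   results (`cohort`, `costs`, `breakdown`, `markov_result`, `fit`) that
#'   were produced.
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) stop_config("unknown stages: ", paste(bad, collapse = ", "))
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  record <- function(stage, path) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
  }
  out <- list(manifest = NULL, status = 0L)
  cohort <- NULL

  if ("generate" %in% stages) {
    log_stage(config, "generate", "cohort of ", config$cohort$n_patients,
              " patients (seed ", config$cohort$seed, ")")
    cohort <- generate_cohort(config$cohort)
    path <- file.path(config$output_dir, "cohort.csv")
    write_cohort_csv(cohort, path)
    record("generate", path)
    out$cohort <- cohort
  }

  need_cohort <- function(stage) {
    if (!is.null(cohort)) return(cohort)
    path <- config$cohort_path %||% file.path(config$output_dir, "cohort.csv")
    if (!file.exists(path)) {
      stop_data("stage '", stage, "' needs a cohort; run the 'generate' ",
                "stage first or set cohort_path")
    }
    cohort <<- read_cohort_csv(path)
    cohort
  }

  costs <- NULL
  breakdown <- NULL
  if ("prevalence" %in% stages) {
    rec <- need_cohort("prevalence")
    if (nrow(rec) == 0L) stop_data("prevalence stage needs a non-empty cohort")
    log_stage(config, "prevalence", "annualising ", nrow(rec), " patients")
    costs <- annual_patient_costs(rec, config$wages)
    breakdown <- aggregate_breakdown(costs, rec$nyha_class)
    path <- file.path(config$output_dir, "annual_costs.csv")
    utils::write.csv(format_numeric_df(as.data.frame(costs)), path,
                     row.names = FALSE)
    record("prevalence", path)
    path <- file.path(config$output_dir, "breakdown_components.csv")
    stats_tab <- breakdown$component_stats
    stats_tab$mean_ppp <- convert_to_ppp(stats_tab$mean, config$toman_per_ppp)
    utils::write.csv(format_numeric_df(stats_tab), path, row.names = FALSE)
    record("prevalence", path)
    path <- file.path(config$output_dir, "breakdown_shares.csv")
    shares <- do.call(rbind, Map(function(tab, nm) {
      cbind(table = nm, tab)
    }, breakdown$shares, names(breakdown$shares)))
    utils::write.csv(format_numeric_df(shares), path, row.names = FALSE)
    record("prevalence", path)
    out$costs <- costs
    out$breakdown <- breakdown
  }

  markov_result <- NULL
  if ("markov" %in% stages) {
    log_stage(config, "markov", "running ", config$markov$horizon_cycles,
              "-cycle cohort model")
    markov_result <- run_markov_cohort(config$markov)
    path <- file.path(config$output_dir, "markov_trace.csv")
    tr <- as.data.frame(markov_result$trace)
    tr <- cbind(cycle = 0:(nrow(tr) - 1L), tr)
    utils::write.csv(format_numeric_df(tr), path, row.names = FALSE)
    record("markov", path)
    path <- file.path(config$output_dir, "markov_summary.csv")
    summ <- data.frame(
      state = names(markov_result$per_state),
      attributed_cost = markov_result$per_state,
      share_raw = markov_result$shares$share_raw,
      share_rounded = markov_result$shares$share_rounded,
      row.names = NULL
    )
    utils::write.csv(format_numeric_df(summ), path, row.names = FALSE)
    record("markov", path)
    out$markov_result <- markov_result
  }

  fit <- NULL
  if ("regress" %in% stages) {
    rec <- need_cohort("regress")
    if (is.null(costs)) {
      if (nrow(rec) == 0L) stop_data("regress stage needs a non-empty cohort")
      costs <- annual_patient_costs(rec, config$wages)
    }
    log_stage(config, "regress", "two-part fit on ", nrow(rec), " patients")
    fit <- fit_two_part(rec, costs$grand_total,
                        covariates = config$covariates,
                        gender_coding = config$gender_coding,
                        family = config$family, link = config$link)
    for (part in c("probit", "glm")) {
      path <- file.path(config$output_dir, paste0("regression_", part, ".csv"))
      utils::write.csv(format_numeric_df(fit[[part]]$coefficients), path,
                       row.names = FALSE)
      record("regress", path)
    }
    out$fit <- fit
  }

  if (!is.null(breakdown) || !is.null(markov_result) || !is.null(fit)) {
    path <- file.path(config$output_dir, "report.md")
    writeLines(render_report(breakdown, markov_result, fit,
                             toman_per_ppp = config$toman_per_ppp), path)
    record("report", path)
  }
  out$manifest <- manifest
  class(out) <- "pipeline_result"
  out
}

# fixed-notation formatting so CSV bytes are reproducible across platforms
format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.10f", df[[nm]])
  }
  df
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> status", x$status, "|", nrow(x$manifest),
      "artifacts\n")
  print(x$manifest)
  invisible(x)
}

#' Render a markdown report of the analysis
#'
#' Produces a human-readable markdown report with an annual-cost table
#' (component means/SDs with shares), a lifetime-cost section (per-state
#' attribution and shares), and the two regression coefficient tables.
#' Sections whose inputs are absent are marked as not run, never treated as
#' an error.
#'
#' @param breakdown an `annual_cost_breakdown` or NULL.
#' @param markov_result a `markov_result` or NULL.
#' @param fit a `twopart_fit` or NULL.
#' @param toman_per_ppp conversion factor for the PPP column.
#' @return character vector of markdown lines.
#' @export
render_report <- function(breakdown = NULL, markov_result = NULL, fit = NULL,
                          toman_per_ppp = hf_reference_ppp_factor()) {
  lines <- c("# Heart-failure cost-of-illness report", "")
  lines <- c(lines, "## Annual cost per patient (prevalence-based)", "")
  if (is.null(breakdown)) {
    lines <- c(lines, "_Stage not run._", "")
  } else {
    cs <- breakdown$component_stats
    lines <- c(lines,
      "| Component | Mean (Toman/yr) | SD | Mean (PPP$) |",
      "|---|---:|---:|---:|",
      sprintf("| %s | %s | %s | %s |", cs$component, fmt_toman(cs$mean),
              fmt_toman(cs$sd),
              fmt_toman(convert_to_ppp(cs$mean, toman_per_ppp), 2)),
      "")
    di <- breakdown$shares$direct_indirect
    lines <- c(lines, sprintf(
      "Direct %d%% / indirect %d%% of the grand total (%s Toman, %s PPP$).",
      di$share_rounded[di$component == "direct"],
      di$share_rounded[di$component == "indirect"],
      fmt_toman(breakdown$totals[["grand"]]),
      fmt_toman(convert_to_ppp(breakdown$totals[["grand"]], toman_per_ppp), 2)),
      "")
    dm <- breakdown$shares$direct_medical
    lines <- c(lines, sprintf(
      "Direct medical split: %s.",
      paste(sprintf("%s %d%%", dm$component, dm$share_rounded), collapse = ", ")),
      "")
    bc <- breakdown$shares$by_class
    lines <- c(lines, sprintf(
      "Annual cost share by NYHA class: %s.",
      paste(sprintf("%s %d%%", bc$component, bc$share_rounded), collapse = ", ")),
      "")
  }
  lines <- c(lines, "## Lifetime cost per patient (Markov model)", "")
  if (is.null(markov_result)) {
    lines <- c(lines, "_Stage not run._", "")
  } else {
    lines <- c(lines,
      sprintf("Expected lifetime cost over %d one-year cycles: %s Toman.",
              markov_result$spec$horizon_cycles,
              fmt_toman(markov_result$lifetime_total, 0)),
      "",
      "| State | Attributed cost (Toman) | Share |",
      "|---|---:|---:|",
      sprintf("| %s | %s | %d%% |", names(markov_result$per_state),
              fmt_toman(markov_result$per_state, 0),
              markov_result$shares$share_rounded),
      "",
      sprintf("Expected life-years: %.2f; P(death from HF) by horizon: %.3f.",
              markov_result$life_years, markov_result$p_death_hf),
      "")
  }
  lines <- c(lines, "## Two-part regression", "")
  if (is.null(fit)) {
    lines <- c(lines, "_Stage not run._", "")
  } else {
    coef_block <- function(tab) {
      c("| Term | Coef | Std.Err | z | P>|z| | 95% CI |",
        "|---|---:|---:|---:|---:|---:|",
        sprintf("| %s | %.7g | %.7g | %.2f | %.3f | [%.7g, %.7g] |",
                tab$term, tab$estimate, tab$std_error, tab$z, tab$p_value,
                tab$conf_low, tab$conf_high))
    }
    lines <- c(lines,
      "### A. Probit (any cost)", "", coef_block(fit$probit$coefficients), "",
      sprintf("### B. %s GLM, %s link (positive costs)", fit$glm$family,
              fit$glm$link),
      "", coef_block(fit$glm$coefficients), "",
      sprintf(paste0("Combined log-likelihood %.6f; AIC %.5f ",
                     "(per-observation %.5f); BIC %.4f."),
              fit$loglik, fit$ic$aic, fit$ic$aic_per_obs, fit$ic$bic),
      "")
  }
  lines
}
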