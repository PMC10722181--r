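#' @keywords internal
"_PACKAGE"

# Errors are classed so callers (and tests) can distinguish configuration
# mistakes from data problems and calibration infeasibility.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("hfcoi_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("hfcoi_data_error", "error")))
}

stop_calibration <- function(...) {
  stop(errorCondition(paste0(...), class = c("hfcoi_calibration_error", "error")))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for the percentage shares in reports,
#' so that e.g. 20.5 reports as 21. Base R's `round()` rounds half to even,
#' which is the wrong convention for report parity with published tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(20.5, 79.5))  # 21 80, where round() gives 20 80
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_pos_num <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
}

is_nonneg_num <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0
}

# Format Toman amounts with thousands separators for reports.
fmt_toman <- function(x, digits = 1) {
  formatC(x, format = "f", digits = digits, big.mark = ",")
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so generation never perturbs user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
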