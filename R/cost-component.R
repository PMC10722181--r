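#' Zero-inflated cost-component specification
#'
#' Describes the marginal distribution of one cost component as a two-part
#' mixture: a point mass at zero with probability `zero_prob`, and a positive
#' right-skewed draw (lognormal or gamma) parameterised by its mean and
#' coefficient of variation. This is the standard generating process for
#' semicontinuous health-expenditure data and the process the two-part
#' regression assumes.
#'
#' @param positive_mean mean of the positive part (Toman, or any unit).
#' @param positive_cv coefficient of variation (SD/mean) of the positive part;
#'   must be strictly positive.
#' @param zero_prob probability of an exact zero.
#' @param family `"lognormal"` (default) or `"gamma"` for the positive part.
#' @return an object of class `cost_component_spec`.
#' @seealso [calibrate_component_to_marginal()], [sample_cost_component()]
#' @export
cost_component_spec <- function(positive_mean, positive_cv, zero_prob = 0,
                                family = c("lognormal", "gamma")) {
  if (!is.character(family) || length(family) == 0) {
    stop_config("cost component 'family' must be a string, got ", class(family)[1])
  }
  family <- family[1]
  if (!family %in% c("lognormal", "gamma")) {
    stop_config("unknown cost component family: '", family,
                "' (use 'lognormal' or 'gamma')")
  }
  if (!is_nonneg_num(positive_mean)) {
    stop_config("'positive_mean' must be a non-negative number")
  }
  if (!is_pos_num(positive_cv)) {
    stop_config("'positive_cv' must be a positive number")
  }
  if (!is_prob(zero_prob)) {
    stop_config("'zero_prob' must be a probability in [0, 1]")
  }
  structure(
    list(positive_mean = positive_mean, positive_cv = positive_cv,
         zero_prob = zero_prob, family = family),
    class = "cost_component_spec"
  )
}

#' @export
print.cost_component_spec <- function(x, ...) {
  m <- component_marginal_moments(x)
  cat(sprintf(
    "<cost_component_spec> %s | P(zero) = %.3f | positive mean = %s, CV = %.3f\n",
    x$family, x$zero_prob, fmt_toman(x$positive_mean, 2), x$positive_cv))
  cat(sprintf("  marginal mean = %s, marginal SD = %s\n",
              fmt_toman(m[["mean"]], 2), fmt_toman(m[["sd"]], 2)))
  invisible(x)
}

#' Marginal moments of a zero-inflated component
#'
#' For the mixture with zero probability \eqn{p_0}, positive mean \eqn{\mu}
#' and positive CV \eqn{c}:
#' mean \eqn{= (1-p_0)\mu} and variance
#' \eqn{= (1-p_0)c^2\mu^2 + p_0(1-p_0)\mu^2}.
#'
#' @param spec a [cost_component_spec()].
#' @return named numeric vector `c(mean =, sd =)`.
#' @export
component_marginal_moments <- function(spec) {
  stopifnot(inherits(spec, "cost_component_spec"))
  p0 <- spec$zero_prob
  mu <- spec$positive_mean
  v <- (1 - p0) * (spec$positive_cv * mu)^2 + p0 * (1 - p0) * mu^2
  c(mean = (1 - p0) * mu, sd = sqrt(v))
}

#' Calibrate a component to target marginal moments
#'
#' Inverts the zero-inflated mixture moments: given a target marginal mean and
#' SD and an assumed zero probability, solves for the positive-part mean and
#' CV so the mixture reproduces the targets exactly. Published cost tables
#' report marginal means/SDs only, so this is how the synthetic generator is
#' tied to them.
#'
#' The mixture variance has a floor of \eqn{p_0/(1-p_0)} times the squared
#' target mean (the Bernoulli part alone); a smaller target SD is infeasible
#' and raises a calibration error stating that floor.
#'
#' @param target_mean,target_sd target marginal mean and SD (> 0).
#' @param zero_prob assumed probability of a zero cost (< 1).
#' @param family positive-part family, passed to [cost_component_spec()].
#' @return a calibrated [cost_component_spec()].
#' @export
#' @examples
#' sp <- calibrate_component_to_marginal(5053339.627, 31551902.47, zero_prob = 0.4)
#' component_marginal_moments(sp)
calibrate_component_to_marginal <- function(target_mean, target_sd, zero_prob = 0,
                                            family = c("lognormal", "gamma")) {
  if (!is_pos_num(target_mean)) stop_calibration("'target_mean' must be > 0")
  if (!is.numeric(target_sd) || length(target_sd) != 1L || is.na(target_sd) ||
      target_sd < 0) {
    stop_calibration("'target_sd' must be a non-negative number")
  }
  if (!is_prob(zero_prob) || zero_prob >= 1) {
    stop_calibration("'zero_prob' must be in [0, 1)")
  }
  p0 <- zero_prob
  mu <- target_mean / (1 - p0)
  sd_floor <- target_mean * sqrt(p0 / (1 - p0))
  var_pos <- (target_sd^2 - p0 * target_mean^2 / (1 - p0)) / (1 - p0)
  if (var_pos <= 0) {
    stop_calibration(sprintf(
      paste0("target_sd = %.6g is infeasible with zero_prob = %.3f: ",
             "the zero-inflation alone implies SD > %.6g ",
             "(feasible SD floor for target_mean = %.6g)"),
      target_sd, p0, sd_floor, target_mean))
  }
  cost_component_spec(positive_mean = mu, positive_cv = sqrt(var_pos) / mu,
                      zero_prob = p0, family = family)
}

#' Draw from a zero-inflated cost component
#'
#' Returns exact zeros with probability `zero_prob` and otherwise a positive
#' draw whose mean and CV match the spec. Lognormal uses
#' \eqn{\sigma^2_{\log} = \log(1 + c^2)}; gamma uses shape \eqn{1/c^2}.
#'
#' @param spec a [cost_component_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`, all values >= 0.
#' @export
sample_cost_component <- function(spec, n = 1) {
  stopifnot(inherits(spec, "cost_component_spec"))
  if (!is_count(n)) stop_config("'n' must be a non-negative count")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (spec$positive_mean == 0) return(numeric(n))
  pos <- switch(spec$family,
    lognormal = {
      sdlog <- sqrt(log1p(spec$positive_cv^2))
      stats::rlnorm(n, meanlog = log(spec$positive_mean) - sdlog^2 / 2,
                    sdlog = sdlog)
    },
    gamma = {
      shape <- 1 / spec$positive_cv^2
      stats::rgamma(n, shape = shape, rate = shape / spec$positive_mean)
    },
    stop_config("unknown cost component family: ", spec$family)
  )
  zero <- stats::runif(n) < spec$zero_prob
  pos[zero] <- 0
  pos
}
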