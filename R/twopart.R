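default_covariates <- function() {
  c("age", "gender", "base_insurance", "comorbidity", "disease_class")
}

#' Build the regression design matrix
#'
#' Maps cohort records to the covariate set used in the cost regression:
#' age (years, linear), gender indicator (1 = female by default; set
#' `gender_coding = "male1"` to flip — the coding is a convention, so it is
#' explicit and configurable), basic-insurance and comorbidity indicators,
#' and NYHA disease class entered as a single linear 1-4 term. An intercept
#' column is prepended.
#'
#' @param records cohort data.frame with columns `age`, `gender`,
#'   `basic_insurance`, `comorbidity`, `nyha_class`.
#' @param covariates subset of the default covariate names to include.
#' @param gender_coding `"female1"` (default) or `"male1"`.
#' @return numeric matrix with an `(Intercept)` column, no missing values.
#' @export
build_design_matrix <- function(records,
                                covariates = default_covariates(),
                                gender_coding = c("female1", "male1")) {
  gender_coding <- match.arg(gender_coding)
  unknown <- setdiff(covariates, default_covariates())
  if (length(unknown)) {
    stop_config("unknown covariates: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(records)
  cols <- list("(Intercept)" = rep(1, n))
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      age = as.numeric(records$age),
      gender = if (gender_coding == "female1") {
        as.numeric(records$gender == "female")
      } else {
        as.numeric(records$gender == "male")
      },
      base_insurance = as.numeric(records$basic_insurance),
      comorbidity = as.numeric(records$comorbidity),
      disease_class = as.numeric(records$nyha_class)
    )
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyNA(X)) stop_data("design matrix contains missing values")
  if (any(!records$nyha_class %in% 1:4) && "disease_class" %in% covariates) {
    stop_data("'nyha_class' must lie in 1..4")
  }
  X
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop_data("design matrix is rank deficient; collinear columns: ",
              paste(dropped, collapse = ", "))
  }
  invisible(X)
}

coef_table <- function(beta, se, level = 0.95) {
  z <- beta / se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    z = unname(z),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    conf_low = unname(beta - zq * se),
    conf_high = unname(beta + zq * se),
    row.names = NULL
  )
}

probit_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * stats::pnorm(eta, log.p = TRUE) +
        (1 - y) * stats::pnorm(-eta, log.p = TRUE))
}

probit_score <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  # inverse Mills ratios; exp(log) form keeps the tails finite
  lam1 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(eta, log.p = TRUE))
  lam0 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(-eta, log.p = TRUE))
  drop(crossprod(X, y * lam1 - (1 - y) * lam0))
}

# observed information: -d2l/dbeta2 = X' diag(w) X with
# w_i = y lam1 (lam1 + eta) + (1-y) lam0 (lam0 - eta), both terms positive
probit_observed_info <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  lam1 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(eta, log.p = TRUE))
  lam0 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(-eta, log.p = TRUE))
  w <- y * lam1 * (lam1 + eta) + (1 - y) * lam0 * (lam0 - eta)
  crossprod(X * sqrt(pmax(w, 0)))
}

#' Fit the probit part (probability of any cost)
#'
#' Maximum-likelihood probit regression of a binary any-cost indicator on the
#' design matrix. Fisher-scoring estimates are polished by Newton steps on
#' the exact log-likelihood until the score norm falls below `tol`;
#' non-convergence is reported in the returned diagnostics and as a warning,
#' never silently. Standard errors come from the observed information
#' (negative Hessian at the optimum); p-values use the normal reference.
#'
#' Quasi-separation (a covariate perfectly predicting the outcome) drives
#' fitted probabilities to 0/1 and the likelihood to a flat ridge; it is
#' detected and reported as a `hfcoi_separation` warning.
#'
#' @param y binary (0/1 or logical) response; must contain both classes.
#' @param X design matrix from [build_design_matrix()] (full column rank).
#' @param tol gradient-norm convergence tolerance.
#' @param max_newton maximum Newton polish iterations.
#' @return object of class `probit_fit`: `coefficients` table
#'   ([coef_table()] columns), `loglik`, `gradient_norm`, `converged`,
#'   `iterations`, `fitted`, `vcov`, `n`.
#' @export
fit_probit <- function(y, X, tol = 1e-8, max_newton = 50L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_data("'y' must be binary (0/1)")
  if (length(unique(y)) < 2L) stop_data("'y' must contain both classes")
  if (nrow(X) != length(y)) stop_data("X and y dimensions disagree")
  check_full_rank(X)

  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial("probit"),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- fit$coefficients
  iters <- fit$iter
  g <- probit_score(beta, X, y)
  newton <- 0L
  while (sqrt(sum(g^2)) > tol && newton < max_newton) {
    info <- probit_observed_info(beta, X, y)
    step <- tryCatch(solve(info, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- beta + step
    if (probit_loglik(cand, X, y) < probit_loglik(beta, X, y) - 1e-8) break
    beta <- cand
    g <- probit_score(beta, X, y)
    newton <- newton + 1L
  }
  gnorm <- sqrt(sum(g^2))
  converged <- gnorm < tol
  if (!converged) {
    warning("probit did not reach gradient norm < ", tol,
            " (final norm ", format(gnorm, digits = 3), ")")
  }
  eta <- drop(X %*% beta)
  p <- stats::pnorm(eta)
  ll <- probit_loglik(beta, X, y)
  # a (numerically) perfect fit of a binary outcome means some covariate
  # combination separates the classes and the MLE is off to infinity
  if (sep_warned || ll > -1e-3 ||
      (any(p > 1 - 1e-10 | p < 1e-10) && max(abs(beta)) > 8)) {
    warning(warningCondition(
      paste("possible separation: fitted probabilities numerically 0 or 1;",
            "some covariate may perfectly predict the outcome"),
      class = c("hfcoi_separation", "warning", "condition")))
  }
  info <- probit_observed_info(beta, X, y)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
    # near-singular information (typically under separation): regularise so
    # the fit is still reported; the separation warning flags the cause
    ridge <- diag(ncol(X)) * max(diag(info)) * 1e-10
    vc <- solve(info + ridge)
  }
  se <- sqrt(diag(vc))
  structure(
    list(coefficients = coef_table(stats::setNames(beta, colnames(X)), se),
         loglik = ll, gradient_norm = gnorm, converged = converged,
         iterations = iters + newton, fitted = p, vcov = vc,
         n = length(y)),
    class = "probit_fit"
  )
}

#' Fit the GLM part (positive costs)
#'
#' Log-link GLM for the strictly positive costs, fitted by iteratively
#' reweighted least squares with a relative deviance-change tolerance of
#' 1e-10. Default family is gamma — the standard choice for right-skewed
#' positive expenditure — with gaussian and inverse-gaussian selectable.
#' Dispersion is estimated by the Pearson method; z statistics use the
#' normal reference.
#'
#' @param y strictly positive response (zeros belong to the probit part and
#'   raise an error here).
#' @param X design matrix (full column rank).
#' @param family `"gamma"` (default), `"gaussian"` or `"inverse.gaussian"`.
#' @param link `"log"` (default) or `"identity"`.
#' @return object of class `glm_positive_fit`: `coefficients` table,
#'   `loglik`, `deviance`, `dispersion` (Pearson), `family`, `link`,
#'   `converged`, `iterations`, `n`, and the underlying `glm` object.
#' @export
fit_glm_positive <- function(y, X, family = c("gamma", "gaussian",
                                              "inverse.gaussian"),
                             link = c("log", "identity")) {
  family <- match.arg(family)
  link <- match.arg(link)
  if (any(y <= 0)) {
    stop_data("fit_glm_positive() requires strictly positive responses; ",
              "zero costs belong to the probit part")
  }
  if (nrow(X) != length(y)) stop_data("X and y dimensions disagree")
  check_full_rank(X)
  fam <- switch(family,
    gamma = stats::Gamma(link = link),
    gaussian = stats::gaussian(link = link),
    inverse.gaussian = stats::inverse.gaussian(link = link))
  dat <- as.data.frame(X[, colnames(X) != "(Intercept)", drop = FALSE])
  form <- if (ncol(dat) == 0L) .y ~ 1 else .y ~ .
  dat$.y <- y
  fit <- stats::glm(form, data = dat, family = fam,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) warning("GLM did not converge in 100 IRLS iterations")
  k <- length(stats::coef(fit))
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- pearson / (length(y) - k)
  sm <- summary(fit, dispersion = dispersion)
  beta <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  structure(
    list(coefficients = coef_table(beta, se),
         loglik = as.numeric(stats::logLik(fit)),
         deviance = stats::deviance(fit),
         dispersion = dispersion,
         family = family, link = link,
         converged = fit$converged, iterations = fit$iter,
         n = length(y), glm = fit),
    class = "glm_positive_fit"
  )
}

#' Fit the full two-part cost model
#'
#' Part one: probit for P(cost > 0) on all patients. Part two: log-link GLM
#' for the level of cost among patients with positive cost. The two parts
#' share the covariate set; the combined log-likelihood is the sum of the
#' parts' contributions, and information criteria are reported in both the
#' whole-model and per-observation conventions ([information_criteria()]).
#'
#' @param records cohort data.frame ([build_design_matrix()] contract).
#' @param response numeric vector of annual costs (>= 0), one per record —
#'   typically `grand_total` from [annual_patient_costs()].
#' @param covariates,gender_coding passed to [build_design_matrix()].
#' @param family,link passed to [fit_glm_positive()].
#' @return object of class `twopart_fit` with elements `probit`, `glm`,
#'   `loglik` (combined), `ic` (information criteria for the combined model),
#'   `covariates`, `gender_coding`, `n`, `n_positive`.
#' @export
fit_two_part <- function(records, response,
                         covariates = default_covariates(),
                         gender_coding = "female1",
                         family = "gamma", link = "log") {
  if (length(response) != nrow(records)) {
    stop_data("'response' must have one value per record")
  }
  if (any(is.na(response)) || any(response < 0)) {
    stop_data("'response' must be non-negative and non-missing")
  }
  X <- build_design_matrix(records, covariates, gender_coding)
  any_cost <- as.numeric(response > 0)
  part1 <- fit_probit(any_cost, X)
  pos <- response > 0
  part2 <- fit_glm_positive(response[pos], X[pos, , drop = FALSE],
                            family = family, link = link)
  ll <- part1$loglik + part2$loglik
  k <- nrow(part1$coefficients) + nrow(part2$coefficients)
  structure(
    list(probit = part1, glm = part2, loglik = ll,
         ic = information_criteria(ll, k = k, n = length(response),
                                   deviance = part2$deviance),
         covariates = covariates, gender_coding = gender_coding,
         n = length(response), n_positive = sum(pos)),
    class = "twopart_fit"
  )
}

#' @export
print.twopart_fit <- function(x, ...) {
  cat("<twopart_fit>", x$n, "patients (", x$n_positive, "with positive cost )\n")
  cat("A. Probit (any cost), log-likelihood", sprintf("%.4f", x$probit$loglik), "\n")
  print(x$probit$coefficients, digits = 4)
  cat("B.", x$glm$family, "GLM (", x$glm$link, "link ), log-likelihood",
      sprintf("%.4f", x$glm$loglik), "\n")
  print(x$glm$coefficients, digits = 4)
  cat(sprintf("combined loglik %.4f | AIC %.3f (per-obs %.5f) | BIC %.3f\n",
              x$loglik, x$ic$aic, x$ic$aic_per_obs, x$ic$bic))
  invisible(x)
}

#' Expected cost from a two-part fit
#'
#' Per-patient expectation `Phi(x b_probit) * g^-1(x b_glm)` — the
#' probability of any cost times the conditional mean given a positive cost.
#'
#' @param fit a [fit_two_part()] result.
#' @param records cohort data.frame with the fit's covariates.
#' @param observed optional observed responses, for the predicted/observed
#'   comparison the model is judged by.
#' @return list with `expected` (per patient), `mean_expected`, and, when
#'   `observed` is given, `mean_observed` and `ratio`
#'   (predicted mean / observed mean).
#' @export
predict_expected_cost <- function(fit, records, observed = NULL) {
  stopifnot(inherits(fit, "twopart_fit"))
  X <- build_design_matrix(records, fit$covariates, fit$gender_coding)
  terms1 <- fit$probit$coefficients$term
  terms2 <- fit$glm$coefficients$term
  b1 <- stats::setNames(fit$probit$coefficients$estimate, terms1)
  b2 <- stats::setNames(fit$glm$coefficients$estimate, terms2)
  if (!setequal(colnames(X), names(b1)) || !setequal(colnames(X), names(b2))) {
    stop_data("covariate names of the two parts do not match the design: ",
              paste(setdiff(names(b2), colnames(X)), collapse = ", "))
  }
  p <- stats::pnorm(drop(X[, names(b1), drop = FALSE] %*% b1))
  eta <- drop(X[, names(b2), drop = FALSE] %*% b2)
  mu <- if (fit$glm$link == "log") exp(eta) else eta
  expected <- p * mu
  out <- list(expected = expected, mean_expected = mean(expected))
  if (!is.null(observed)) {
    out$mean_observed <- mean(observed)
    out$ratio <- out$mean_expected / out$mean_observed
  }
  out
}

#' Information criteria in both reporting conventions
#'
#' Statistical software disagrees on AIC/BIC scaling for two-part and GLM
#' fits, so every convention is computed and labelled: the whole-model
#' textbook forms `AIC = 2k - 2 logLik`, `BIC = k ln(n) - 2 logLik`; the
#' per-observation form `AIC/n` (used by Stata's `twopm`-style output); and,
#' when a deviance is supplied, the deviance-based
#' `BIC = deviance - df_residual ln(n)` variant.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters (>= 0).
#' @param n number of observations (> 0).
#' @param deviance optional residual deviance for the deviance-based BIC.
#' @return list `aic`, `bic`, `aic_per_obs`, `bic_deviance` (NULL without a
#'   deviance), plus `k` and `n`.
#' @export
#' @examples
#' information_criteria(-10, k = 0, n = 1)$aic  # 20
information_criteria <- function(loglik, k, n, deviance = NULL) {
  if (!is_count(k)) stop_config("'k' must be a count >= 0")
  if (!is_count(n) || n == 0) stop_config("'n' must be a positive count")
  aic <- 2 * k - 2 * loglik
  list(
    aic = aic,
    bic = k * log(n) - 2 * loglik,
    aic_per_obs = aic / n,
    bic_deviance = if (!is.null(deviance)) deviance - (n - k) * log(n),
    k = k, n = n
  )
}

#' Simulate a cohort from a known two-part process
#'
#' Draws covariates shaped like the regression design (age ~ N(63, 14)
#' truncated to 8-95, three Bernoulli indicators, class uniform on 1-4),
#' then a zero/positive outcome from a probit with coefficients
#' `coef_probit` and, conditionally on a positive outcome, a gamma draw with
#' log-link mean `exp(x b_glm)` and shape `1/positive_cv^2`. Used for
#' estimator-recovery and predicted-vs-observed checks where the truth is
#' known by construction.
#'
#' @param n cohort size.
#' @param coef_probit,coef_glm named coefficient vectors over
#'   `(Intercept)`, `age`, `gender`, `base_insurance`, `comorbidity`,
#'   `disease_class` (subsets allowed; missing terms are 0).
#' @param positive_cv CV of the conditional gamma.
#' @param seed RNG seed.
#' @return list with `records` (covariate data.frame in the cohort dialect),
#'   `response`, and the true coefficient vectors.
#' @export
simulate_two_part_cohort <- function(n, coef_probit, coef_glm,
                                     positive_cv = 1, seed = 1L) {
  with_seed(seed, {
    records <- data.frame(
      age = rtruncnorm(n, 63, 14, 8, 95),
      gender = ifelse(stats::runif(n) < 0.5, "female", "male"),
      basic_insurance = stats::runif(n) < 0.9,
      comorbidity = stats::runif(n) < 0.6,
      nyha_class = sample.int(4L, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    X <- build_design_matrix(records)
    full <- function(b) {
      out <- stats::setNames(numeric(ncol(X)), colnames(X))
      out[names(b)] <- b
      out
    }
    b1 <- full(coef_probit)
    b2 <- full(coef_glm)
    p <- stats::pnorm(drop(X %*% b1))
    positive <- stats::runif(n) < p
    mu <- exp(drop(X %*% b2))
    shape <- 1 / positive_cv^2
    y <- numeric(n)
    y[positive] <- stats::rgamma(sum(positive), shape = shape,
                                 rate = shape / mu[positive])
    list(records = records, response = y, coef_probit = b1, coef_glm = b2)
  })
}
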