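test_that("intercept-only probit recovers the normal quantile of the rate", {
  set.seed(3)
  y <- as.numeric(stats::runif(400) < 0.62)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_probit(y, X)
  expect_equal(fit$coefficients$estimate, stats::qnorm(mean(y)),
               tolerance = 1e-6)
  expect_lte(fit$gradient_norm, 1e-8)
  expect_true(fit$converged)
  expect_lte(fit$loglik, 0)
  # z = coef / se and CI brackets the estimate
  tab <- fit$coefficients
  expect_equal(tab$z, tab$estimate / tab$std_error, tolerance = 1e-8)
  expect_true(all(tab$conf_low <= tab$estimate & tab$estimate <= tab$conf_high))
})

test_that("probit optimum beats a brute-force grid on a tiny dataset", {
  set.seed(8)
  x <- stats::rnorm(10)
  y <- c(1, 0, 1, 1, 0, 1, 0, 1, 0, 1)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_probit(y, X)
  b <- fit$coefficients$estimate
  grid <- expand.grid(b0 = b[1] + seq(-2, 2, length.out = 50),
                      b1 = b[2] + seq(-2, 2, length.out = 50))
  ll_grid <- apply(grid, 1, function(g) oracle_probit_loglik(g, X, y))
  expect_gte(fit$loglik, max(ll_grid))
})

test_that("probit flags separation and rank deficiency explicitly", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x  # x perfectly predicts y
  X <- cbind("(Intercept)" = 1, x = x)
  sep_seen <- FALSE
  withCallingHandlers(
    fit_probit(y, X),
    warning = function(w) {
      if (inherits(w, "hfcoi_separation")) sep_seen <<- TRUE
      invokeRestart("muffleWarning")
    })
  expect_true(sep_seen)

  set.seed(1)
  x1 <- stats::rnorm(50)
  X2 <- cbind("(Intercept)" = 1, a = x1, b = 2 * x1)
  y2 <- as.numeric(stats::runif(50) < 0.5)
  expect_error(fit_probit(y2, X2), "collinear.*b", class = "hfcoi_data_error")

  expect_error(fit_probit(rep(1, 10), X[1:10, , drop = FALSE]),
               "both classes", class = "hfcoi_data_error")
})

test_that("positive-part GLM matches closed forms and rejects zeros", {
  set.seed(5)
  y <- stats::rgamma(300, shape = 2, rate = 2 / 50)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_glm_positive(y, X)
  expect_equal(fit$coefficients$estimate, log(mean(y)), tolerance = 1e-8)

  # degenerate constant response: intercept ln(c), slope 0, zero deviance
  yc <- rep(7.5, 40)
  Xc <- cbind("(Intercept)" = 1, x = stats::rnorm(40))
  fitc <- fit_glm_positive(yc, Xc)
  expect_equal(fitc$coefficients$estimate[1], log(7.5), tolerance = 1e-8)
  expect_equal(fitc$coefficients$estimate[2], 0, tolerance = 1e-8)
  expect_lt(fitc$deviance, 1e-12)

  expect_error(fit_glm_positive(c(y, 0), rbind(X, 1)),
               "probit", class = "hfcoi_data_error")
})

test_that("both parts recover known coefficients on simulated cohorts", {
  b1 <- c("(Intercept)" = 1.0, age = -0.01, gender = -0.2,
          base_insurance = 0.6, comorbidity = -0.05, disease_class = -0.1)
  b2 <- c("(Intercept)" = 19.6, age = -0.001, gender = -0.36,
          base_insurance = -0.32, comorbidity = 0.06, disease_class = 0.12)
  sim <- simulate_two_part_cohort(5000, b1, b2, positive_cv = 1.5, seed = 31)
  fit <- fit_two_part(sim$records, sim$response)
  p_tab <- fit$probit$coefficients
  g_tab <- fit$glm$coefficients
  expect_true(all(abs(p_tab$estimate - b1[p_tab$term]) <= 3 * p_tab$std_error))
  expect_true(all(abs(g_tab$estimate - b2[g_tab$term]) <= 3 * g_tab$std_error))
  # the combined log-likelihood is the sum of the parts
  expect_equal(fit$loglik, fit$probit$loglik + fit$glm$loglik)
})

test_that("standardising a covariate rescales coef and SE but not z or p", {
  b1 <- c("(Intercept)" = 0.8, age = -0.02)
  b2 <- c("(Intercept)" = 15, age = 0.01)
  sim <- simulate_two_part_cohort(2000, b1, b2, positive_cv = 1, seed = 9)
  fit_a <- fit_two_part(sim$records, sim$response,
                        covariates = c("age", "gender"))
  rec_scaled <- sim$records
  rec_scaled$age <- rec_scaled$age / 10
  fit_b <- fit_two_part(rec_scaled, sim$response,
                        covariates = c("age", "gender"))
  for (part in c("probit", "glm")) {
    a <- fit_a[[part]]$coefficients
    b <- fit_b[[part]]$coefficients
    i <- a$term == "age"
    expect_equal(b$estimate[i], 10 * a$estimate[i], tolerance = 1e-4)
    expect_equal(b$std_error[i], 10 * a$std_error[i], tolerance = 1e-4)
    expect_equal(b$z[i], a$z[i], tolerance = 1e-5)
    expect_equal(b$p_value[i], a$p_value[i], tolerance = 1e-5)
  }
})

test_that("expected-cost prediction combines the parts multiplicatively", {
  # probability forced to ~1 and intercept-only GLM: prediction = exp(b0)
  fit <- structure(list(
    probit = list(coefficients = data.frame(
      term = "(Intercept)", estimate = 30, std_error = 1, z = 30,
      p_value = 0, conf_low = 28, conf_high = 32)),
    glm = list(coefficients = data.frame(
      term = "(Intercept)", estimate = log(1234), std_error = 1, z = 1,
      p_value = 0.3, conf_low = 0, conf_high = 1), link = "log"),
    covariates = character(0), gender_coding = "female1"
  ), class = "twopart_fit")
  rec <- make_record()
  pr <- predict_expected_cost(fit, rec)
  expect_equal(pr$expected, 1234, tolerance = 1e-9)

  # probability forced to ~0 predicts zero
  fit$probit$coefficients$estimate <- -30
  expect_equal(predict_expected_cost(fit, rec)$expected, 0, tolerance = 1e-9)

  # self-consistency: cohort-mean prediction tracks the observed mean
  b1 <- c("(Intercept)" = 1.0, age = -0.01, disease_class = -0.1)
  b2 <- c("(Intercept)" = 19.6, gender = -0.36, disease_class = 0.12)
  sim <- simulate_two_part_cohort(10000, b1, b2, positive_cv = 1.5, seed = 77)
  f <- fit_two_part(sim$records, sim$response)
  pr <- predict_expected_cost(f, sim$records, sim$response)
  expect_lt(abs(pr$ratio - 1), 0.02)
})

test_that("information criteria follow every labelled convention", {
  ic <- information_criteria(-10, k = 0, n = 1)
  expect_identical(ic$aic, 20)
  expect_identical(ic$aic_per_obs, 20)
  ic <- information_criteria(-100, k = 3, n = 50, deviance = 42)
  expect_equal(ic$aic, 2 * 3 + 200)
  expect_equal(ic$bic, 3 * log(50) + 200)
  expect_equal(ic$aic_per_obs, ic$aic / 50)
  expect_equal(ic$bic_deviance, 42 - (50 - 3) * log(50))

  # a published per-observation AIC of 40.87735 with loglik -9538.861943 and
  # six parameters pins the sample size: brute-force integer search
  ll <- -9538.861943
  k <- 6
  n_grid <- 1:5000
  err <- abs((2 * k - 2 * ll) / n_grid - 40.87735)
  n_star <- n_grid[which.min(err)]
  expect_identical(n_star, 467L)
  expect_equal(information_criteria(ll, k, n_star)$aic_per_obs, 40.87735,
               tolerance = 1e-5)
})
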