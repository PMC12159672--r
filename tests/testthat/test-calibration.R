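# Calibration regressions: likelihood correctness against direct density
# evaluation, closed-form checks, AICc, all-subsets ranking, averaging
# arithmetic, delta-method predictions and cross-validation.

test_that("beta log-likelihood equals direct dbeta evaluation", {
  d <- make_calib_data(300, seed = 1)
  fit <- fit_calibration(d, c("bi_s", "site"), "coverage", "beta_logit")
  X <- build_design(d, fit$terms, fit$xlevels)
  mu <- plogis(drop(X %*% fit$coefficients))
  ll <- sum(dbeta(d$coverage, mu * fit$phi, (1 - mu) * fit$phi, log = TRUE))
  expect_equal(fit$logLik, ll, tolerance = 1e-9)
})

test_that("Poisson log-likelihood and MLE match closed forms", {
  set.seed(2)
  d <- make_calib_data(400, seed = 2)
  fit0 <- fit_calibration(d, character(0), "sonotypes", "poisson_log")
  expect_equal(unname(fit0$coefficients[1]), log(mean(d$sonotypes)),
               tolerance = 1e-8)
  mu <- exp(drop(build_design(d, character(0)) %*% fit0$coefficients))
  expect_equal(fit0$logLik, sum(dpois(d$sonotypes, mu, log = TRUE)),
               tolerance = 1e-9)
})

test_that("beta ML fit agrees with an independent optimizer", {
  d <- make_calib_data(500, seed = 3)
  fit <- fit_calibration(d, c("bi_s", "bi_s_sq"), "coverage", "beta_logit")
  X <- build_design(d, fit$terms, fit$xlevels)
  nll <- function(par) {
    mu <- plogis(drop(X %*% par[1:3]))
    -sum(dbeta(d$coverage, mu * exp(par[4]), (1 - mu) * exp(par[4]),
               log = TRUE))
  }
  alt <- optim(c(0, 0, 0, 1), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  expect_equal(fit$logLik, -alt$value, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), alt$par[1:3], tolerance = 1e-3)
})

test_that("intercept-only beta fit recovers the simulated mean", {
  set.seed(4)
  n <- 2000
  y <- rbeta(n, 0.7 * 20, 0.3 * 20)
  d <- data.frame(coverage = y)
  fit <- fit_calibration(d, character(0), "coverage", "beta_logit")
  est <- plogis(fit$coefficients[1])
  se <- sqrt(fit$vcov[1, 1]) * est * (1 - est)   # delta method
  expect_lt(abs(est - 0.7), 3 * se)
  expect_gt(fit$phi, 10)
})

test_that("responses outside the family support are rejected", {
  d <- make_calib_data(50, seed = 5)
  d$coverage[1] <- 0
  expect_error(fit_calibration(d, "bi_s", "coverage", "beta_logit"),
               "strictly in")
  d$sonotypes[2] <- 2.5
  expect_error(fit_calibration(d, "bi_s", "sonotypes", "poisson_log"),
               "nonnegative integers")
  d2 <- make_calib_data(50, seed = 6)
  d2$aci_s <- d2$bi_s
  expect_error(fit_calibration(d2, c("aci_s", "bi_s"), "sonotypes",
                               "poisson_log"), "aliased")
})

test_that("squeeze transform pulls proportions strictly inside (0,1)", {
  y <- c(0, 0.05, 0.5, 1)
  ys <- squeeze_proportion(y)
  expect_true(all(ys > 0 & ys < 1))
  expect_equal(ys[3], (0.5 * 3 + 0.5) / 4)
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(list(logLik = 0, k = 2, n = 10)), 4 + 12 / 7,
               tolerance = 1e-12)
  big <- aicc(list(logLik = -100, k = 3, n = 1e7))
  expect_equal(big, 206, tolerance = 1e-4)           # AICc -> AIC
  expect_error(aicc(list(logLik = 0, k = 5, n = 6)), "exceed")
})

test_that("adding a covariate never lowers the likelihood", {
  d <- make_calib_data(300, seed = 7)
  for (fam in c("beta_logit", "poisson_log")) {
    resp <- if (fam == "beta_logit") "coverage" else "sonotypes"
    small <- fit_calibration(d, "bi_s", resp, fam)
    big <- fit_calibration(d, c("bi_s", "np_s"), resp, fam)
    expect_gte(big$logLik, small$logLik - 1e-6)
  }
})

test_that("enumeration covers all subsets with coherent weights", {
  d <- make_calib_data(200, seed = 8)
  rk <- enumerate_models(d, "sonotypes", "poisson_log",
                         candidates = c("bi_s", "h_s"))
  expect_equal(nrow(rk$table), 4)
  expect_equal(rk$table$delta[1], 0)
  expect_equal(sum(rk$table$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(rk$table$aicc) >= 0))
  # rerunning is deterministic
  rk2 <- enumerate_models(d, "sonotypes", "poisson_log",
                          candidates = c("bi_s", "h_s"))
  expect_identical(rk$table, rk2$table)
})

test_that("selected term sets are invariant to covariate rescaling", {
  d <- make_calib_data(300, seed = 9)
  d2 <- d
  d2$bi_s <- d$bi_s * 10 - 3
  rk1 <- enumerate_models(d, "sonotypes", "poisson_log",
                          candidates = c("bi_s", "h_s", "np_s"))
  rk2 <- enumerate_models(d2, "sonotypes", "poisson_log",
                          candidates = c("bi_s", "h_s", "np_s"))
  expect_equal(rk1$table$terms, rk2$table$terms)
  expect_equal(rk1$table$aicc, rk2$table$aicc, tolerance = 1e-6)
})

test_that("model averaging follows the zero-substitution arithmetic", {
  d <- make_calib_data(250, seed = 10)
  rk <- enumerate_models(d, "sonotypes", "poisson_log",
                         candidates = c("bi_s", "h_s", "np_s"))
  avg <- average_models(rk, delta_max = 2)
  sel <- which(rk$table$delta < 2)
  w <- rk$table$weight[sel] / sum(rk$table$weight[sel])
  manual <- numeric(length(avg$coefficients))
  names(manual) <- names(avg$coefficients)
  for (i in seq_along(sel)) {
    cf <- rk$fits[[sel[i]]]$coefficients
    manual[names(cf)] <- manual[names(cf)] + w[i] * cf
  }
  expect_equal(avg$coefficients, manual, tolerance = 1e-12)
  expect_true(all(avg$inclusion <= avg$n_components))
  # shrinkage: averaged magnitude bounded by largest component magnitude
  for (nm in names(avg$coefficients)) {
    comp_max <- max(abs(vapply(rk$fits[sel], function(f) {
      if (nm %in% names(f$coefficients)) f$coefficients[[nm]] else 0
    }, numeric(1))))
    expect_lte(abs(avg$coefficients[[nm]]), comp_max + 1e-12)
  }
})

test_that("a single-component average reproduces that model", {
  d <- make_calib_data(400, seed = 11, beta1 = 6)   # strong signal
  rk <- enumerate_models(d, "coverage", "beta_logit",
                         candidates = c("bi_s", "h_s"))
  avg <- average_models(rk, delta_max = 1e-9)       # keep only the best
  expect_equal(avg$n_components, 1)
  best <- rk$fits[[1]]
  pr_avg <- predict_response(avg, d[1:10, ])
  fit_best <- fit_calibration(d, best$terms, "coverage", "beta_logit")
  pr_best <- predict_response(fit_best, d[1:10, ])
  expect_equal(pr_avg$mean, pr_best$mean, tolerance = 1e-6)
  expect_equal(pr_avg$se, pr_best$se, tolerance = 1e-4)
})

test_that("predictions invert the link and pass the bootstrap oracle", {
  # hand-built fits: eta = 0 -> mean 0.5 (beta); eta = log 5 -> mean 5
  bfit <- structure(list(coefficients = c("(Intercept)" = 0),
                         vcov = matrix(0.04, 1, 1,
                                       dimnames = list("(Intercept)",
                                                       "(Intercept)")),
                         family = "beta_logit", terms = character(0),
                         xlevels = NULL), class = "calib_fit")
  expect_equal(predict_response(bfit, data.frame(x = 1))$mean, 0.5)
  pfit <- structure(list(coefficients = c("(Intercept)" = log(5)),
                         vcov = matrix(0.01, 1, 1,
                                       dimnames = list("(Intercept)",
                                                       "(Intercept)")),
                         family = "poisson_log", terms = character(0),
                         xlevels = NULL), class = "calib_fit")
  expect_equal(predict_response(pfit, data.frame(x = 1))$mean, 5)

  # delta-method se vs parametric bootstrap over coefficient draws
  d <- make_calib_data(600, seed = 12)
  fit <- fit_calibration(d, c("bi_s", "h_s"), "coverage", "beta_logit")
  nd <- d[1:5, ]
  pr <- predict_response(fit, nd)
  set.seed(99)
  L <- chol(fit$vcov)
  draws <- matrix(rnorm(10000 * 3), 10000, 3) %*% L
  draws <- sweep(draws, 2, fit$coefficients, "+")
  X <- build_design(nd, fit$terms, fit$xlevels)
  boot_se <- apply(plogis(X %*% t(draws)), 1, sd)
  expect_lt(max(abs(pr$se - boot_se) / boot_se), 0.1)
})

test_that("cross-validation is deterministic and MAE <= RMSE", {
  d <- make_calib_data(300, seed = 13)
  cv1 <- cross_validate(d, c("bi_s"), "sonotypes", "poisson_log",
                        repeats = 10, seed = 5)
  cv2 <- cross_validate(d, c("bi_s"), "sonotypes", "poisson_log",
                        repeats = 10, seed = 5)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  expect_true(all(cv1$per_repeat$mae <= cv1$per_repeat$rmse + 1e-12))
  expect_lte(cv1$mae_mean, cv1$rmse_mean)
})

test_that("cross-validation error vanishes on noiseless link-linear data", {
  set.seed(14)
  n <- 400
  d <- data.frame(bi_s = runif(n))
  d$sonotypes <- NA  # unused
  d$coverage <- plogis(-1 + 2 * d$bi_s)   # exact mean, no noise
  cv <- cross_validate(d, "bi_s", "coverage", "beta_logit", repeats = 3,
                       seed = 6)
  expect_lt(cv$rmse_mean, 1e-5)
  expect_lt(cv$mae_mean, 1e-5)
})
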