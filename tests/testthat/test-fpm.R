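# Flexible parametric model: likelihood, fitting, predictions.

test_that("df = 1 likelihood equals the closed-form Weibull likelihood", {
  d <- quick_data(n = 300, seed = 10)
  spec <- fpm_spec(df = 1, covariates = c("x", "comorb"))
  m <- fpm_fit(d, spec, event_cause = 1)
  bases <- list(baseline = m$baseline_basis, tvc = m$tvc_bases)
  # the orthogonalised log-time column is affine: v1(logt) = a0 + a1*logt
  v01 <- rcs(c(0, 1), m$baseline_basis)[, 1]
  a0 <- v01[1]; a1 <- v01[2] - v01[1]
  wb_loglik <- function(theta) {
    p <- theta[4] * a1                      # Weibull shape
    loglam <- theta[1] + theta[4] * a0      # log lambda
    lp <- loglam + cbind(d$covariates$x, d$covariates$comorb) %*%
      theta[2:3]
    H <- exp(lp) * d$time^p
    h <- exp(lp) * p * d$time^(p - 1)
    ev <- d$cause == 1
    sum(log(h[ev])) - sum(H)
  }
  for (theta in list(c(-4, 0.3, -0.2, 0.9), c(-3.5, 0, 0, 1.4),
                     m$coef)) {
    expect_equal(fpm_loglik(theta, d, spec, 1, bases = bases),
                 wb_loglik(theta), tolerance = 1e-10)
  }
})

test_that("stacking a dataset with itself doubles the log-likelihood", {
  d <- quick_data(n = 150, seed = 3)
  df2 <- data.frame(time = rep(d$time, 2), cause = rep(d$cause, 2),
                    x = rep(d$covariates$x, 2))
  dd <- survival_data(df2, covariates = "x")
  d1 <- survival_data(df2[seq_len(150), ], covariates = "x")
  spec <- fpm_spec(df = 2, covariates = "x")
  m <- fpm_fit(d1, spec, event_cause = 1)
  bases <- list(baseline = m$baseline_basis, tvc = m$tvc_bases)
  theta <- m$coef * 0.9
  expect_equal(fpm_loglik(theta, dd, spec, 1, bases = bases),
               2 * fpm_loglik(theta, d1, spec, 1, bases = bases),
               tolerance = 1e-12)
})

test_that("hazard, cumulative hazard and survival are mutually consistent", {
  d <- quick_data(n = 500, seed = 5)
  fits <- fit_pair(d, df = 3, tvc1 = "x")
  z <- c(x = 1, age1 = 0, age2 = 1, comorb = 0)
  t <- c(3, 12, 30, 50)
  for (m in list(fits$m1, fits$m2)) {
    # finite differences of H = -log S reproduce the hazard
    h <- predict_hazard(m, t, z)
    eps <- 1e-5 * t
    fd <- (predict_cumhaz(m, t + eps, z) -
             predict_cumhaz(m, t - eps, z)) / (2 * eps)
    expect_equal(h, fd, tolerance = 1e-6)
    # quadrature of the hazard reproduces survival
    S_direct <- predict_survival(m, t, z)
    S_quad <- vapply(t, function(tt) {
      exp(-integrate(function(u) predict_hazard(m, u, z), 0, tt,
                     rel.tol = 1e-9)$value)
    }, 0)
    expect_equal(S_direct, S_quad, tolerance = 1e-6)
  }
})

test_that("survival predictions: S(0) = 1, monotone, in [0, 1]", {
  d <- quick_data(n = 400, seed = 6)
  m <- fit_pair(d)$m1
  z <- c(x = 0, age1 = 1, age2 = 0, comorb = 1)
  tt <- seq(0, 60, by = 0.5)
  S <- predict_survival(m, tt, z)
  expect_identical(S[1], 1)
  expect_true(all(diff(S) <= 1e-12))
  expect_true(all(S >= 0 & S <= 1))
  expect_error(predict_survival(m, -1, z), ">= 0")
  expect_error(predict_hazard(m, 0, z), "> 0")
})

test_that("hazard ratios: constant exp(beta) under PH, time-dependent with tvc", {
  d <- quick_data(n = 800, seed = 8)
  fits <- fit_pair(d, df = 2)
  z1 <- c(x = 1, age1 = 0, age2 = 0, comorb = 0)
  z0 <- c(x = 0, age1 = 0, age2 = 0, comorb = 0)
  t <- c(6, 12, 36, 59)
  hr <- hazard_ratio(fits$m1, t, z1, z0)
  expect_equal(hr, rep(exp(fits$m1$coef[["x"]]), 4), tolerance = 1e-10)
  expect_equal(hazard_ratio(fits$m1, t, z1, z1), rep(1, 4))
  # with a time-dependent treatment effect the HR varies over time
  ftvc <- fit_pair(d, df = 2, tvc1 = "x")
  hr_tvc <- hazard_ratio(ftvc$m1, t, z1, z0)
  expect_gt(diff(range(hr_tvc)), 1e-4)
})

test_that("parameter recovery on simulated data (df = 1, n = 5000)", {
  d <- quick_data(n = 5000, seed = 20)
  m <- fpm_fit(d, fpm_spec(df = 1, covariates = ALL_COV),
               event_cause = 1)
  se <- sqrt(diag(m$vcov))[match("x", names(m$coef))]
  expect_lt(abs(m$coef[["x"]] - log(0.7)), 3 * se)
})

test_that("null covariate effect is not detected spuriously", {
  hits <- 0L
  for (r in 1:50) {
    d <- quick_data(n = 300, seed = 100 + r)
    set.seed(5000 + r)
    d$covariates$noise <- rbinom(d$n, 1, 0.5)
    m <- fpm_fit(d, fpm_spec(df = 2, covariates = c("x", "noise")),
                 event_cause = 1)
    se <- sqrt(diag(m$vcov))[match("noise", names(m$coef))]
    if (abs(m$coef[["noise"]]) < 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of 50 replicates
})

test_that("time-unit change rescales the hazard by the inverse factor", {
  d <- quick_data(n = 700, seed = 9)
  m_months <- fit_pair(d)$m1
  d_years <- d
  d_years$time <- d$time / 12
  d_years$horizon <- NULL
  m_years <- fpm_fit(d_years, fpm_spec(df = 2, covariates = ALL_COV),
                     event_cause = 1)
  z <- c(x = 1, age1 = 1, age2 = 0, comorb = 0)
  t_m <- c(6, 18, 40)
  expect_equal(predict_hazard(m_years, t_m / 12, z) / 12,
               predict_hazard(m_months, t_m, z), tolerance = 1e-4)
})

test_that("raw-basis refit changes coefficients but not predictions", {
  d <- quick_data(n = 500, seed = 12)
  spec <- fpm_spec(df = 3, covariates = c("x", "comorb"), tvc = "x",
                   dftvc = 2)
  m_ort <- fpm_fit(d, spec, 1, orthogonal = TRUE)
  m_raw <- fpm_fit(d, spec, 1, orthogonal = FALSE)
  expect_gt(max(abs(m_ort$coef - m_raw$coef)), 0.01)
  expect_equal(m_ort$loglik, m_raw$loglik, tolerance = 1e-8)
  z <- c(x = 1, comorb = 1)
  tt <- c(2, 10, 25, 55)
  expect_equal(predict_survival(m_ort, tt, z),
               predict_survival(m_raw, tt, z), tolerance = 1e-8)
  expect_equal(predict_hazard(m_ort, tt, z),
               predict_hazard(m_raw, tt, z), tolerance = 1e-6)
})

test_that("optimum is a true maximum; analytic information matches FD route", {
  d <- quick_data(n = 500, seed = 14)
  m <- fit_pair(d, df = 2)$m1
  expect_lt(m$grad_norm, 1e-3)
  ev <- eigen(m$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))  # Hessian negative definite at the optimum
  I_fd <- crstand:::fd_information(d, m)
  I_an <- solve(m$vcov)
  expect_equal(I_fd, I_an, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("degenerate covariates are rejected by name", {
  d <- quick_data(n = 200, seed = 15)
  d$covariates$flat <- 1
  expect_error(fpm_fit(d, fpm_spec(df = 2, covariates = c("x", "flat")),
                       1), "flat")
})

test_that("model JSON round trip is bit-exact", {
  d <- quick_data(n = 300, seed = 16)
  m <- fit_pair(d, df = 2, tvc1 = "x")$m1
  path <- withr::local_tempfile(fileext = ".json")
  fpm_save(m, path)
  m2 <- fpm_load(path)
  expect_identical(m2$coef, m$coef)
  expect_identical(unname(m2$vcov), unname(m$vcov))
  expect_identical(m2$baseline_basis$knots$values,
                   m$baseline_basis$knots$values)
  expect_identical(m2$baseline_basis$Rmat, m$baseline_basis$Rmat)
  z <- c(x = 1, age1 = 0, age2 = 0, comorb = 1)
  expect_identical(predict_survival(m2, c(5, 30, 55), z),
                   predict_survival(m, c(5, 30, 55), z))
})
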