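# Regression standardisation: failure probabilities, CIFs, RMFT,
# contrasts, delta-method inference, separable effects.

test_that("single-subject standardisation equals the conditional prediction", {
  d <- quick_data(n = 250, seed = 41)
  m <- fit_pair(d)$m1
  d1 <- survival_data(
    data.frame(time = d$time[1], cause = max(d$cause[1], 1),
               x = 1, age1 = 0, age2 = 1, comorb = 0),
    covariates = c("x", "age1", "age2", "comorb"))
  tt <- c(0, 10, 40)
  cv <- std_failure(m, d1, at_spec(x = 1), tt)
  z <- c(x = 1, age1 = 0, age2 = 1, comorb = 0)
  expect_equal(cv$estimate, 1 - predict_survival(m, tt, z))
  # non-marginal mode (first row only) on the full data: identical idea
  cv2 <- std_failure(m, d, at_spec(x = 1, age1 = 0, age2 = 1,
                                   comorb = 0, subset_first = TRUE),
                     tt)
  expect_equal(cv2$estimate, cv$estimate, tolerance = 1e-12)
})

test_that("failure/CIF curves start at 0 with SE 0 and are monotone in [0,1]", {
  d <- quick_data(n = 400, seed = 42)
  fits <- fit_pair(d, df = 2, tvc1 = "x")
  tt <- seq(0, 60, length.out = 25)
  fc <- std_failure(fits$m1, d, at_spec(x = 1), tt)
  cc <- std_cif(fits$set, d, at_spec(x = 1), tt, cause = "cancer")
  for (cv in list(fc, cc)) {
    expect_identical(cv$estimate[1], 0)
    expect_identical(cv$se[1], 0)
    expect_true(all(diff(cv$estimate) >= -1e-10))
    expect_true(all(cv$estimate >= 0 & cv$estimate <= 1))
    expect_true(all(cv$ci_low <= cv$estimate + 1e-12 &
                      cv$estimate <= cv$ci_high + 1e-12))
  }
})

test_that("cause-specific CIFs and all-cause survival sum to one", {
  d <- quick_data(n = 400, seed = 43)
  fits <- fit_pair(d, df = 2)
  tt <- seq(0, 60, length.out = 21)
  at <- at_spec(x = 1)
  c1 <- std_cif(fits$set, d, at, tt, cause = "cancer", nodes = 100)
  c2 <- std_cif(fits$set, d, at, tt, cause = "other", nodes = 100)
  sa <- std_survival(fits$set, d, at, tt)
  expect_equal(c1$estimate + c2$estimate + sa$estimate,
               rep(1, length(tt)), tolerance = 1e-6)
})

test_that("estimates and SEs are invariant to row permutation", {
  d <- quick_data(n = 300, seed = 44)
  perm <- sample(d$n)
  dp <- d
  dp$time <- d$time[perm]; dp$cause <- d$cause[perm]
  dp$covariates <- d$covariates[perm, ]
  fits <- fit_pair(d)
  # reuse the models (fit is permutation-invariant only up to optimiser
  # noise); standardisation itself must be exactly order-invariant
  tt <- c(0, 12, 36, 60)
  a <- std_cif(fits$set, d, at_spec(x = 0), tt, cause = "cancer")
  b <- std_cif(fits$set, dp, at_spec(x = 0), tt, cause = "cancer")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("delta method: exact for linear maps, closed form for exp", {
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  a <- c(2, -1)
  se_lin <- delta_method(function(th) sum(a * th), c(0.5, 1.2), V)
  # central differences are exact for linear maps up to rounding
  expect_equal(se_lin, sqrt(drop(a %*% V %*% a)), tolerance = 1e-8)
  se_exp <- delta_method(function(th) exp(th[1]), c(0.7, 0), V)
  expect_equal(se_exp, exp(0.7) * sqrt(V[1, 1]), tolerance = 1e-6)
  # finite estimate with a non-finite Jacobian entry must error
  expect_error(delta_method(function(th) if (th[1] > 0.5) Inf else 1,
                            c(0.5, 1), V), "Jacobian")
})

test_that("contrasts: self-difference is exactly 0, self-ratio 1, NaN at 0/0", {
  d <- quick_data(n = 300, seed = 45)
  fits <- fit_pair(d)
  tt <- c(0, 12, 36)
  cv <- std_cif(fits$set, d, at_spec(x = 1), tt, cause = "cancer")
  dd <- contrast(list(cv, cv), kind = "difference")
  expect_identical(dd$contrasts[[1]]$estimate, rep(0, 3))
  expect_identical(dd$contrasts[[1]]$se, rep(0, 3))
  rr <- contrast(list(cv, cv), kind = "ratio")
  expect_true(is.nan(rr$contrasts[[1]]$estimate[1]))  # 0/0 at t = 0
  expect_equal(rr$contrasts[[1]]$estimate[-1], rep(1, 2))
})

test_that("lincom over cause-specific RMFTs equals the sum of the parts", {
  d <- quick_data(n = 250, seed = 46)
  fits <- fit_pair(d)
  at <- at_spec(x = 0)
  r1 <- suppressWarnings(std_rmft(fits$set, d, at, 48, cause = "cancer"))
  r2 <- suppressWarnings(std_rmft(fits$set, d, at, 48, cause = "other"))
  lc <- contrast(list(r1, r2), kind = "lincom", coef = c(1, 1))
  expect_equal(lc$contrasts[[1]]$estimate, r1$estimate + r2$estimate,
               tolerance = 1e-10)
  expect_error(contrast(list(r1, r2), kind = "lincom"), "coefficient")
})

test_that("RMFT matches trapezoidal integration of the CIF curve", {
  d <- quick_data(n = 120, seed = 47)
  fits <- fit_pair(d)
  at <- at_spec(x = 1)
  tstar <- 40
  r <- std_rmft(fits$set, d, at, tstar, cause = "cancer")
  grid <- seq(0, tstar, by = 0.05)
  cif <- std_cif(fits$set, d, at, grid, cause = "cancer",
                 check_nodes = FALSE)
  trap <- sum(diff(grid) * (head(cif$estimate, -1) +
                              tail(cif$estimate, -1)) / 2)
  expect_equal(r$estimate, trap, tolerance = 0.01)
  # t* = 0 -> exactly 0; monotone in t*
  expect_identical(std_rmft(fits$set, d, at, 0,
                            cause = "cancer")$estimate, 0)
  r2 <- suppressWarnings(std_rmft(fits$set, d, at, 55, cause = "cancer"))
  expect_gt(r2$estimate, r$estimate)
})

test_that("at-setting validation: unknown names error, off-support warns", {
  d <- quick_data(n = 200, seed = 48)
  fits <- fit_pair(d)
  expect_error(std_failure(fits$m1, d, at_spec(bogus = 1), c(0, 10)),
               "bogus")
  expect_error(std_cif(fits$set, d, at_spec(bogus = 1), c(0, 10),
                       cause = "cancer"), "bogus")
  expect_warning(std_failure(fits$m1, d, at_spec(x = 3), c(0, 10)),
                 "outside the observed support")
})

test_that("separable machinery: clones collapse to the total effect", {
  d <- quick_data(n = 400, seed = 49)
  cov_c <- c("x_c", "age1", "age2", "comorb")
  cov_o <- c("x_o", "age1", "age2", "comorb")
  mc <- fpm_fit(d, fpm_spec(df = 2, covariates = cov_c), 1,
                label = "cancer")
  mo <- fpm_fit(d, fpm_spec(df = 2, covariates = cov_o), 2,
                label = "other")
  mx1 <- fpm_fit(d, fpm_spec(df = 2, covariates = ALL_COV[1:4]), 1,
                 label = "cancer")
  mx2 <- fpm_fit(d, fpm_spec(df = 2, covariates = ALL_COV[1:4]), 2,
                 label = "other")
  clone_set <- cause_model_set(mc, mo)
  x_set <- cause_model_set(mx1, mx2)
  tt <- c(0, 12, 36)
  collapsed <- std_cif(clone_set, d, at_spec(x_c = 1, x_o = 1), tt,
                       cause = "cancer")
  total <- std_cif(x_set, d, at_spec(x = 1), tt, cause = "cancer")
  expect_equal(collapsed$estimate, total$estimate, tolerance = 1e-12)
  # full separable run with the canonical pairs
  sep <- separable_effects(clone_set, d, x_c = "x_c", x_o = "x_o",
                           times = tt, cause = "cancer")
  expect_length(sep$curves, 3L)
  expect_equal(sep$total$contrasts[[1]]$estimate,
               std_cif(x_set, d, at_spec(x = 1), tt,
                       cause = "cancer")$estimate -
                 std_cif(x_set, d, at_spec(x = 0), tt,
                         cause = "cancer")$estimate,
               tolerance = 1e-10)
  # tampered clone is rejected
  dbad <- d
  dbad$covariates$x_c[1] <- 1 - dbad$covariates$x_c[1]
  expect_error(separable_effects(clone_set, dbad, "x_c", "x_o", tt,
                                 cause = "cancer"), "exact copy")
  # model/clone mismatch is rejected
  expect_error(separable_effects(x_set, d, "x_c", "x_o", tt,
                                 cause = "cancer"), "must contain")
})

test_that("std_cif needs two models and a known cause label", {
  d <- quick_data(n = 200, seed = 50)
  fits <- fit_pair(d)
  expect_error(std_cif(cause_model_set(list(fits$m1)), d, at_spec(x = 1),
                       c(0, 10), cause = "cancer"), "at least 2")
  expect_error(std_cif(fits$set, d, at_spec(x = 1), c(0, 10),
                       cause = "nope"), "unknown cause")
})
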