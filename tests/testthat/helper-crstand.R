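# Shared fixtures, all built in code.

ALL_COV <- c("x", "age1", "age2", "comorb")

quick_data <- function(n = 600, seed = 1, ...) {
  simulate_crdata(sim_spec(n = n, seed = seed, ...))
}

# A pair of cause-specific fits (df = 2 PH by default) plus the model set.
fit_pair <- function(data, df = 2, covariates = ALL_COV,
                     tvc1 = character(0), dftvc1 = 2) {
  m1 <- fpm_fit(data, fpm_spec(df = df, covariates = covariates,
                               tvc = tvc1, dftvc = dftvc1),
                event_cause = 1, label = "cancer")
  m2 <- fpm_fit(data, fpm_spec(df = df, covariates = covariates),
                event_cause = 2, label = "other")
  list(m1 = m1, m2 = m2, set = cause_model_set(m1, m2))
}

# Tiny raw table in the hbiostat prostate schema (synthetic stand-in for
# the real download; only used to test the preparation rules).
make_prostate_raw <- function() {
  data.frame(
    rx = c("placebo", "placebo", "5.0 mg estrogen", "5.0 mg estrogen",
           "0.2 mg estrogen", "1.0 mg estrogen", "5.0 mg estrogen",
           "placebo"),
    status = c("alive", "dead - prostatic ca", "dead - heart or vascular",
               "alive", "alive", "dead - prostatic ca",
               "dead - other ca", "dead - cerebrovascular"),
    age = c(55, 59, 60, 74, 75, 80, 68, 77),
    hg = c(12.0, 11.9, 13.4, 9.8, 12.1, 14.0, 11.99, 12.01),
    hx = c(0, 1, 0, 1, 0, 1, 0, 0),
    pf = c("normal activity", "in bed < 50% daytime", "normal activity",
           "normal activity", "confined to bed", "normal activity",
           "in bed < 50% daytime", "normal activity"),
    dtime = c(60, 14, 30, 55, 40, 8, 22, 47),
    stringsAsFactors = FALSE
  )
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
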