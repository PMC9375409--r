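#' Specify a flexible parametric survival model
#'
#' Model on the log cumulative hazard scale:
#' \deqn{\log H(t \mid z) = s(\log t; \gamma) + z'\beta +
#'   \sum_j s_j(\log t; \delta_j) z_j}
#' with \eqn{s} a restricted cubic spline of log time with \code{df} basis
#' columns and, for each covariate in \code{tvc}, a time-dependent effect
#' \eqn{s_j} with \code{dftvc} columns (a spline-by-covariate interaction;
#' the proportional-effect \eqn{\beta_j} acts as its intercept).
#'
#' @param df baseline spline degrees of freedom (number of basis columns;
#'   the spline uses \code{df + 1} knots).
#' @param covariates character vector of covariate names.
#' @param tvc subset of \code{covariates} given time-dependent effects.
#' @param dftvc degrees of freedom for each time-dependent effect; scalar
#'   (recycled) or named vector.
#' @return An object of class \code{"fpm_spec"}.
#' @export
fpm_spec <- function(df = 3L, covariates = character(),
                     tvc = character(), dftvc = 2L) {
  df <- as.integer(df)
  stopifnot(df >= 1L)
  if (length(bad <- setdiff(tvc, covariates))) {
    stop("tvc covariates not in covariate list: ",
         paste(bad, collapse = ", "))
  }
  if (length(tvc)) {
    if (is.null(names(dftvc))) {
      dftvc <- stats::setNames(rep(as.integer(dftvc),
                                   length.out = length(tvc)), tvc)
    } else {
      dftvc <- stats::setNames(as.integer(dftvc[tvc]), tvc)
    }
    if (any(is.na(dftvc)) || any(dftvc < 1L)) stop("dftvc must be >= 1")
  } else dftvc <- stats::setNames(integer(0), character(0))
  structure(list(df = df, covariates = covariates, tvc = tvc,
                 dftvc = dftvc, scale = "log cumulative hazard"),
            class = "fpm_spec")
}

## Parameter layout: (Intercept) | beta (covariates) | gamma (_rcs1..df) |
## for each tvc v: delta_v (_rcs_<v>1..dftvc[v])
param_names <- function(spec) {
  nm <- c("(Intercept)", spec$covariates,
          paste0("_rcs", seq_len(spec$df)))
  for (v in spec$tvc) {
    nm <- c(nm, paste0("_rcs_", v, seq_len(spec$dftvc[[v]])))
  }
  nm
}

param_index <- function(spec) {
  p0 <- 1L
  nb <- length(spec$covariates)
  idx <- list(intercept = 1L,
              beta = if (nb) 1L + seq_len(nb) else integer(0),
              gamma = 1L + nb + seq_len(spec$df))
  pos <- 1L + nb + spec$df
  idx$delta <- list()
  for (v in spec$tvc) {
    idx$delta[[v]] <- pos + seq_len(spec$dftvc[[v]])
    pos <- pos + spec$dftvc[[v]]
  }
  idx$npar <- pos
  idx
}

## Build per-row design matrices for the linear predictor eta and its
## derivative with respect to log time (rows of logt aligned with rows
## of Z).
fpm_design <- function(spec, bases, logt, Z) {
  n <- length(logt)
  B <- rcs(logt, bases$baseline)
  Bd <- rcs_derivative(logt, bases$baseline)
  X <- cbind(1, Z, B)
  D <- cbind(0, matrix(0, n, ncol(Z)), Bd)
  for (v in spec$tvc) {
    Bv <- rcs(logt, bases$tvc[[v]])
    Bvd <- rcs_derivative(logt, bases$tvc[[v]])
    X <- cbind(X, Bv * Z[, v])
    D <- cbind(D, Bvd * Z[, v])
  }
  list(X = X, D = D)
}

build_bases <- function(spec, data, event_cause, knots = NULL,
                        orthogonal = TRUE) {
  logt <- log(data$time)
  ev_logt <- logt[data$cause == event_cause]
  if (!length(ev_logt)) stop("no events of cause ", event_cause)
  base_knots <- if (!is.null(knots$baseline)) knots$baseline else
    place_knots(ev_logt, spec$df)
  bases <- list(baseline = spline_basis(base_knots, x = logt,
                                        orthogonal = orthogonal))
  bases$tvc <- list()
  for (v in spec$tvc) {
    kv <- if (!is.null(knots$tvc[[v]])) knots$tvc[[v]] else
      place_knots(ev_logt, spec$dftvc[[v]])
    bases$tvc[[v]] <- spline_basis(kv, x = logt, orthogonal = orthogonal,
                                   column_prefix = paste0("_rcs_", v))
  }
  bases
}

covariate_matrix <- function(data, covariates) {
  if (!length(covariates)) return(matrix(0, data$n, 0))
  miss <- setdiff(covariates, names(data$covariates))
  if (length(miss)) stop("covariates not in data: ",
                         paste(miss, collapse = ", "))
  as.matrix(data$covariates[covariates])
}

## Smooth penalty for a non-positive spline slope at an event time:
## log(ds) is extended linearly (C1) below kappa so the likelihood stays
## finite and the optimiser is repelled from hazard-negative regions.
.kappa <- 1e-8

safe_log_ds <- function(ds) {
  ifelse(ds > .kappa, log(pmax(ds, .kappa)),
         log(.kappa) + (ds - .kappa) / .kappa)
}

safe_dlog_ds <- function(ds) ifelse(ds > .kappa, 1 / ds, 1 / .kappa)

.eta_cap <- 690

#' Log-likelihood of a flexible parametric survival model
#'
#' Cause-specific likelihood: rows failing from \code{event_cause}
#' contribute \eqn{\log h(t_i)}; all rows contribute \eqn{-H(t_i)}
#' (deaths from other causes are censored at their death time).
#'
#' @param params coefficient vector in the layout
#'   (intercept, covariate effects, baseline spline, tvc splines).
#' @param data a [survival_data()] object.
#' @param spec an [fpm_spec()].
#' @param event_cause integer cause code this model describes.
#' @param bases optional pre-built spline bases (internal reuse); by
#'   default built from the data (knots on the event times of
#'   \code{event_cause}).
#' @param knots optional list with elements \code{baseline} and
#'   \code{tvc} of [knot_set()] overrides.
#' @return scalar log-likelihood.
#' @export
fpm_loglik <- function(params, data, spec, event_cause = 1L,
                       bases = NULL, knots = NULL) {
  stopifnot(inherits(data, "survival_data"), inherits(spec, "fpm_spec"))
  if (is.null(bases)) bases <- build_bases(spec, data, event_cause, knots)
  Z <- covariate_matrix(data, spec$covariates)
  des <- fpm_design(spec, bases, log(data$time), Z)
  d <- as.numeric(data$cause == event_cause)
  .loglik_core(params, des, d, log(data$time))
}

.loglik_core <- function(theta, des, d, logt) {
  eta <- drop(des$X %*% theta)
  ds <- drop(des$D %*% theta)
  H <- exp(pmin(eta, .eta_cap))
  sum(d * (safe_log_ds(ds) - logt + eta)) - sum(H)
}

.grad_core <- function(theta, des, d, logt) {
  eta <- drop(des$X %*% theta)
  ds <- drop(des$D %*% theta)
  H <- exp(pmin(eta, .eta_cap))
  drop(crossprod(des$X, d - H) + crossprod(des$D, d * safe_dlog_ds(ds)))
}

hess_core <- function(theta, des, d, logt) {
  eta <- drop(des$X %*% theta)
  ds <- drop(des$D %*% theta)
  H <- exp(pmin(eta, .eta_cap))
  term1 <- -crossprod(des$X, des$X * H)
  w2 <- d * ifelse(ds > .kappa, 1 / ds^2, 0)
  term2 <- -crossprod(des$D, des$D * w2)
  term1 + term2
}

weibull_start <- function(data, spec, d, Z, bases) {
  logt <- log(data$time)
  init <- tryCatch({
    fml <- if (ncol(Z)) survival::Surv(data$time, d) ~ Z else
      survival::Surv(data$time, d) ~ 1
    wb <- survival::survreg(fml, dist = "weibull")
    a <- 1 / wb$scale
    cc <- -wb$coefficients[1] / wb$scale
    bb <- if (ncol(Z)) -wb$coefficients[-1] / wb$scale else numeric(0)
    list(a = a, c = cc, beta = bb)
  }, error = function(e) {
    list(a = 1, c = log(max(sum(d), 1) / sum(data$time)),
         beta = rep(0, ncol(Z)))
  })
  ## express c + a*log(t) in the (1, orthogonalised baseline) columns
  B <- rcs(logt, bases$baseline)
  target <- init$c + init$a * logt
  th_time <- qr.solve(cbind(1, B), target)
  idx <- param_index(spec)
  theta <- numeric(idx$npar)
  theta[idx$intercept] <- th_time[1]
  theta[idx$gamma] <- th_time[-1]
  theta[idx$beta] <- init$beta
  theta
}

#' Fit a flexible parametric cause-specific survival model
#'
#' Maximum likelihood on the log cumulative hazard scale.  Deaths from
#' causes other than \code{event_cause} are treated as censored at their
#' death time (cause-specific hazard modelling).  Baseline (and tvc) knots
#' default to equally spaced centiles of the log event times of the
#' modelled cause; pass \code{knots} to override.  Optimisation is BFGS
#' from Weibull starting values followed by Newton polishing with the
#' analytic Hessian; \code{vcov} is the inverse observed information.
#'
#' @inheritParams fpm_loglik
#' @param label short name for the model (used in standardisation output).
#' @param orthogonal orthogonalise the spline bases (default TRUE; FALSE
#'   refits in the raw truncated-power parameterisation, which changes
#'   coefficients but not predictions).
#' @param control list: \code{maxit} (BFGS iterations, default 500),
#'   \code{gtol} (max gradient norm at the optimum, default 1e-5).
#' @return Object of class \code{"fpm"}: spec, bases, named \code{coef},
#'   \code{vcov}, \code{loglik}, \code{event_cause}, fit diagnostics.
#' @export
fpm_fit <- function(data, spec, event_cause = 1L, knots = NULL,
                    label = paste0("cause", event_cause),
                    orthogonal = TRUE, control = list()) {
  stopifnot(inherits(data, "survival_data"), inherits(spec, "fpm_spec"))
  maxit <- control$maxit %||% 500L
  gtol <- control$gtol %||% 1e-5
  Z <- covariate_matrix(data, spec$covariates)
  for (j in seq_len(ncol(Z))) {
    if (stats::sd(Z[, j]) == 0) {
      stop("degenerate covariate (constant column): ",
           spec$covariates[j])
    }
  }
  bases <- build_bases(spec, data, event_cause, knots, orthogonal)
  logt <- log(data$time)
  des <- fpm_design(spec, bases, logt, Z)
  d <- as.numeric(data$cause == event_cause)
  nll <- function(th) -.loglik_core(th, des, d, logt)
  ngr <- function(th) -.grad_core(th, des, d, logt)
  theta0 <- weibull_start(data, spec, d, Z, bases)
  opt <- stats::optim(theta0, nll, ngr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-8))
  theta <- opt$par
  ## Newton polish with analytic Hessian (step-halving safeguard)
  ll <- .loglik_core(theta, des, d, logt)
  for (it in seq_len(40L)) {
    g <- .grad_core(theta, des, d, logt)
    if (max(abs(g)) < gtol) break
    Hm <- hess_core(theta, des, d, logt)
    step <- tryCatch(solve(Hm, -g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- theta + lam * step
      llc <- .loglik_core(cand, des, d, logt)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- theta; llc <- ll; break }
    }
    if (identical(cand, theta)) break  # no further progress possible
    theta <- cand; ll <- llc
  }
  g <- .grad_core(theta, des, d, logt)
  if (max(abs(g)) > gtol * 100) {
    stop("fpm_fit did not converge: max |gradient| = ",
         format(max(abs(g))))
  }
  Hm <- hess_core(theta, des, d, logt)
  vc <- tryCatch(solve(-Hm), error = function(e) {
    stop("observed information is singular at the optimum")
  })
  vc <- (vc + t(vc)) / 2
  nm <- param_names(spec)
  structure(list(spec = spec,
                 baseline_basis = bases$baseline,
                 tvc_bases = bases$tvc,
                 coef = stats::setNames(theta, nm),
                 vcov = structure(vc, dimnames = list(nm, nm)),
                 loglik = ll,
                 event_cause = as.integer(event_cause),
                 label = label,
                 n = data$n,
                 n_events = sum(d),
                 grad_norm = max(abs(g)),
                 orthogonal = orthogonal),
            class = "fpm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fpm <- function(x, ...) {
  cat("Flexible parametric survival model (log cumulative hazard scale)\n")
  cat("  label:", x$label, " cause:", x$event_cause,
      " events:", x$n_events, "/", x$n, "\n")
  cat("  baseline df:", x$spec$df)
  if (length(x$spec$tvc)) {
    cat("; tvc:", paste(sprintf("%s(df=%d)", x$spec$tvc,
                                x$spec$dftvc[x$spec$tvc]),
                        collapse = ", "))
  }
  cat("\n  log-likelihood:", format(x$loglik), "\n")
  hr <- exp(x$coef[x$spec$covariates])
  if (length(hr)) {
    cat("  prop. hazard ratios:\n")
    print(round(hr, 4))
  }
  invisible(x)
}

#' @export
logLik.fpm <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' @export
coef.fpm <- function(object, ...) object$coef

#' @export
vcov.fpm <- function(object, ...) object$vcov

## eta and d eta / d log t for n covariate rows at q times (n x q each)
eta_ds_mats <- function(model, theta, Zmat, u) {
  logu <- log(u)
  spec <- model$spec
  idx <- param_index(spec)
  B <- rcs(logu, model$baseline_basis)
  Bd <- rcs_derivative(logu, model$baseline_basis)
  a_time <- theta[idx$intercept] + drop(B %*% theta[idx$gamma])
  d_time <- drop(Bd %*% theta[idx$gamma])
  n <- nrow(Zmat)
  zb <- if (length(idx$beta)) drop(Zmat %*% theta[idx$beta]) else
    rep(0, n)
  eta <- outer(zb, a_time, `+`)
  ds <- matrix(d_time, n, length(u), byrow = TRUE)
  for (v in spec$tvc) {
    Bv <- rcs(logu, model$tvc_bases[[v]])
    Bvd <- rcs_derivative(logu, model$tvc_bases[[v]])
    av <- drop(Bv %*% theta[idx$delta[[v]]])
    dv <- drop(Bvd %*% theta[idx$delta[[v]]])
    eta <- eta + outer(Zmat[, v], av)
    ds <- ds + outer(Zmat[, v], dv)
  }
  list(eta = eta, ds = ds)
}

zrow_matrix <- function(model, z) {
  cv <- model$spec$covariates
  if (!length(cv)) return(matrix(0, 1, 0))
  if (is.data.frame(z)) z <- unlist(z[1, , drop = TRUE])
  z <- unlist(as.list(z))
  miss <- setdiff(cv, names(z))
  if (length(miss)) stop("covariate value(s) missing: ",
                         paste(miss, collapse = ", "))
  matrix(as.numeric(z[cv]), 1, length(cv),
         dimnames = list(NULL, cv))
}

#' Predicted survival from a fitted model
#'
#' \eqn{S(t|z) = \exp(-\exp(\eta(t,z)))}; \eqn{S(0) = 1} by convention.
#'
#' @param model a fitted \code{"fpm"}.
#' @param t non-negative times.
#' @param z named covariate values (one row).
#' @return vector of survival probabilities.
#' @export
predict_survival <- function(model, t, z = NULL) {
  stopifnot(inherits(model, "fpm"))
  if (any(t < 0)) stop("t must be >= 0")
  out <- rep(1, length(t))
  pos <- t > 0
  if (any(pos)) {
    Zm <- zrow_matrix(model, z)
    m <- eta_ds_mats(model, model$coef, Zm, t[pos])
    out[pos] <- exp(-exp(pmin(m$eta[1, ], .eta_cap)))
  }
  out
}

#' Predicted cause-specific hazard
#'
#' \eqn{h(t|z) = t^{-1} \, (\partial s_{tot}/\partial \log t) \,
#' \exp(\eta(t,z))}.  A warning (not an error) is issued if the spline
#' slope makes the hazard negative anywhere on the requested grid.
#'
#' @inheritParams predict_survival
#' @param t strictly positive times.
#' @return vector of hazards.
#' @export
predict_hazard <- function(model, t, z = NULL) {
  stopifnot(inherits(model, "fpm"))
  if (any(t <= 0)) stop("t must be > 0")
  Zm <- zrow_matrix(model, z)
  m <- eta_ds_mats(model, model$coef, Zm, t)
  h <- m$ds[1, ] * exp(pmin(m$eta[1, ], .eta_cap)) / t
  if (any(h < 0)) warning("negative predicted hazard at some times ",
                          "(spline slope < 0 off the event region)")
  h
}

#' Predicted cumulative hazard
#' @inheritParams predict_hazard
#' @return vector of \eqn{H(t|z)}.
#' @export
predict_cumhaz <- function(model, t, z = NULL) {
  -log(predict_survival(model, t, z))
}

#' Hazard ratio between two covariate patterns
#'
#' Elementwise \eqn{h(t|z_1)/h(t|z_0)}.  Constant and equal to
#' \eqn{\exp(\beta)} differences under proportional hazards; varies with
#' \code{t} when the contrasted covariates carry time-dependent effects.
#' Points with zero denominator hazard are returned as \code{NaN} with a
#' warning.
#'
#' @inheritParams predict_hazard
#' @param z1,z0 named covariate rows (numerator, denominator).
#' @return vector of hazard ratios.
#' @export
hazard_ratio <- function(model, t, z1, z0) {
  h1 <- predict_hazard(model, t, z1)
  h0 <- predict_hazard(model, t, z0)
  if (any(h0 == 0)) warning("zero denominator hazard; returning NaN")
  ifelse(h0 == 0, NaN, h1 / h0)
}

## Observed information via central finite differences of the analytic
## gradient (validation route for the analytic Hessian).
fd_information <- function(data, model) {
  spec <- model$spec
  Z <- covariate_matrix(data, spec$covariates)
  logt <- log(data$time)
  bases <- list(baseline = model$baseline_basis, tvc = model$tvc_bases)
  des <- fpm_design(spec, bases, logt, Z)
  d <- as.numeric(data$cause == model$event_cause)
  th <- model$coef
  p <- length(th)
  Hn <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hstep <- 1e-5 * (1 + abs(th[j]))
    tp <- th; tp[j] <- tp[j] + hstep
    tm <- th; tm[j] <- tm[j] - hstep
    Hn[, j] <- (.grad_core(tp, des, d, logt) -
                  .grad_core(tm, des, d, logt)) / (2 * hstep)
  }
  -(Hn + t(Hn)) / 2
}
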