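#' Kaplan-Meier product-limit estimator
#'
#' Survival step curve with Greenwood standard errors.  Tie convention:
#' deaths precede censorings at tied times (subjects censored at t are
#' still at risk for deaths at t).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @return Object of class \code{"step_curve"}: data.frame with columns
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{surv}, \code{se}; attribute \code{"scale"} = "survival".
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("time must be > 0")
  event <- as.integer(event != 0)
  if (all(event == 0)) warning("all observations censored; S(t) = 1")
  n <- length(time)
  tu <- sort(unique(time))
  ix <- match(time, tu)
  ev_tab <- tabulate(ix[event == 1], nbins = length(tu))
  cn_tab <- tabulate(ix[event == 0], nbins = length(tu))
  ## at risk just before tu[j]: everyone with time >= tu[j]
  risk_tab <- n - c(0, cumsum(ev_tab + cn_tab))[seq_along(tu)]
  keep <- ev_tab > 0
  ut <- tu[keep]
  n_risk <- risk_tab[keep]
  n_event <- ev_tab[keep]
  n_censor <- cn_tab[keep]
  surv <- cumprod((n_risk - n_event) / n_risk)
  ## Greenwood
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  se <- surv * sqrt(ifelse(is.finite(gw), gw, NA))
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv, se = se),
            class = c("step_curve", "data.frame"), scale = "survival")
}

#' Evaluate a step curve (right-continuous)
#' @param curve a \code{"step_curve"}.
#' @param t times at which to read the curve.
#' @param column which value column (default the curve's main value).
#' @return numeric vector.
#' @export
step_eval <- function(curve, t, column = NULL) {
  if (is.null(column)) {
    column <- if (identical(attr(curve, "scale"), "survival"))
      "surv" else "cif"
  }
  start <- if (identical(attr(curve, "scale"), "survival")) 1 else 0
  vals <- c(start, curve[[column]])
  idx <- findInterval(t, curve$time) + 1L
  vals[idx]
}

#' Aalen-Johansen estimator of cause-specific cumulative incidence
#'
#' \deqn{\widehat{CIF}_k(t) = \sum_{t_j \le t} \hat S(t_j-)
#'   \, e_{kj} / n_j} with \eqn{\hat S} the all-cause Kaplan-Meier
#' survival.  Point estimates only (used as a nonparametric oracle and
#' for descriptive plots); with a single cause it reduces exactly to
#' \eqn{1 - \hat S}.
#'
#' @param time positive follow-up times.
#' @param cause integer codes 0 (censored) .. K.
#' @return named list, one \code{"step_curve"} per cause (columns
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{cif}) plus
#'   \code{"overall"}, the all-cause Kaplan-Meier curve.
#' @export
aalen_johansen <- function(time, cause) {
  stopifnot(length(time) == length(cause))
  if (any(time <= 0)) stop("time must be > 0")
  cause <- as.integer(cause)
  K <- max(cause, 0L)
  km <- kaplan_meier(time, as.integer(cause > 0))
  ut <- km$time
  ## S(t-): survival just before each jump
  S_minus <- c(1, km$surv[-length(km$surv)])
  out <- list()
  for (k in seq_len(K)) {
    sel <- cause == k
    ek <- tabulate(match(time[sel], ut), nbins = length(ut))
    cif <- cumsum(S_minus * ek / km$n_risk)
    out[[paste0("cause", k)]] <-
      structure(data.frame(time = ut, n_risk = km$n_risk, n_event = ek,
                           cif = cif),
                class = c("step_curve", "data.frame"), scale = "cif")
  }
  out$overall <- km
  out
}

#' Export a step curve to CSV
#' @param curve a \code{"step_curve"}.
#' @param path output path.
#' @export
write_step_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Plot Kaplan-Meier failure curves by group
#'
#' Failure scale (1 - S), one step curve per group level.
#'
#' @param time positive follow-up times.
#' @param event 0/1 all-cause event indicator.
#' @param group grouping vector (e.g. treatment arm).
#' @param xlab,ylab,main usual graphics labels.
#' @export
plot_km_failure <- function(time, event, group,
                            xlab = "Months since randomisation",
                            ylab = "Probability of death",
                            main = "All-cause failure by group") {
  levs <- sort(unique(group))
  graphics::plot(NULL, xlim = c(0, max(time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main)
  for (i in seq_along(levs)) {
    sel <- group == levs[i]
    km <- kaplan_meier(time[sel], event[sel])
    graphics::lines(stats::stepfun(km$time, c(0, 1 - km$surv)),
                    do.points = FALSE, col = i, lty = i)
  }
  graphics::legend("topleft", legend = paste("group", levs),
                   col = seq_along(levs), lty = seq_along(levs),
                   bty = "n")
  invisible(NULL)
}
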