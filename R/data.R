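#' Declare a competing-risks survival dataset
#'
#' One row per subject: a strictly positive follow-up time, an integer
#' cause code (0 = censored/alive, 1..K = cause of death) and a numeric
#' covariate matrix (binary/dummy or spline-expanded continuous columns).
#' Administrative censoring at \code{horizon} is applied here: rows with
#' \code{time > horizon} are censored at the horizon.
#'
#' @param data a data.frame.
#' @param time name of the follow-up time column (months).
#' @param cause name of the cause-of-death column (integers 0..K).
#' @param covariates character vector of covariate column names.
#' @param treatment optional name of the binary treatment column (must be
#'   one of \code{covariates}).
#' @param horizon optional administrative censoring time (> 0).
#' @param cause_labels optional character vector naming causes 1..K.
#' @return An object of class \code{"survival_data"}: list with
#'   \code{time}, \code{cause}, \code{covariates} (data.frame),
#'   \code{n}, \code{n_causes}, \code{cause_labels}, \code{treatment},
#'   \code{horizon}.
#' @export
survival_data <- function(data, time = "time", cause = "cause",
                          covariates = character(), treatment = NULL,
                          horizon = NULL, cause_labels = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(time, cause, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tt <- data[[time]]
  if (!is.numeric(tt)) stop("time column '", time, "' is not numeric")
  bad <- which(!is.finite(tt) | tt <= 0)
  if (length(bad)) {
    stop("time must be > 0 and finite; offending row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  dd <- data[[cause]]
  if (any(is.na(dd)) || any(dd != round(dd)) || any(dd < 0)) {
    stop("cause column '", cause,
         "' must be non-negative integers (0 = censored)")
  }
  dd <- as.integer(dd)
  Z <- data[covariates]
  for (v in covariates) {
    if (!is.numeric(Z[[v]])) stop("covariate '", v, "' is not numeric")
    if (any(!is.finite(Z[[v]]))) {
      stop("covariate '", v, "' has missing/non-finite values; rows: ",
           paste(utils::head(which(!is.finite(Z[[v]])), 10L),
                 collapse = ", "))
    }
  }
  if (!is.null(treatment) && !(treatment %in% covariates)) {
    stop("treatment '", treatment, "' must be listed among covariates")
  }
  if (!is.null(horizon)) {
    stopifnot(is.numeric(horizon), horizon > 0)
    over <- tt > horizon
    dd[over] <- 0L
    tt[over] <- horizon
  }
  K <- max(dd, 0L)
  if (is.null(cause_labels)) {
    cause_labels <- if (K > 0) paste0("cause", seq_len(K)) else character(0)
  }
  if (length(cause_labels) < K) stop("need a label for every cause 1..K")
  structure(list(time = tt, cause = dd,
                 covariates = as.data.frame(Z), n = length(tt),
                 n_causes = K, cause_labels = cause_labels,
                 treatment = treatment, horizon = horizon),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat("Competing-risks survival data: n =", x$n, "\n")
  tab <- table(factor(x$cause, levels = 0:x$n_causes))
  lbl <- c("censored", x$cause_labels[seq_len(x$n_causes)])
  cat("  events: ",
      paste(sprintf("%s=%d", lbl, as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$horizon)) cat("  administrative censoring at",
                               x$horizon, "\n")
  invisible(x)
}

#' Per-cause event counts
#' @param data a [survival_data()] object.
#' @return named integer vector, one entry per cause 1..K.
#' @export
event_counts <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  k <- seq_len(data$n_causes)
  stats::setNames(vapply(k, function(j) sum(data$cause == j), 0L),
                  data$cause_labels[k])
}

#' Load a delimited table as survival data
#'
#' Reads a CSV (header required) and declares it via [survival_data()].
#' Invalid rows (non-positive times, missing values in used columns) raise
#' an error naming the rows; nothing is dropped silently.
#'
#' @param path file path of a delimited text file.
#' @param sep field separator (default comma).
#' @param ... passed on to [survival_data()] (\code{time}, \code{cause},
#'   \code{covariates}, ...).
#' @return A [survival_data()] object.
#' @export
load_table <- function(path, sep = ",", ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  survival_data(raw, ...)
}

#' Write survival data back to CSV
#' @param data a [survival_data()] object.
#' @param path output file.
#' @param time,cause column names to use on output.
#' @export
write_table <- function(data, path, time = "time", cause = "cause") {
  stopifnot(inherits(data, "survival_data"))
  out <- cbind(stats::setNames(data.frame(data$time, data$cause),
                               c(time, cause)),
               data$covariates)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default status-to-cause map for the prostate trial table
#'
#' Maps the raw status strings of the hbiostat prostate-trial schema to
#' cause codes: alive -> 0, death from prostate cancer -> 1, any other
#' death -> 2.  Pass an edited copy to [prepare_prostate()] if the raw
#' codebook differs.
#'
#' @return named integer vector.
#' @export
prostate_status_map <- function() {
  c("alive" = 0L,
    "dead - prostatic ca" = 1L,
    "dead - heart or vascular" = 2L,
    "dead - cerebrovascular" = 2L,
    "dead - pulmonary embolus" = 2L,
    "dead - other ca" = 2L,
    "dead - respiratory disease" = 2L,
    "dead - other specific non-ca" = 2L,
    "dead - unspecified non-ca" = 2L,
    "dead - unknown cause" = 2L)
}

#' Prepare the prostate-cancer trial table for analysis
#'
#' Derives the two-arm analysis dataset from the public Byar & Green
#' prostate trial table (hbiostat.org schema): keeps the placebo and
#' high-dose (5.0 mg) estrogen arms, recodes treatment as \code{rx}
#' (1 = DES, 0 = placebo), dichotomises hemoglobin at 12 g/100ml
#' (\code{hgBinary} = 1 if < 12), bins age at 59/74 into \code{ageCat}
#' (0: 0-59, 1: 60-74, 2: 75+) with dummies \code{ageCat1},
#' \code{ageCat2}, codes daily activity as \code{normalAct} (1 = normal
#' activity) and maps the status string to \code{eventType} (0 alive,
#' 1 prostate-cancer death, 2 other causes).  Unmapped arm or status
#' codes raise an error listing them; no silent drops.
#'
#' @param raw data.frame with columns \code{rx}, \code{status},
#'   \code{age}, \code{hg}, \code{hx}, \code{pf}, \code{dtime}.
#' @param status_map named integer vector mapping status strings to cause
#'   codes; default [prostate_status_map] semantics (editable so a
#'   codebook correction is a one-line fix).
#' @param arms character vector of length 2: the raw labels of the
#'   placebo and high-dose arms.
#' @return data.frame with columns \code{rx}, \code{normalAct},
#'   \code{ageCat}, \code{ageCat1}, \code{ageCat2}, \code{hx},
#'   \code{hgBinary}, \code{dtime}, \code{eventType}.
#' @export
prepare_prostate <- function(raw, status_map = prostate_status_map(),
                             arms = c("placebo", "5.0 mg estrogen")) {
  need <- c("rx", "status", "age", "hg", "hx", "pf", "dtime")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  rx_chr <- trimws(as.character(raw$rx))
  known_arms <- c(arms, "0.2 mg estrogen", "1.0 mg estrogen")
  unknown <- setdiff(unique(rx_chr), known_arms)
  if (length(unknown)) {
    stop("unknown treatment arm code(s): ",
         paste(unknown, collapse = "; "))
  }
  keep <- rx_chr %in% arms
  d <- raw[keep, , drop = FALSE]
  rx_chr <- rx_chr[keep]
  status_chr <- trimws(as.character(d$status))
  unmapped <- setdiff(unique(status_chr), names(status_map))
  if (length(unmapped)) {
    stop("unmapped status code(s): ", paste(unmapped, collapse = "; "),
         " - extend status_map")
  }
  age <- as.numeric(d$age)
  if (any(is.na(age))) stop("missing age in row(s): ",
                            paste(which(is.na(age)), collapse = ", "))
  ageCat <- ifelse(age <= 59, 0L, ifelse(age <= 74, 1L, 2L))
  out <- data.frame(
    rx = as.integer(rx_chr == arms[2]),
    normalAct = as.integer(trimws(as.character(d$pf)) ==
                             "normal activity"),
    ageCat = ageCat,
    ageCat1 = as.integer(ageCat == 1L),
    ageCat2 = as.integer(ageCat == 2L),
    hx = as.integer(d$hx),
    hgBinary = as.integer(as.numeric(d$hg) < 12),
    dtime = as.numeric(d$dtime),
    eventType = as.integer(status_map[status_chr])
  )
  out
}

#' Clone a treatment column into separable-effect components
#'
#' Adds exact copies of the treatment column under new names (for example
#' \code{rx_c}, the component acting on the cause of interest, and
#' \code{rx_o}, the component acting on the competing cause) so the two
#' components can be set independently in counterfactual at-settings.
#'
#' @param data a [survival_data()] object.
#' @param treatment name of the existing treatment column.
#' @param clones character vector of new column names.
#' @return The modified \code{survival_data}.
#' @export
clone_treatment <- function(data, treatment = data$treatment,
                            clones = c(paste0(treatment, "_c"),
                                       paste0(treatment, "_o"))) {
  stopifnot(inherits(data, "survival_data"))
  if (is.null(treatment) || !(treatment %in% names(data$covariates))) {
    stop("treatment column not found")
  }
  for (nm in clones) data$covariates[[nm]] <- data$covariates[[treatment]]
  data
}
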