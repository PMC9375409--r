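#' Restricted cubic spline knot set
#'
#' A knot set holds the ordered knot locations of a restricted cubic spline
#' on the spline's input scale (log months for the time splines, natural
#' units for continuous covariates).  A spline with \code{df} basis columns
#' uses \code{df + 1} knots: two boundary knots and \code{df - 1} internal
#' knots.
#'
#' @param values strictly increasing numeric vector of knot locations.
#' @return An object of class \code{"knot_set"} with elements
#'   \code{values} and \code{df}.
#' @export
knot_set <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a knot set needs at least 2 knots (boundary knots)")
  }
  if (any(!is.finite(values))) stop("knots must be finite")
  if (any(diff(values) <= 0)) stop("knots must be strictly increasing")
  structure(list(values = values, df = length(values) - 1L),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat("Knot set: df =", x$df, "\n  knots:",
      paste(signif(x$values, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Place knots for a restricted cubic spline of log time
#'
#' Boundary knots go at the minimum and maximum of the (log) event times of
#' the cause being modelled; the \code{df - 1} internal knots sit at equally
#' spaced centiles of those event times (df = 2: median; df = 3: 33.3rd and
#' 66.7th centiles).  Centiles use type-7 (linear interpolation) quantiles;
#' supply knots explicitly to a fitting function to match another
#' convention.
#'
#' @param event_log_times numeric vector of log event times (uncensored
#'   events of the modelled cause only).
#' @param df integer >= 1, number of spline basis columns.
#' @return A [knot_set()].
#' @export
place_knots <- function(event_log_times, df) {
  if (length(event_log_times) == 0L) stop("no event times supplied")
  if (any(!is.finite(event_log_times))) stop("event times must be finite")
  df <- as.integer(df)
  if (df < 1L) stop("df must be >= 1")
  n_distinct <- length(unique(event_log_times))
  if (df >= n_distinct) {
    stop("insufficient distinct event times (", n_distinct,
         ") for df = ", df)
  }
  bounds <- range(event_log_times)
  internal <- if (df >= 2L) {
    as.numeric(stats::quantile(event_log_times,
                               probs = seq_len(df - 1L) / df,
                               type = 7, names = FALSE))
  } else numeric(0)
  knot_set(c(bounds[1], internal, bounds[2]))
}

## Raw (un-orthogonalised) restricted cubic spline basis, truncated-power
## form: first column is x itself; remaining columns are cubic truncated
## powers constrained to be linear beyond the boundary knots.
rcs_raw <- function(x, knots) {
  k <- knots$values
  m <- length(k)
  df <- knots$df
  out <- matrix(0, length(x), df)
  out[, 1] <- x
  if (df >= 2L) {
    kmin <- k[1]; kmax <- k[m]
    for (j in 2:(m - 1)) {
      lam <- (kmax - k[j]) / (kmax - kmin)
      out[, j] <- pmax(x - k[j], 0)^3 - lam * pmax(x - kmin, 0)^3 -
        (1 - lam) * pmax(x - kmax, 0)^3
    }
  }
  out
}

rcs_raw_deriv <- function(x, knots) {
  k <- knots$values
  m <- length(k)
  df <- knots$df
  out <- matrix(0, length(x), df)
  out[, 1] <- 1
  if (df >= 2L) {
    kmin <- k[1]; kmax <- k[m]
    for (j in 2:(m - 1)) {
      lam <- (kmax - k[j]) / (kmax - kmin)
      out[, j] <- 3 * pmax(x - k[j], 0)^2 - 3 * lam * pmax(x - kmin, 0)^2 -
        3 * (1 - lam) * pmax(x - kmax, 0)^2
    }
  }
  out
}

#' Build a spline basis (knots plus orthogonalisation matrix)
#'
#' Constructs the restricted cubic spline basis at the fitting data
#' \code{x} and stores the upper-triangular transform ("R matrix") from a
#' QR factorisation of \code{cbind(1, raw_basis)} so that exactly the same
#' orthogonalised basis can be reproduced at arbitrary new inputs
#' post-estimation.  With \code{orthogonal = FALSE} the transform is the
#' identity and [rcs()] returns the raw truncated-power basis.
#'
#' @param knots a [knot_set()].
#' @param x numeric vector of fitting-time inputs (used to build the
#'   orthogonalisation; required when \code{orthogonal = TRUE}).
#' @param orthogonal logical; orthogonalise the basis columns?
#' @param column_prefix label prefix for basis columns
#'   (default \code{"_rcs"}).
#' @return Object of class \code{"spline_basis"}: knots, \code{Rmat},
#'   its inverse, and column names.
#' @export
spline_basis <- function(knots, x = NULL, orthogonal = TRUE,
                         column_prefix = "_rcs") {
  stopifnot(inherits(knots, "knot_set"))
  df <- knots$df
  if (orthogonal) {
    if (is.null(x)) stop("x is required to orthogonalise the basis")
    if (any(!is.finite(x))) stop("non-finite x")
    raw <- rcs_raw(x, knots)
    M <- cbind(1, raw)
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
      stop("spline basis is rank deficient at the supplied x; ",
           "too few distinct values for df = ", df)
    }
    R <- qr.R(qrM)
    ## fix signs so the constant column maps to +1 and diag(R) > 0
    s <- sign(diag(R)); s[s == 0] <- 1
    R <- diag(s) %*% R
    Rmat <- R / sqrt(length(x))
  } else {
    Rmat <- diag(df + 1L)
  }
  structure(list(knots = knots,
                 Rmat = Rmat,
                 Rinv = solve(Rmat),
                 column_names = paste0(column_prefix, seq_len(df)),
                 df = df),
            class = "spline_basis")
}

#' Evaluate a restricted cubic spline basis
#'
#' Returns the \code{n x df} basis matrix at \code{x}.  Passing a bare
#' [knot_set()] computes a fresh orthogonalisation at \code{x} (the
#' resulting basis is attached as attribute \code{"basis"}); passing a
#' \code{"spline_basis"} reuses its stored projection, which is what makes
#' post-estimation predictions at new times/ages reproduce the fitted
#' basis exactly.
#'
#' @param x numeric vector (finite).
#' @param basis a \code{"spline_basis"} or a \code{"knot_set"}.
#' @return \code{length(x) x df} matrix; columns named per the basis.
#' @export
rcs <- function(x, basis) {
  if (any(!is.finite(x))) stop("non-finite x")
  if (inherits(basis, "knot_set")) {
    basis <- spline_basis(basis, x = x)
    out <- rcs(x, basis)
    attr(out, "basis") <- basis
    return(out)
  }
  stopifnot(inherits(basis, "spline_basis"))
  raw <- rcs_raw(x, basis$knots)
  V <- cbind(1, raw) %*% basis$Rinv
  out <- V[, -1L, drop = FALSE]
  colnames(out) <- basis$column_names
  out
}

#' Derivative of a restricted cubic spline basis
#'
#' Column-wise derivative of [rcs()] with respect to \code{x}, using the
#' same stored projection (the derivative of the constant column is zero).
#'
#' @inheritParams rcs
#' @param basis a fitted \code{"spline_basis"}.
#' @return \code{length(x) x df} matrix of derivatives.
#' @export
rcs_derivative <- function(x, basis) {
  if (any(!is.finite(x))) stop("non-finite x")
  stopifnot(inherits(basis, "spline_basis"))
  rawd <- rcs_raw_deriv(x, basis$knots)
  V <- cbind(0, rawd) %*% basis$Rinv
  out <- V[, -1L, drop = FALSE]
  colnames(out) <- basis$column_names
  out
}
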