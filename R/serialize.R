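## JSON persistence of fitted models: spec, knots, projection matrices,
## coefficients, covariance, log-likelihood.  Numbers are written at full
## double precision (digits = NA) so the round trip is bit-exact.

basis_to_list <- function(b) {
  list(knots = b$knots$values, Rmat = b$Rmat,
       column_names = b$column_names)
}

basis_from_list <- function(l) {
  Rmat <- matrix(unlist(l$Rmat), nrow = length(l$knots),
                 ncol = length(l$knots), byrow = TRUE)
  structure(list(knots = knot_set(unlist(l$knots)),
                 Rmat = Rmat, Rinv = solve(Rmat),
                 column_names = unlist(l$column_names),
                 df = length(l$knots) - 1L),
            class = "spline_basis")
}

#' Save a fitted model as JSON
#' @param model a fitted \code{"fpm"}.
#' @param path output file path.
#' @export
fpm_save <- function(model, path) {
  stopifnot(inherits(model, "fpm"))
  obj <- list(
    package = "crstand", format = 1L,
    spec = list(df = model$spec$df, covariates = model$spec$covariates,
                tvc = model$spec$tvc, dftvc = model$spec$dftvc),
    baseline_basis = basis_to_list(model$baseline_basis),
    tvc_bases = lapply(model$tvc_bases, basis_to_list),
    coef = model$coef, vcov = model$vcov, loglik = model$loglik,
    event_cause = model$event_cause, label = model$label,
    n = model$n, n_events = model$n_events,
    grad_norm = model$grad_norm, orthogonal = model$orthogonal)
  ## I(17) = 17 significant digits: enough to round-trip an IEEE double
  ## exactly through decimal text
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a fitted model from JSON
#' @param path file written by [fpm_save()].
#' @return a fitted \code{"fpm"} object.
#' @export
fpm_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$package, "crstand")) stop("not a crstand model file")
  spec <- fpm_spec(df = obj$spec$df,
                   covariates = as.character(unlist(obj$spec$covariates)),
                   tvc = as.character(unlist(obj$spec$tvc)),
                   dftvc = if (length(obj$spec$tvc))
                     stats::setNames(as.integer(unlist(obj$spec$dftvc)),
                                     as.character(unlist(obj$spec$tvc)))
                   else 2L)
  nm <- param_names(spec)
  coef <- stats::setNames(unlist(obj$coef), nm)
  p <- length(nm)
  vc <- matrix(unlist(obj$vcov), p, p, byrow = TRUE,
               dimnames = list(nm, nm))
  tvcb <- lapply(obj$tvc_bases, basis_from_list)
  names(tvcb) <- names(obj$tvc_bases)
  structure(list(spec = spec,
                 baseline_basis = basis_from_list(obj$baseline_basis),
                 tvc_bases = tvcb,
                 coef = coef, vcov = vc, loglik = obj$loglik,
                 event_cause = as.integer(obj$event_cause),
                 label = obj$label, n = obj$n, n_events = obj$n_events,
                 grad_norm = obj$grad_norm,
                 orthogonal = isTRUE(obj$orthogonal)),
            class = "fpm")
}
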