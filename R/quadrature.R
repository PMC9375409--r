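## Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch
## symmetric-tridiagonal eigenproblem.  Deterministic; memoised per n.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n == 1L) {
    out <- list(nodes = 0, weights = 2)
  } else {
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(nodes = e$values[ord],
                weights = 2 * (e$vectors[1, ord])^2)
  }
  .gl_cache[[key]] <- out
  out
}

## Rescale the rule to (0, upper], with a graded substitution
## u = upper * s^power (s in (0,1)) that absorbs the u^(p-1) behaviour of
## hazard integrands near 0 (shape p near 1), restoring the rule's full
## order of accuracy.  power = 1 is the plain affine map.
gl_rule <- function(upper, nodes, power = 2) {
  gl <- gauss_legendre(nodes)
  s <- (gl$nodes + 1) / 2
  list(u = upper * s^power,
       w = gl$weights / 2 * upper * power * s^(power - 1))
}
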