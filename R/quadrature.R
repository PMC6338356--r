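## Gaussian quadrature rules via Golub-Welsch (symmetric tridiagonal Jacobi
## matrix eigendecomposition).  Rules are memoised per order.

.quad_cache <- new.env(parent = emptyenv())

#' Gauss-Legendre nodes and weights
#'
#' @param n order (number of nodes).
#' @param a,b interval endpoints (default the unit interval).
#' @return list with `nodes` and `weights`; exact for polynomials of degree
#'   `2n - 1`.
#' @export
gauss_legendre <- function(n, a = 0, b = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1L, b > a)
  key <- paste0("gl", n)
  rule <- .quad_cache[[key]]
  if (is.null(rule)) {
    if (n == 1L) {
      rule <- list(x = 0, w = 2)
    } else {
      k <- seq_len(n - 1L)
      off <- k / sqrt(4 * k^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(k, k + 1L)] <- off
      J[cbind(k + 1L, k)] <- off
      e <- eigen(J, symmetric = TRUE)
      ord <- order(e$values)
      rule <- list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
    }
    .quad_cache[[key]] <- rule
  }
  list(nodes = (a + b) / 2 + (b - a) / 2 * rule$x,
       weights = (b - a) / 2 * rule$w)
}

#' Gauss-Hermite nodes and weights (physicists' weight exp(-z^2))
#'
#' @param n order.
#' @return list with `nodes` and `weights` such that
#'   `sum(weights * f(nodes))` approximates `integral f(z) exp(-z^2) dz`.
#' @export
gauss_hermite <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  key <- paste0("gh", n)
  rule <- .quad_cache[[key]]
  if (is.null(rule)) {
    if (n == 1L) {
      rule <- list(x = 0, w = sqrt(pi))
    } else {
      k <- seq_len(n - 1L)
      off <- sqrt(k / 2)
      J <- matrix(0, n, n)
      J[cbind(k, k + 1L)] <- off
      J[cbind(k + 1L, k)] <- off
      e <- eigen(J, symmetric = TRUE)
      ord <- order(e$values)
      rule <- list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
    }
    .quad_cache[[key]] <- rule
  }
  list(nodes = rule$x, weights = rule$w)
}

#' Integrate a function over the unit interval
#'
#' Gauss-Legendre quadrature on (0,1). Integrands that involve the speed
#' density must have its endpoint singularities analytically folded in before
#' calling (all model integrands do: their remaining factors vanish fast
#' enough at 0 and 1).
#'
#' @param g vectorized integrand on (0,1).
#' @param order quadrature order.
#' @return the quadrature approximation of `integral_0^1 g(x) dx`.
#' @export
integrate_unit_interval <- function(g, order = 64L) {
  q <- gauss_legendre(order)
  v <- g(q$nodes)
  if (!all(is.finite(v))) stop("non-finite integrand value at a quadrature node")
  sum(q$weights * v)
}

#' Expectation of a function of gamma under a normal distribution
#'
#' Computes `integral N(gamma | center, sd^2) h(gamma) dgamma` by
#' Gauss-Hermite quadrature after the change of variable
#' `gamma = center + sqrt(2) * sd * z`. For `sd = 0` returns `h(center)`
#' exactly.
#'
#' @param h vectorized function of gamma.
#' @param center mean of the normal.
#' @param sd standard deviation (>= 0).
#' @param order Gauss-Hermite order.
#' @return the expectation value.
#' @export
expect_over_gamma <- function(h, center, sd, order = 32L) {
  stopifnot(sd >= 0)
  if (sd == 0) return(h(center))
  q <- gauss_hermite(order)
  v <- h(center + sqrt(2) * sd * q$nodes)
  if (!all(is.finite(v))) stop("non-finite h value at a quadrature node")
  sum(q$weights * v) / sqrt(pi)
}
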