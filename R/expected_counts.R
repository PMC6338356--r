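## The model's forward map: sample-configuration probabilities I, J, K, the
## legacy-loss term L, the Lambda functionals and the six Poisson means of the
## generalized 2x3 McDonald-Kreitman table.
##
## All quantities reduce to a small set of "basis" transition-density actions
## u_f(t, x) = integral p(t, x, y) f(y) m(dy) with
##   f in { y^m, (1-y)^m (per distinct sample size m), 1, s(y)/s(1) },
## which are marched jointly by one Crank-Nicolson call per (gamma, t-range):
##   J(x,m) = u_1 - u_{y^m} - u_{(1-y)^m}
##   K(x,m) = s(x)/s(1) + u_{y^m} - u_{s/s(1)}
##   I(x,m) = (s(1)-s(x))/s(1) - (u_1 - u_{(1-y)^m} - u_{s/s(1)})
##   L(m)   = integral (x^m - u_{y^m}(t,x)) (s(1)-s(x)) m(dx)
## and the new-mutation fixation term of Lambda_1 is 2*(t - Phi(t)) with
## Phi(t) the running integral of the fixation flux limit (accumulated during
## the march from the s(y)/s(1) column).

# initial basis columns on the grid; mm = sorted distinct sample sizes
.basis_init <- function(gamma, mm, grid, ctrl) {
  x <- grid$x
  k <- length(mm)
  F0 <- matrix(0, length(x), 2 * k + 2)
  for (j in seq_len(k)) {
    F0[, j] <- x^mm[j]
    F0[, k + j] <- (1 - x)^mm[j]
  }
  F0[, 2 * k + 1] <- 1
  F0[, 2 * k + 2] <- .sratio(x, gamma, ctrl$gamma_tol)
  F0
}

# Compute nu_j = Lambda_j / s(1) for every pair (rows of `pairs`) at every
# time in t_vec (nonnegative, sorted, multiples of dt apart from exact zeros).
# Returns an array [npair, 3, length(t_vec)].
.lambda_nu_block <- function(gamma, t_vec, pairs, ctrl, grid = NULL, dt = NULL) {
  ctrl <- as_prf_control(ctrl)
  if (is.null(grid)) grid <- diffusion_grid(ctrl$grid_points)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  mm <- sort(unique(as.vector(pairs)))
  k <- length(mm)
  npair <- nrow(pairs)
  nt <- length(t_vec)
  stopifnot(all(t_vec >= 0), !is.unsorted(t_vec))

  gl <- gauss_legendre(ctrl$gl_order)
  xg <- gl$nodes
  glw <- gl$weights
  w <- .wx(xg, gamma, ctrl)                 # (s(1)-s(x)) m(x)
  sr <- .sratio(xg, gamma, ctrl$gamma_tol)  # s(x)/s(1)
  s1 <- .s1(gamma, ctrl$gamma_tol)
  xpow <- sapply(mm, function(m) xg^m)           # ngl x k
  xqow <- sapply(mm, function(m) (1 - xg)^m)

  out <- array(0, dim = c(npair, 3, nt))

  pos <- t_vec > 0
  if (any(pos)) {
    tp <- t_vec[pos]
    if (is.null(dt)) dt <- max(tp) / ctrl$time_steps
    F0 <- .basis_init(gamma, mm, grid, ctrl)
    res <- .cn_march(gamma, grid, F0, tp, dt, flux_col = 2L * k + 2L)
    B <- .interp_matrix(grid, xg)
    for (r in seq_along(tp)) {
      U <- B %*% res$u[, , r]               # ngl x (2k+2)
      a <- U[, seq_len(k), drop = FALSE]
      b <- U[, k + seq_len(k), drop = FALSE]
      u1 <- U[, 2 * k + 1]
      cc <- U[, 2 * k + 2]
      J <- pmin(pmax(u1 - a - b, 0), 1)
      K <- pmin(pmax(sr + a - cc, 0), 1)
      I <- pmin(pmax((1 - sr) - (u1 - b - cc), 0), 1)
      L <- as.numeric(crossprod(glw * w, xpow - a))
      fixterm <- 2 * (tp[r] - res$Phi[r])
      ri <- which(t_vec == tp[r])[1]
      for (p in seq_len(npair)) {
        im <- match(pairs[p, 1], mm)
        jn <- match(pairs[p, 2], mm)
        lam1 <- sum(glw * (I[, im] * K[, jn] + I[, jn] * K[, im]) * w) +
          fixterm + L[im] + L[jn]
        lam2 <- sum(glw * (2 - xpow[, im] - xqow[, im] - xpow[, jn] - xqow[, jn] -
                             2 * J[, im] * J[, jn]) * w)
        lam3 <- sum(glw * (J[, im] * J[, jn]) * w)
        out[p, , ri] <- pmax(c(lam1, lam2, lam3), 0) / s1
      }
    }
  }
  if (any(!pos)) {
    # exact t = 0 reduction: p(0,x,y) = delta, so I = (1-x)^m, J = 1 - x^m -
    # (1-x)^m, K = x^m, L = 0 and the fixation term vanishes
    J0 <- pmax(1 - xpow - xqow, 0)
    for (p in seq_len(npair)) {
      im <- match(pairs[p, 1], mm)
      jn <- match(pairs[p, 2], mm)
      lam1 <- sum(glw * (xqow[, im] * xpow[, jn] + xqow[, jn] * xpow[, im]) * w)
      lam2 <- sum(glw * (2 - xpow[, im] - xqow[, im] - xpow[, jn] - xqow[, jn] -
                           2 * J0[, im] * J0[, jn]) * w)
      lam3 <- sum(glw * (J0[, im] * J0[, jn]) * w)
      out[p, , which(!pos)] <- pmax(c(lam1, lam2, lam3), 0) / s1
    }
  }
  out
}

# I, J, K at arbitrary frequencies xout for one sample size m
.sample_config_probs <- function(gamma, t, m, xout, ctrl = NULL, grid = NULL) {
  ctrl <- as_prf_control(ctrl)
  if (is.null(grid)) grid <- diffusion_grid(ctrl$grid_points)
  stopifnot(all(xout > 0 & xout < 1), t >= 0, m >= 1)
  sr <- .sratio(xout, gamma, ctrl$gamma_tol)
  if (t == 0) {
    return(list(I = (1 - xout)^m, J = 1 - xout^m - (1 - xout)^m, K = xout^m))
  }
  F0 <- .basis_init(gamma, m, grid, ctrl)
  res <- .cn_march(gamma, grid, F0, t, t / ctrl$time_steps)
  B <- .interp_matrix(grid, xout)
  U <- B %*% res$u[, , 1]
  a <- U[, 1]; b <- U[, 2]; u1 <- U[, 3]; cc <- U[, 4]
  list(I = pmin(pmax((1 - sr) - (u1 - b - cc), 0), 1),
       J = pmin(pmax(u1 - a - b, 0), 1),
       K = pmin(pmax(sr + a - cc, 0), 1))
}

#' Sample-configuration probabilities
#'
#' For a site at ancestral population frequency `x` at the divergence split,
#' the probability that a present-day sample of `m` sequences from one
#' descendant species is, respectively, monomorphic for the wild type
#' (`prob_mono_wildtype`, the I function), polymorphic (`prob_polymorphic`,
#' the J function), or monomorphic for the mutant (`prob_mono_mutant`, the K
#' function), after the diffusion has run for `t` units of N_e generations.
#'
#' @param x ancestral frequency strictly inside (0,1) (vectorized).
#' @param m sample size (number of aligned sequences).
#' @param gamma scaled selection coefficient.
#' @param t divergence time in N_e generations.
#' @param ctrl optional [prf_control()].
#' @return probabilities in `[0,1]`.
#' @export
prob_mono_wildtype <- function(x, m, gamma, t, ctrl = NULL) {
  .sample_config_probs(gamma, t, m, x, ctrl)$I
}

#' @rdname prob_mono_wildtype
#' @export
prob_polymorphic <- function(x, m, gamma, t, ctrl = NULL) {
  .sample_config_probs(gamma, t, m, x, ctrl)$J
}

#' @rdname prob_mono_wildtype
#' @export
prob_mono_mutant <- function(x, m, gamma, t, ctrl = NULL) {
  .sample_config_probs(gamma, t, m, x, ctrl)$K
}

#' Legacy fixation-loss term L(m)
#'
#' `L(m) = integral x^m (s(1)-s(x)) m(dx) - integral integral p(t,x,y) y^m
#' (s(1)-s(x)) m(dy) m(dx)`: the contribution to fixed differences from
#' ancestral polymorphisms that have been lost from the population but whose
#' sampled configuration still registers as fixed. Zero at `t = 0`,
#' non-decreasing in `t`.
#'
#' @param m sample size.
#' @param gamma scaled selection coefficient.
#' @param t divergence time (>= 0).
#' @param ctrl optional [prf_control()].
#' @return the (nonnegative, up to quadrature error) value of L(m).
#' @export
legacy_loss_term <- function(m, gamma, t, ctrl = NULL) {
  ctrl <- as_prf_control(ctrl)
  gl <- gauss_legendre(ctrl$gl_order)
  w <- .wx(gl$nodes, gamma, ctrl)  # (s(1)-s(x)) m(x)
  if (t == 0) return(0)
  grid <- diffusion_grid(ctrl$grid_points)
  F0 <- matrix(grid$x^m, ncol = 1)
  res <- .cn_march(gamma, grid, F0, t, t / ctrl$time_steps)
  a <- as.numeric(.interp_matrix(grid, gl$nodes) %*% res$u[, , 1])
  sum(gl$weights * (gl$nodes^m - a) * w)
}

#' The Lambda functionals of the time-dependent PRF model
#'
#' `Lambda_1` (fixed differences), `Lambda_2` (new polymorphisms) and
#' `Lambda_3` (legacy polymorphisms): the per-unit-mutation-rate category
#' weights, such that e.g. the expected number of replacement fixed
#' differences is `theta_r / s(1)` times the normal-mixture expectation of
#' `Lambda_1`. All three are symmetric in `(m, n)`.
#'
#' @param gamma scaled selection coefficient.
#' @param t divergence time in N_e generations.
#' @param m,n sample sizes of the two species.
#' @param ctrl optional [prf_control()].
#' @return named vector `c(lambda1, lambda2, lambda3)`.
#' @export
lambda_functions <- function(gamma, t, m, n, ctrl = NULL) {
  ctrl <- as_prf_control(ctrl)
  nu <- .lambda_nu_block(gamma, t, cbind(m, n), ctrl)[1, , 1]
  lam <- nu * .s1(gamma, ctrl$gamma_tol)
  names(lam) <- c("lambda1", "lambda2", "lambda3")
  lam
}

# Gauss-Hermite average of nu_j over gamma ~ N(gamma_i, sigma_w^2).
# `evalfun(gvec)` must return a length(gvec) x 3 matrix of nu values.
.nu_mix <- function(evalfun, gamma_i, sigma_w, ctrl) {
  if (sigma_w == 0) {
    v <- evalfun(gamma_i)
    return(as.numeric(v))
  }
  q <- gauss_hermite(ctrl$gh_order)
  gv <- gamma_i + sqrt(2) * sigma_w * q$nodes
  v <- evalfun(gv)
  as.numeric(crossprod(q$weights, v)) / sqrt(pi)
}

# direct (uncached) nu evaluation at a vector of gammas, one (m,n), one t
.nu_direct <- function(gvec, t, m, n, ctrl) {
  out <- matrix(0, length(gvec), 3)
  for (i in seq_along(gvec))
    out[i, ] <- .lambda_nu_block(gvec[i], t, cbind(m, n), ctrl)[1, , 1]
  out
}

#' Expected 2x3 contingency table of the time-dependent PRF model
#'
#' The six Poisson means: replacement entries are `theta_r` times the
#' `N(gamma | gamma_i, sigma_w^2)` expectation of `Lambda_j(gamma)/s(1)`
#' (Gauss-Hermite; the `1/s(1)` normalization is evaluated inside the
#' expectation by default since `s(1)` depends on gamma), silent entries are
#' `theta_s * Lambda_j(0) / s(1)|_{gamma=0}`. Linear in both mutation rates.
#'
#' @param theta_s,theta_r scaled silent/replacement mutation rates (>= 0).
#' @param gamma_i locus mean scaled selection coefficient.
#' @param sigma_w within-locus standard deviation of gamma (>= 0).
#' @param t divergence time in N_e generations.
#' @param m,n sample sizes.
#' @param ctrl optional [prf_control()].
#' @param cache optional [lambda_cache()] used instead of direct
#'   Crank-Nicolson solves.
#' @return named vector `c(e_Kr, e_Or, e_Hr, e_Ks, e_Os, e_Hs)`.
#' @export
expected_table <- function(theta_s, theta_r, gamma_i, sigma_w, t, m, n,
                           ctrl = NULL, cache = NULL) {
  ctrl <- as_prf_control(ctrl)
  stopifnot(theta_s >= 0, theta_r >= 0, sigma_w >= 0, t >= 0)
  if (!is.null(cache)) {
    p <- cache_pair_index(cache, m, n)
    evalfun <- function(gvec) nu_eval(cache, gvec, t, p)
    nu0 <- as.numeric(nu_eval(cache, 0, t, p))
  } else {
    evalfun <- function(gvec) .nu_direct(gvec, t, m, n, ctrl)
    nu0 <- .lambda_nu_block(0, t, cbind(m, n), ctrl)[1, , 1]
  }
  if (ctrl$s1_inside) {
    nur <- .nu_mix(evalfun, gamma_i, sigma_w, ctrl)
  } else {
    s1i <- .s1(gamma_i, ctrl$gamma_tol)
    lamfun <- function(gvec) {
      v <- evalfun(gvec)
      v * vapply(gvec, .s1, 0, ctrl$gamma_tol) / s1i
    }
    nur <- .nu_mix(lamfun, gamma_i, sigma_w, ctrl)
  }
  c(e_Kr = theta_r * nur[1], e_Or = theta_r * nur[2], e_Hr = theta_r * nur[3],
    e_Ks = theta_s * nu0[1], e_Os = theta_s * nu0[2], e_Hs = theta_s * nu0[3])
}
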