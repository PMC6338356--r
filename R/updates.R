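## Standalone single-step update operations.  These expose the sampler's
## moves on an explicit state object for testing and experimentation;
## run_chain() applies the same mathematics in a vectorized loop.
##
## A state is list(global = list(mu_gamma, sigma_b, sigma_w, t_div),
##                 loci = data.frame(theta_s, theta_r, gamma_i)).

.state_rates <- function(state, data, cache, ctrl) {
  pair_idx <- vapply(seq_len(nrow(data)), function(i)
    cache_pair_index(cache, data$m[i], data$n[i]), 0L)
  ghq <- gauss_hermite(ctrl$gh_order)
  list(pair_idx = pair_idx, ghq = ghq,
       nu0 = .nu0_all(cache, state$global$t_div, pair_idx),
       gbar = .gbar_all(cache, state$loci$gamma_i, state$global$sigma_w,
                        state$global$t_div, pair_idx, ghq))
}

#' Gibbs update of the per-locus mutation rates
#'
#' Draws every `theta_s` and `theta_r` from its exact gamma full conditional:
#' shape = prior shape + sum of the three category counts, rate = prior rate +
#' sum of the three per-unit-theta Poisson-mean coefficients.
#'
#' @param state sampler state (see file header).
#' @param data locus counts data frame.
#' @param priors a [prior_config()].
#' @param cache a [lambda_cache()] covering the data's sample sizes.
#' @param ctrl optional [prf_control()].
#' @return the state with updated `loci$theta_s`, `loci$theta_r`.
#' @export
gibbs_update_thetas <- function(state, data, priors, cache, ctrl = NULL) {
  ctrl <- as_prf_control(ctrl)
  r <- .state_rates(state, data, cache, ctrl)
  rs <- rowSums(r$nu0)
  rr <- rowSums(r$gbar)
  if (!all(is.finite(rs)) || !all(is.finite(rr)))
    stop("non-finite full-conditional rate")
  cs <- data$Ks + data$Os + data$Hs
  cr <- data$Kr + data$Or + data$Hr
  state$loci$theta_s <- rgamma(nrow(data), priors$alpha_s + cs,
                               rate = priors$beta_s + rs)
  state$loci$theta_r <- rgamma(nrow(data), priors$alpha_r + cr,
                               rate = priors$beta_r + rr)
  state
}

#' Metropolis random-walk update of the locus selection coefficients
#'
#' Gaussian proposal for each `gamma_i`, accepted with the usual posterior
#' ratio (hierarchical normal prior times the replacement-category Poisson
#' likelihood).
#'
#' @inheritParams gibbs_update_thetas
#' @param scale proposal SD (> 0).
#' @return list with the updated `state` and logical `accept` per locus.
#' @export
metropolis_update_gamma_i <- function(state, data, scale, priors, cache,
                                      ctrl = NULL) {
  stopifnot(scale >= 0)
  ctrl <- as_prf_control(ctrl)
  r <- .state_rates(state, data, cache, ctrl)
  CR <- as.matrix(data[, c("Kr", "Or", "Hr")])
  gam <- state$loci$gamma_i
  gprop <- gam + rnorm(length(gam), 0, scale)
  gbar_p <- .gbar_all(cache, gprop, state$global$sigma_w, state$global$t_div,
                      r$pair_idx, r$ghq)
  llc <- .ll_rows(CR, state$loci$theta_r * r$gbar, ctrl$clip)
  llp <- .ll_rows(CR, state$loci$theta_r * gbar_p, ctrl$clip)
  logr <- dnorm(gprop, state$global$mu_gamma, state$global$sigma_b, log = TRUE) -
    dnorm(gam, state$global$mu_gamma, state$global$sigma_b, log = TRUE) +
    llp - llc
  accept <- log(runif(length(gam))) < logr
  state$loci$gamma_i[accept] <- gprop[accept]
  list(state = state, accept = accept)
}

#' Metropolis random-walk update of the divergence time
#'
#' Gaussian proposal for `t_div`; proposals outside `(0, t_max)` are rejected
#' outright (uniform prior support), otherwise accepted with the full
#' (silent + replacement) likelihood ratio.
#'
#' @inheritParams metropolis_update_gamma_i
#' @return list with the updated `state` and logical `accept`.
#' @export
metropolis_update_tdiv <- function(state, data, scale, priors, cache,
                                   ctrl = NULL) {
  stopifnot(scale >= 0)
  ctrl <- as_prf_control(ctrl)
  r <- .state_rates(state, data, cache, ctrl)
  CS <- as.matrix(data[, c("Ks", "Os", "Hs")])
  CR <- as.matrix(data[, c("Kr", "Or", "Hr")])
  tp <- state$global$t_div + rnorm(1, 0, scale)
  accept <- FALSE
  if (tp > 0 && tp < priors$t_max) {
    nu0_p <- .nu0_all(cache, tp, r$pair_idx)
    gbar_p <- .gbar_all(cache, state$loci$gamma_i, state$global$sigma_w, tp,
                        r$pair_idx, r$ghq)
    d <- sum(.ll_rows(CS, state$loci$theta_s * nu0_p, ctrl$clip)) +
      sum(.ll_rows(CR, state$loci$theta_r * gbar_p, ctrl$clip)) -
      sum(.ll_rows(CS, state$loci$theta_s * r$nu0, ctrl$clip)) -
      sum(.ll_rows(CR, state$loci$theta_r * r$gbar, ctrl$clip))
    accept <- log(runif(1)) < d
  }
  if (accept) state$global$t_div <- tp
  list(state = state, accept = accept)
}

#' Create the adaptation state for the ADAM hyper update
#'
#' @param window_k acceptance-window length.
#' @param hyper_iso isotropic fallback proposal SD for degenerate
#'   covariances.
#' @return list of class `"adapt_state"` holding the running empirical
#'   covariance accumulator, acceptance window and jump scale.
#' @export
adapt_state <- function(window_k = 100L, hyper_iso = 0.2) {
  structure(list(acc = .cov_init(), window = integer(window_k), win_i = 0L,
                 delta = 1, window_k = as.integer(window_k),
                 hyper_iso = hyper_iso),
            class = "adapt_state")
}

#' One ADAM update of the hyperparameter triple
#'
#' SVD-directed joint Metropolis update of `(mu_gamma, sigma_b, sigma_w)`
#' with proposal covariance `delta * Sigma_t` along the singular directions
#' of the running empirical covariance, followed by the recursive covariance
#' and windowed jump-scale updates. Falls back to an isotropic proposal while
#' the covariance is degenerate.
#'
#' @inheritParams gibbs_update_thetas
#' @param adapt an [adapt_state()].
#' @return list with updated `state`, `adapt` and logical `accept`.
#' @export
adam_update_hypers <- function(state, adapt, data, priors, cache, ctrl = NULL) {
  ctrl <- as_prf_control(ctrl)
  r <- .state_rates(state, data, cache, ctrl)
  CR <- as.matrix(data[, c("Kr", "Or", "Hr")])
  gam <- state$loci$gamma_i
  x <- c(state$global$mu_gamma, state$global$sigma_b, state$global$sigma_w)
  Ct <- .cov_get(adapt$acc)
  sv <- if (is.null(Ct)) NULL else svd(Ct)
  if (is.null(sv) || min(sv$d) < 1e-12) {
    xp <- x + rnorm(3, 0, adapt$hyper_iso)
  } else {
    xp <- x + as.numeric(sv$u %*% (sqrt(adapt$delta * sv$d) * rnorm(3)))
  }
  rll_cur <- sum(.ll_rows(CR, state$loci$theta_r * r$gbar, ctrl$clip))
  lp_cur <- .hyper_lp(x[1], x[2], x[3], gam, priors, rll_cur)
  accept <- FALSE
  if (xp[2] > 0 && xp[3] > 0 && xp[3] < priors$sigma_max) {
    gbar_p <- if (xp[3] != x[3])
      .gbar_all(cache, gam, xp[3], state$global$t_div, r$pair_idx, r$ghq)
    else r$gbar
    rll_p <- sum(.ll_rows(CR, state$loci$theta_r * gbar_p, ctrl$clip))
    lp_p <- .hyper_lp(xp[1], xp[2], xp[3], gam, priors, rll_p)
    accept <- log(runif(1)) < lp_p - lp_cur
  }
  if (accept) {
    state$global$mu_gamma <- xp[1]
    state$global$sigma_b <- xp[2]
    state$global$sigma_w <- xp[3]
  }
  adapt$win_i <- adapt$win_i + 1L
  adapt$window[adapt$win_i] <- as.integer(accept)
  if (adapt$win_i == adapt$window_k) {
    adapt$delta <- adam_jump_scale(mean(adapt$window))
    adapt$win_i <- 0L
  }
  adapt$acc <- .cov_push(adapt$acc, c(state$global$mu_gamma,
                                      state$global$sigma_b,
                                      state$global$sigma_w))
  list(state = state, adapt = adapt, accept = accept)
}
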