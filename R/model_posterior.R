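## Priors and joint posterior of the hierarchical time-dependent PRF model.
##
## Hierarchy: gamma_i ~ N(mu_gamma, sigma_b^2) across loci; within locus i the
## per-mutation selection coefficient is N(gamma_i, sigma_w^2) (already
## integrated into the Poisson means); theta_{s,i}, theta_{r,i} carry gamma
## priors; (mu_gamma, sigma_b^2) a normal-inverse-gamma prior; t_div and
## sigma_w bounded uniforms.

#' Prior configuration
#'
#' Hyperparameters of the prior (all shape/rate/precision hyperparameters
#' default to the "uninformative" 0.001; the uniform upper bounds default to
#' 20, comfortably above every reported estimate).
#'
#' @param alpha_s,beta_s gamma-prior shape/rate for silent mutation rates.
#' @param alpha_r,beta_r gamma-prior shape/rate for replacement rates.
#' @param alpha_0,beta_0,mu_0,n_0 normal-inverse-gamma hyperparameters for
#'   `(mu_gamma, sigma_b^2)`.
#' @param t_max,sigma_max upper bounds of the uniform priors on `t_div` and
#'   `sigma_w`.
#' @param ig_parameterization `"rate"` (default) or `"scale"` for the
#'   inverse-gamma component on `sigma_b^2`.
#' @return list of class `"prior_config"`.
#' @export
prior_config <- function(alpha_s = 0.001, beta_s = 0.001,
                         alpha_r = 0.001, beta_r = 0.001,
                         alpha_0 = 0.001, beta_0 = 0.001,
                         mu_0 = 0.001, n_0 = 0.001,
                         t_max = 20, sigma_max = 20,
                         ig_parameterization = c("rate", "scale")) {
  ig_parameterization <- match.arg(ig_parameterization)
  stopifnot(alpha_s > 0, beta_s > 0, alpha_r > 0, beta_r > 0,
            alpha_0 > 0, beta_0 > 0, n_0 > 0, t_max > 0, sigma_max > 0)
  structure(list(alpha_s = alpha_s, beta_s = beta_s, alpha_r = alpha_r,
                 beta_r = beta_r, alpha_0 = alpha_0, beta_0 = beta_0,
                 mu_0 = mu_0, n_0 = n_0, t_max = t_max,
                 sigma_max = sigma_max,
                 ig_parameterization = ig_parameterization),
            class = "prior_config")
}

# log inverse-gamma density of v (= sigma_b^2)
.lig <- function(v, alpha, beta, param = "rate") {
  if (param == "scale") beta <- 1 / beta
  alpha * log(beta) - lgamma(alpha) - (alpha + 1) * log(v) - beta / v
}

.check_global <- function(global, priors) {
  with(global, is.finite(mu_gamma) && sigma_b > 0 &&
         sigma_w > 0 && sigma_w <= priors$sigma_max &&
         t_div > 0 && t_div <= priors$t_max)
}

#' Log prior density
#'
#' Sum of the locus-level priors (`gamma_i ~ N(mu_gamma, sigma_b^2)`, gamma
#' priors on the two mutation rates) and the hyperpriors (NIG on
#' `(mu_gamma, sigma_b^2)` expressed in the `sigma_b` coordinate, i.e.
#' including the `2 sigma_b` Jacobian, and the bounded uniforms on `t_div`
#' and `sigma_w`). Returns `-Inf` outside the prior support.
#'
#' @param global list with `mu_gamma`, `sigma_b`, `sigma_w`, `t_div`.
#' @param loci data frame with columns `theta_s`, `theta_r`, `gamma_i`.
#' @param priors a [prior_config()].
#' @return log density (finite or `-Inf`).
#' @export
log_prior <- function(global, loci, priors = prior_config()) {
  if (!.check_global(global, priors)) return(-Inf)
  if (nrow(loci) && (any(loci$theta_s <= 0) || any(loci$theta_r <= 0)))
    return(-Inf)
  lp <- .lig(global$sigma_b^2, priors$alpha_0, priors$beta_0,
             priors$ig_parameterization) + log(2 * global$sigma_b) +
    dnorm(global$mu_gamma, priors$mu_0, global$sigma_b / sqrt(priors$n_0),
          log = TRUE) -
    log(priors$t_max) - log(priors$sigma_max)
  if (nrow(loci)) {
    lp <- lp +
      sum(dnorm(loci$gamma_i, global$mu_gamma, global$sigma_b, log = TRUE)) +
      sum(dgamma(loci$theta_s, priors$alpha_s, rate = priors$beta_s, log = TRUE)) +
      sum(dgamma(loci$theta_r, priors$alpha_r, rate = priors$beta_r, log = TRUE))
  }
  lp
}

#' Log likelihood of a counts dataset
#'
#' Sum over loci and the six table categories of Poisson log-pmfs whose means
#' come from [expected_table()]; silent categories use `(gamma = 0,
#' sigma_w = 0)`. Expected counts are floored at `ctrl$clip` before entering
#' the log-pmf.
#'
#' @param global,loci as in [log_prior()].
#' @param data data frame of locus counts (see [read_counts_table()]): columns
#'   `m, n, Ks, Os, Hs, Kr, Or, Hr`.
#' @param ctrl optional [prf_control()].
#' @param cache optional [lambda_cache()] for fast evaluation.
#' @return log likelihood; non-finite inputs propagate as `-Inf`.
#' @export
log_likelihood <- function(global, loci, data, ctrl = NULL, cache = NULL) {
  ctrl <- as_prf_control(ctrl)
  stopifnot(nrow(loci) == nrow(data))
  ll <- 0
  for (i in seq_len(nrow(data))) {
    e <- expected_table(loci$theta_s[i], loci$theta_r[i], loci$gamma_i[i],
                        global$sigma_w, global$t_div,
                        data$m[i], data$n[i], ctrl, cache)
    lam <- pmax(e, ctrl$clip)
    cts <- c(data$Kr[i], data$Or[i], data$Hr[i],
             data$Ks[i], data$Os[i], data$Hs[i])
    ll <- ll + sum(dpois(cts, lam, log = TRUE))
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Log posterior density (up to the normalizing constant)
#'
#' `log_prior + log_likelihood`; `-Inf` propagates. With an empty dataset it
#' equals the log prior.
#'
#' @inheritParams log_likelihood
#' @param priors a [prior_config()].
#' @return log density.
#' @export
log_posterior <- function(global, loci, data, priors = prior_config(),
                          ctrl = NULL, cache = NULL) {
  lp <- log_prior(global, loci, priors)
  if (!is.finite(lp)) return(-Inf)
  if (is.null(data) || nrow(data) == 0) return(lp)
  lp + log_likelihood(global, loci, data, ctrl, cache)
}
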