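## MCMC engine: Gibbs updates for the mutation rates, Metropolis random walks
## for gamma_i and t_div, and the three-phase adaptive-directional
## adaptive-Metropolis (ADAM) scheme for the hyperparameter triple
## (mu_gamma, sigma_b, sigma_w):
##   phase 1  componentwise updates (NIG Gibbs for (mu_gamma, sigma_b),
##            random walks for sigma_w, t_div) to seed an empirical
##            covariance C0;
##   phase 2  joint normal proposals with fixed covariance C0;
##   phase 3  at each step, SVD C_t = D Sigma_t D^T of the running empirical
##            covariance (cumulative over all post-phase-1 states), proposal
##            along the SVD directions with covariance delta * Sigma_t, where
##            delta = exp(2 d (delta_k - 0.3)), d = 3, and delta_k is the
##            acceptance rate over the last `window_k` iterations.

#' Chain configuration
#'
#' Phase lengths and burn-in default to the reference schedule proportions
#' (2.5% / 5% componentwise / fixed-covariance phases, 12.5% burn-in,
#' mirroring 50k / 100k / 250k out of 2M iterations).
#'
#' @param n_iter total number of iterations.
#' @param phase1,phase2 lengths of the componentwise and fixed-covariance
#'   phases (defaults: proportional scaling).
#' @param burn_in discarded prefix (default 12.5% of `n_iter`).
#' @param thin post-burn-in sampling stride.
#' @param window_k acceptance window length for the adaptive jump scale.
#' @param seed RNG seed (the single source of randomness of the run).
#' @param n_subchains number of consecutive subchains the retained draws are
#'   split into (for Gelman-Rubin diagnostics).
#' @param proposal_scales named vector of random-walk SDs: `gamma_i`,
#'   `sigma_w`, `t_div`, and `hyper_iso` (isotropic fallback for degenerate
#'   adaptive covariances).
#' @param nig_gibbs_phase3 keep the NIG Gibbs update for
#'   `(mu_gamma, sigma_b)` alongside the joint ADAM block in phase 3
#'   (default `FALSE`: the joint update fully replaces it).  Retaining the
#'   Gibbs step markedly reduces thinned-sample autocorrelation of the hyper
#'   block on ridge-shaped posteriors.
#' @return list of class `"chain_config"`.
#' @export
chain_config <- function(n_iter = 2e6, phase1 = NULL, phase2 = NULL,
                         burn_in = NULL, thin = 400L, window_k = 100L,
                         seed = 1L, n_subchains = 10L,
                         proposal_scales = c(gamma_i = 1, sigma_w = 0.5,
                                             t_div = 0.2, hyper_iso = 0.2),
                         nig_gibbs_phase3 = FALSE) {
  n_iter <- as.integer(n_iter)
  if (is.null(phase1)) phase1 <- max(10L, as.integer(round(0.025 * n_iter)))
  if (is.null(phase2)) phase2 <- max(10L, as.integer(round(0.05 * n_iter)))
  if (is.null(burn_in)) burn_in <- as.integer(round(0.125 * n_iter))
  stopifnot(phase1 + phase2 <= n_iter, thin >= 1L, window_k >= 1L,
            burn_in < n_iter, n_subchains >= 1L,
            all(c("gamma_i", "sigma_w", "t_div", "hyper_iso") %in%
                  names(proposal_scales)),
            all(proposal_scales > 0))
  structure(list(n_iter = n_iter, phase1 = as.integer(phase1),
                 phase2 = as.integer(phase2), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), window_k = as.integer(window_k),
                 seed = as.integer(seed), n_subchains = as.integer(n_subchains),
                 proposal_scales = proposal_scales,
                 nig_gibbs_phase3 = isTRUE(nig_gibbs_phase3)),
            class = "chain_config")
}

#' ADAM jump scale
#'
#' `delta = exp(2 d (delta_k - 0.3))` with `d = 3`: the windowed-acceptance
#' controlled scaling of the SVD-directed proposal covariance.
#'
#' @param delta_k windowed acceptance rate in `[0, 1]`.
#' @param d parameter dimension (3 for the hyper block).
#' @return positive jump scale.
#' @export
adam_jump_scale <- function(delta_k, d = 3) {
  stopifnot(delta_k >= 0, delta_k <= 1)
  exp(2 * d * (delta_k - 0.3))
}

# running (Welford) mean/covariance accumulator
.cov_init <- function(d = 3L) list(n = 0L, mean = numeric(d),
                                   M2 = matrix(0, d, d))
.cov_push <- function(acc, x) {
  acc$n <- acc$n + 1L
  dlt <- x - acc$mean
  acc$mean <- acc$mean + dlt / acc$n
  acc$M2 <- acc$M2 + outer(dlt, x - acc$mean)
  acc
}
.cov_get <- function(acc) {
  if (acc$n < 2L) return(NULL)
  acc$M2 / (acc$n - 1L)
}

#' Gelman-Rubin potential scale reduction
#'
#' Split-free PSRF across the supplied chains: with within-chain variance `W`
#' and between-chain variance `B` of the chain means,
#' `Rhat = sqrt(((n-1)/n * W + (1 + 1/M) * B / n) / W)`, floored at 1 so that
#' identical subchains give exactly 1.
#'
#' @param subchains list of equal-length numeric vectors, or a matrix with
#'   one chain per column, or a [run_chain()] result (then computed per
#'   parameter across its subchains).
#' @param ... unused.
#' @return named vector of `Rhat` values.
#' @export
gelman_rubin <- function(subchains, ...) {
  if (inherits(subchains, "prf_draws")) {
    sc <- subchain_split(subchains)
    return(vapply(colnames(subchains$draws), function(p)
      gelman_rubin(lapply(sc, function(m) m[, p])), 0))
  }
  if (is.matrix(subchains))
    subchains <- lapply(seq_len(ncol(subchains)), function(j) subchains[, j])
  lens <- vapply(subchains, length, 0L)
  if (length(unique(lens)) != 1L) stop("subchains must have equal lengths")
  n <- lens[1]
  if (n < 10L) stop("subchains too short for a meaningful diagnostic")
  M <- length(subchains)
  if (M < 2L) stop("need at least 2 subchains")
  means <- vapply(subchains, mean, 0)
  W <- mean(vapply(subchains, var, 0))
  B <- n * var(means)
  if (W <= 0) return(1)
  max(1, sqrt(((n - 1) / n * W + (1 + 1 / M) * B / n) / W))
}

#' Split retained draws into consecutive subchains
#'
#' @param fit a [run_chain()] result.
#' @return list of draw matrices (equal lengths; a remainder shorter than a
#'   subchain is dropped from the front).
#' @export
subchain_split <- function(fit) {
  d <- fit$draws
  ns <- fit$config$n_subchains
  len <- nrow(d) %/% ns
  if (len < 1L) stop("not enough retained draws for the requested subchains")
  start <- nrow(d) - ns * len
  lapply(seq_len(ns), function(s)
    d[start + ((s - 1L) * len + 1L):(s * len), , drop = FALSE])
}

# silent nu matrix (L x 3) and replacement gbar matrix (L x 3) helpers;
# one C++ call each (the Gauss-Hermite average over gamma is done in C++)
.gbar_all <- function(cache, gam, sigma_w, t, pair_idx, ghq) {
  g <- cache$gamma_grid
  tg <- cache$t_grid
  gbar_interp_cpp(cache$tbl, as.integer(cache$dims[1:3]),
                  g[1], g[2] - g[1], tg[1], tg[2] - tg[1],
                  as.numeric(gam), sigma_w, t, as.integer(pair_idx) - 1L,
                  ghq$nodes, ghq$weights)
}

.nu0_all <- function(cache, t, pair_idx) {
  .gbar_all(cache, numeric(length(pair_idx)), 0, t, pair_idx,
            list(nodes = 0, weights = 1))
}

.gbar_one <- function(cache, gamma_i, sigma_w, t, pair, ghq) {
  as.numeric(.gbar_all(cache, gamma_i, sigma_w, t, pair, ghq))
}

# Poisson log-lik of count matrix C (L x 3) against mean matrix Lam (L x 3),
# by row
.ll_rows <- function(C, Lam, clip) {
  rowSums(matrix(dpois(as.vector(C), pmax(as.vector(Lam), clip), log = TRUE),
                 nrow(C), 3))
}

# hyper-block log target (everything that depends on (mu_gamma, sigma_b,
# sigma_w) given the rest): NIG prior + gamma_i level + replacement
# likelihood.  rll must be the summed replacement log-likelihood at sigma_w.
.hyper_lp <- function(mu, sb, sw, gam, priors, rll) {
  if (sb <= 0 || sw <= 0 || sw >= priors$sigma_max) return(-Inf)
  .lig(sb^2, priors$alpha_0, priors$beta_0, priors$ig_parameterization) +
    log(2 * sb) +
    dnorm(mu, priors$mu_0, sb / sqrt(priors$n_0), log = TRUE) +
    sum(dnorm(gam, mu, sb, log = TRUE)) + rll
}

#' Run the MCMC sampler
#'
#' Executes the three-phase schedule described above on a counts dataset and
#' returns thinned posterior draws of all parameters. Fully reproducible
#' given `config$seed`.
#'
#' @param data data frame of locus counts (see [read_counts_table()]).
#' @param priors a [prior_config()].
#' @param config a [chain_config()].
#' @param ctrl optional [prf_control()] for the numerical engine.
#' @param cache optional prebuilt [lambda_cache()]; built from the data's
#'   sample sizes and `priors$t_max` when missing.
#' @param adaptive if `FALSE`, phases 2-3 are replaced by the plain
#'   componentwise phase-1 updates throughout (non-adaptive baseline used in
#'   tests).
#' @param verbose print per-phase progress.
#' @return object of class `"prf_draws"`: list with `draws` (matrix, one row
#'   per retained iteration), `accept` (acceptance rates per update type),
#'   `config`, `priors`, `loci` (locus names), and `cache`.
#' @export
run_chain <- function(data, priors = prior_config(), config = chain_config(),
                      ctrl = NULL, cache = NULL, adaptive = TRUE,
                      verbose = FALSE) {
  ctrl <- as_prf_control(ctrl)
  stopifnot(nrow(data) >= 1L)
  if (priors$ig_parameterization != "rate")
    stop("the sampler's NIG Gibbs step requires ig_parameterization = 'rate'")
  set.seed(config$seed)
  L <- nrow(data)
  pairs <- cbind(data$m, data$n)
  if (is.null(cache))
    cache <- lambda_cache(pairs, t_max = priors$t_max, ctrl = ctrl)
  pair_idx <- vapply(seq_len(L), function(i)
    cache_pair_index(cache, data$m[i], data$n[i]), 0L)
  ghq <- gauss_hermite(ctrl$gh_order)
  CS <- as.matrix(data[, c("Ks", "Os", "Hs")])
  CR <- as.matrix(data[, c("Kr", "Or", "Hr")])
  nS <- rowSums(CS)
  nR <- rowSums(CR)
  sc <- config$proposal_scales

  # initialization: method-of-moments thetas at t = 1, hypers (0, 1, 1)
  t_div <- 1.0
  mu <- 0; sb <- 1; sw <- 1
  gam <- numeric(L)
  nu0 <- .nu0_all(cache, t_div, pair_idx)
  gbar <- .gbar_all(cache, gam, sw, t_div, pair_idx, ghq)
  theta_s <- pmax((nS + 0.5) / pmax(rowSums(nu0), 1e-6), 1e-3)
  theta_r <- pmax((nR + 0.5) / pmax(rowSums(gbar), 1e-6), 1e-3)

  llS <- .ll_rows(CS, theta_s * nu0, ctrl$clip)
  llR <- .ll_rows(CR, theta_r * gbar, ctrl$clip)
  if (!all(is.finite(llS)) || !all(is.finite(llR)))
    stop("log posterior not finite at initialization")

  n_iter <- config$n_iter
  p1 <- config$phase1
  p2 <- if (adaptive) config$phase2 else 0L
  n_ret <- (n_iter - config$burn_in) %/% config$thin
  par_names <- c("mu_gamma", "sigma_b", "sigma_w", "t_div",
                 paste0("theta_s.", data$locus), paste0("theta_r.", data$locus),
                 paste0("gamma.", data$locus))
  draws <- matrix(NA_real_, n_ret, length(par_names),
                  dimnames = list(NULL, par_names))

  acc <- c(gamma_i = 0, sigma_w = 0, t_div = 0, hyper = 0)
  try_n <- c(gamma_i = 0, sigma_w = 0, t_div = 0, hyper = 0)

  covacc <- .cov_init()
  C0 <- NULL; C0_chol <- NULL
  win <- integer(config$window_k); win_i <- 0L
  delta <- 1
  ridx <- 0L

  for (iter in seq_len(n_iter)) {
    phase <- if (!adaptive) 1L else if (iter <= p1) 1L
             else if (iter <= p1 + p2) 2L else 3L

    ## --- locus sweep (index order): theta_s, theta_r Gibbs; gamma_i MH ---
    theta_s <- rgamma(L, priors$alpha_s + nS, rate = priors$beta_s + rowSums(nu0))
    theta_r <- rgamma(L, priors$alpha_r + nR, rate = priors$beta_r + rowSums(gbar))
    llS <- .ll_rows(CS, theta_s * nu0, ctrl$clip)
    llR <- .ll_rows(CR, theta_r * gbar, ctrl$clip)

    gprop <- gam + rnorm(L, 0, sc["gamma_i"])
    gbar_p <- .gbar_all(cache, gprop, sw, t_div, pair_idx, ghq)
    llR_p <- .ll_rows(CR, theta_r * gbar_p, ctrl$clip)
    logr <- dnorm(gprop, mu, sb, log = TRUE) - dnorm(gam, mu, sb, log = TRUE) +
      llR_p - llR
    accept <- log(runif(L)) < logr
    gam[accept] <- gprop[accept]
    gbar[accept, ] <- gbar_p[accept, , drop = FALSE]
    llR[accept] <- llR_p[accept]
    acc["gamma_i"] <- acc["gamma_i"] + sum(accept)
    try_n["gamma_i"] <- try_n["gamma_i"] + L

    ## --- hyper block ---
    if (phase == 1L) {
      # NIG Gibbs for (mu_gamma, sigma_b)
      n0p <- priors$n_0 + L
      gbarm <- mean(gam)
      mup <- (priors$n_0 * priors$mu_0 + L * gbarm) / n0p
      a0p <- priors$alpha_0 + L / 2
      b0p <- priors$beta_0 + 0.5 * sum((gam - gbarm)^2) +
        priors$n_0 * L * (gbarm - priors$mu_0)^2 / (2 * n0p)
      sb <- sqrt(1 / rgamma(1, a0p, rate = b0p))
      mu <- rnorm(1, mup, sb / sqrt(n0p))
      # sigma_w random walk
      swp <- sw + rnorm(1, 0, sc["sigma_w"])
      try_n["sigma_w"] <- try_n["sigma_w"] + 1
      if (swp > 0 && swp < priors$sigma_max) {
        gbar_p <- .gbar_all(cache, gam, swp, t_div, pair_idx, ghq)
        llR_p <- .ll_rows(CR, theta_r * gbar_p, ctrl$clip)
        if (log(runif(1)) < sum(llR_p) - sum(llR)) {
          sw <- swp; gbar <- gbar_p; llR <- llR_p
          acc["sigma_w"] <- acc["sigma_w"] + 1
        }
      }
    } else {
      if (config$nig_gibbs_phase3 && phase == 3L) {
        n0p <- priors$n_0 + L
        gbarm <- mean(gam)
        mup <- (priors$n_0 * priors$mu_0 + L * gbarm) / n0p
        a0p <- priors$alpha_0 + L / 2
        b0p <- priors$beta_0 + 0.5 * sum((gam - gbarm)^2) +
          priors$n_0 * L * (gbarm - priors$mu_0)^2 / (2 * n0p)
        sb <- sqrt(1 / rgamma(1, a0p, rate = b0p))
        mu <- rnorm(1, mup, sb / sqrt(n0p))
      }
      # joint update of (mu_gamma, sigma_b, sigma_w)
      x <- c(mu, sb, sw)
      if (phase == 2L) {
        if (is.null(C0_chol)) {
          C0 <- .cov_get(covacc)
          if (is.null(C0)) C0 <- diag(sc["hyper_iso"]^2, 3)
          C0_chol <- tryCatch(chol(C0), error = function(e)
            chol(C0 + diag(1e-8, 3)))
          covacc <- .cov_init()   # restart: covariance from post-phase-1 states
        }
        xp <- x + as.numeric(crossprod(C0_chol, rnorm(3)))
      } else {
        Ct <- .cov_get(covacc)
        sv <- if (is.null(Ct)) NULL else svd(Ct)
        if (is.null(sv) || min(sv$d) < 1e-12) {
          xp <- x + rnorm(3, 0, sc["hyper_iso"])
        } else {
          # Y = D^T X; propose Y' ~ N(Y, delta * Sigma_t); X' = (D^T)^{-1} Y'
          xp <- x + as.numeric(sv$u %*% (sqrt(delta * sv$d) * rnorm(3)))
        }
      }
      try_n["hyper"] <- try_n["hyper"] + 1
      ok <- FALSE
      lp_cur <- .hyper_lp(x[1], x[2], x[3], gam, priors, sum(llR))
      if (xp[2] > 0 && xp[3] > 0 && xp[3] < priors$sigma_max) {
        if (xp[3] != sw) {
          gbar_p <- .gbar_all(cache, gam, xp[3], t_div, pair_idx, ghq)
          llR_p <- .ll_rows(CR, theta_r * gbar_p, ctrl$clip)
        } else {
          gbar_p <- gbar; llR_p <- llR
        }
        lp_prop <- .hyper_lp(xp[1], xp[2], xp[3], gam, priors, sum(llR_p))
        if (log(runif(1)) < lp_prop - lp_cur) {
          mu <- xp[1]; sb <- xp[2]; sw <- xp[3]
          gbar <- gbar_p; llR <- llR_p
          ok <- TRUE
        }
      }
      if (ok) acc["hyper"] <- acc["hyper"] + 1
      if (phase == 3L) {
        win_i <- win_i + 1L
        win[win_i] <- as.integer(ok)
        if (win_i == config$window_k) {
          delta <- adam_jump_scale(mean(win))
          win_i <- 0L
        }
      }
    }
    if (iter > p1) covacc <- .cov_push(covacc, c(mu, sb, sw))

    ## --- t_div random walk ---
    tp <- t_div + rnorm(1, 0, sc["t_div"])
    try_n["t_div"] <- try_n["t_div"] + 1
    if (tp > 0 && tp < priors$t_max) {
      nu0_p <- .nu0_all(cache, tp, pair_idx)
      gbar_p <- .gbar_all(cache, gam, sw, tp, pair_idx, ghq)
      llS_p <- .ll_rows(CS, theta_s * nu0_p, ctrl$clip)
      llR_p <- .ll_rows(CR, theta_r * gbar_p, ctrl$clip)
      if (log(runif(1)) < sum(llS_p) + sum(llR_p) - sum(llS) - sum(llR)) {
        t_div <- tp; nu0 <- nu0_p; gbar <- gbar_p; llS <- llS_p; llR <- llR_p
        acc["t_div"] <- acc["t_div"] + 1
      }
    }

    ## --- record ---
    if (iter > config$burn_in && (iter - config$burn_in) %% config$thin == 0L) {
      ridx <- ridx + 1L
      draws[ridx, ] <- c(mu, sb, sw, t_div, theta_s, theta_r, gam)
    }
    if (verbose && iter %% max(1L, n_iter %/% 10L) == 0L)
      message(sprintf("iter %d/%d (phase %d) delta=%.3g t=%.3g mu=%.3g",
                      iter, n_iter, phase, delta, t_div, mu))
  }

  structure(list(draws = draws[seq_len(ridx), , drop = FALSE],
                 accept = ifelse(try_n > 0, acc / pmax(try_n, 1), NA),
                 config = config, priors = priors, ctrl = ctrl,
                 loci = data$locus, data = data, cache = cache,
                 jump_scale = delta),
            class = "prf_draws")
}
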