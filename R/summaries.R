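## Posterior post-processing: medians and credible intervals, the three
## positively-selected population-proportion integrals, per-class
## aggregation, and divergence-time conversion to calendar years.

#' Posterior medians and credible intervals
#'
#' Equal-tailed interval at the given level, computed by default from the
#' final subchain of the retained draws (set `subchain = "all"` to pool).
#'
#' @param draws a [run_chain()] result, or a numeric matrix of draws.
#' @param level credible level in `[0, 1]` (default 0.95; 0 collapses the
#'   interval to the median).
#' @param subchain `"last"` or `"all"`.
#' @return data frame with `parameter`, `median`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws, level = 0.95, subchain = c("last", "all")) {
  subchain <- match.arg(subchain)
  m <- if (inherits(draws, "prf_draws")) {
    if (subchain == "last") subchain_split(draws)[[draws$config$n_subchains]]
    else draws$draws
  } else as.matrix(draws)
  if (nrow(m) == 0) stop("empty draws")
  stopifnot(level >= 0, level <= 1)
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  q <- apply(m, 2, quantile, probs = probs, names = FALSE)
  data.frame(parameter = colnames(m), median = q[2, ],
             lower = q[1, ], upper = q[3, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Population proportion of beneficial new mutations
#'
#' `P(gamma > 0)` under `N(gamma_i, sigma_w^2)`:
#' `1 - Phi(-gamma_i / sigma_w)`. For `sigma_w = 0` the degenerate indicator
#' `gamma_i > 0`, with the tie at `gamma_i = 0` set to 0.5 by continuity.
#'
#' @param gamma_i locus mean selection coefficient (vectorized).
#' @param sigma_w within-locus SD (>= 0).
#' @return probability in `[0, 1]`.
#' @export
prop_beneficial_new <- function(gamma_i, sigma_w) {
  stopifnot(sigma_w >= 0)
  if (sigma_w == 0) return(ifelse(gamma_i > 0, 1, ifelse(gamma_i < 0, 0, 0.5)))
  pnorm(gamma_i / sigma_w)
}

# Half-line over full-line ratio of the normal expectation of a Lambda_j
# combination.  lamfun(gvec) returns the Lambda combination; numerator by
# Gauss-Legendre on [0, upper], denominator by Gauss-Hermite.
.prop_ratio <- function(lamfun, gamma_i, sigma_w, ctrl) {
  if (sigma_w == 0) {
    if (gamma_i > 0) return(1)
    if (gamma_i < 0) return(0)
    return(0.5)
  }
  den <- expect_over_gamma(lamfun, gamma_i, sigma_w, max(ctrl$gh_order, 48L))
  # composite Gauss-Legendre on [0, upper] with panel breaks around the bump
  upper <- max(gamma_i + 10 * sigma_w, 1e-3)
  brk <- sort(unique(pmin(pmax(c(0, gamma_i + c(-8, -2, 0, 2, 8) * sigma_w,
                                 upper), 0), upper)))
  num <- 0
  for (j in seq_len(length(brk) - 1)) {
    if (brk[j + 1] <= brk[j]) next
    gl <- gauss_legendre(max(ctrl$gl_order, 48L), brk[j], brk[j + 1])
    num <- num + sum(gl$weights * lamfun(gl$nodes) *
                       dnorm(gl$nodes, gamma_i, sigma_w))
  }
  if (den <= 0) stop("vanishing denominator in population-proportion ratio")
  min(max(num / den, 0), 1)
}

.lam_eval <- function(js, t, m, n, ctrl, cache) {
  if (!is.null(cache)) {
    p <- cache_pair_index(cache, m, n)
    function(gvec) {
      nu <- nu_eval(cache, gvec, t, p)
      s1 <- vapply(gvec, .s1, 0)
      as.numeric(nu[, js, drop = FALSE] %*% rep(1, length(js))) * s1
    }
  } else {
    function(gvec) {
      v <- .nu_direct(gvec, t, m, n, ctrl)
      s1 <- vapply(gvec, .s1, 0)
      as.numeric(v[, js, drop = FALSE] %*% rep(1, length(js))) * s1
    }
  }
}

#' Population proportion of sample polymorphisms due to positive selection
#'
#' Ratio of the half-line to full-line normal expectations of
#' `Lambda_2 + Lambda_3`.
#'
#' @param gamma_i locus mean selection coefficient.
#' @param sigma_w within-locus SD (>= 0).
#' @param t divergence time.
#' @param m,n sample sizes.
#' @param ctrl optional [prf_control()].
#' @param cache optional [lambda_cache()].
#' @return probability in `[0, 1]`.
#' @export
prop_beneficial_poly <- function(gamma_i, sigma_w, t, m, n, ctrl = NULL,
                                 cache = NULL) {
  ctrl <- as_prf_control(ctrl)
  .prop_ratio(.lam_eval(2:3, t, m, n, ctrl, cache), gamma_i, sigma_w, ctrl)
}

#' Population proportion of fixed differences due to positive selection
#'
#' As [prop_beneficial_poly()] with `Lambda_1`.
#' @inheritParams prop_beneficial_poly
#' @return probability in `[0, 1]`.
#' @export
prop_beneficial_fixed <- function(gamma_i, sigma_w, t, m, n, ctrl = NULL,
                                  cache = NULL) {
  ctrl <- as_prf_control(ctrl)
  .prop_ratio(.lam_eval(1L, t, m, n, ctrl, cache), gamma_i, sigma_w, ctrl)
}

#' Convert divergence time to calendar years
#'
#' @param t_div divergence time in units of N_e generations.
#' @param ne_generation_span calendar span of N_e generations, in million
#'   years (default 0.645, the Drosophila value).
#' @return divergence time in million years.
#' @export
divergence_time_years <- function(t_div, ne_generation_span = 0.645) {
  stopifnot(t_div >= 0, ne_generation_span > 0)
  t_div * ne_generation_span
}

#' Full posterior summary report
#'
#' Global-parameter medians and credible intervals, per-locus gamma summaries
#' sorted by the median, the three positively-selected population proportions
#' (computed per retained draw per locus, summarized by medians, and
#' aggregated across loci and per expression class by the median), and the
#' divergence time in million years.
#'
#' @param fit a [run_chain()] result.
#' @param level credible level.
#' @param subchain `"last"` (default) or `"all"`.
#' @param ne_generation_span million years per N_e generations.
#' @return list of class `"prf_summary"` with elements `global`, `loci`,
#'   `proportions`, `class_proportions`, `divergence_myr`.
#' @export
summary_report <- function(fit, level = 0.95, subchain = c("last", "all"),
                           ne_generation_span = 0.645) {
  stopifnot(inherits(fit, "prf_draws"))
  subchain <- match.arg(subchain)
  m <- if (subchain == "last")
    subchain_split(fit)[[fit$config$n_subchains]] else fit$draws
  glob <- posterior_summary(m[, c("mu_gamma", "sigma_b", "sigma_w", "t_div")],
                            level)
  L <- length(fit$loci)
  gcols <- paste0("gamma.", fit$loci)
  gl <- posterior_summary(m[, gcols, drop = FALSE], level)
  gl$locus <- fit$loci
  gl$class <- fit$data$class
  med_by_locus <- gl$median
  gl <- gl[order(gl$median), ]

  # proportions per draw per locus, median over draws
  sw <- m[, "sigma_w"]
  td <- m[, "t_div"]
  pr <- matrix(0, L, 3, dimnames = list(fit$loci, c("new", "poly", "fixed")))
  for (i in seq_len(L)) {
    g <- m[, gcols[i]]
    pnew <- pnorm(g / sw)
    ppoly <- numeric(length(g))
    pfix <- numeric(length(g))
    for (k in seq_along(g)) {
      ppoly[k] <- prop_beneficial_poly(g[k], sw[k], td[k],
                                       fit$data$m[i], fit$data$n[i],
                                       fit$ctrl, fit$cache)
      pfix[k] <- prop_beneficial_fixed(g[k], sw[k], td[k],
                                       fit$data$m[i], fit$data$n[i],
                                       fit$ctrl, fit$cache)
    }
    pr[i, ] <- c(median(pnew), median(ppoly), median(pfix))
  }
  cls <- fit$data$class
  agg <- function(idx) apply(pr[idx, , drop = FALSE], 2, median)
  groups <- c(list(all = seq_len(L)),
              lapply(setNames(nm = unique(cls)), function(cl) which(cls == cl)))
  class_prop <- do.call(rbind, lapply(groups, agg))
  # fraction of loci with positive posterior-median gamma, per class
  pos <- tapply(med_by_locus > 0, cls, mean)

  structure(list(global = glob, loci = gl, proportions = pr,
                 class_proportions = class_prop,
                 frac_positive_median = pos,
                 divergence_myr = divergence_time_years(
                   glob$median[glob$parameter == "t_div"], ne_generation_span),
                 level = level),
            class = "prf_summary")
}

#' @export
print.prf_summary <- function(x, ...) {
  cat("Global parameters (median [", 100 * x$level, "% CI])\n", sep = "")
  with(x$global, for (i in seq_along(parameter))
    cat(sprintf("  %-9s %8.3f [%8.3f, %8.3f]\n", parameter[i], median[i],
                lower[i], upper[i])))
  cat(sprintf("Divergence time: %.3f million years\n", x$divergence_myr))
  cat("Median positively-selected proportions (new / poly / fixed):\n")
  print(round(x$class_proportions, 3))
  invisible(x)
}
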