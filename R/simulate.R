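## Model-faithful synthetic-data generator reproducing the three-step
## simulation-study procedure: fix the four global parameters; per locus draw
## mutation rates from continuous uniforms, sample sizes from discrete
## uniforms and a locus-mean selection coefficient gamma_m ~ N(mu_gamma,
## sigma_b^2); then draw the six table counts from Poissons whose means come
## from the model's expected table.

#' Simulation design
#'
#' Defaults state the reference simulation-study world: 30 loci, global truth
#' `(mu_gamma, sigma_b, sigma_w, t_div) = (-6.82, 3.78, 2.56, 4.38)` (the
#' first simulated set), mutation rates uniform on (0.5, 5) and sample sizes
#' discrete-uniform on 5..12 (bracketing the seven-to-twelve alignments of
#' the Drosophila data); the uniform ranges are not reported for the original
#' simulated sets and are package choices.
#'
#' @param L number of loci.
#' @param global_truth named vector/list with `mu_gamma`, `sigma_b`,
#'   `sigma_w`, `t_div`.
#' @param theta_s_range,theta_r_range continuous-uniform bounds for the
#'   scaled mutation rates.
#' @param m_range,n_range discrete-uniform bounds (inclusive) for the sample
#'   sizes.
#' @param seed RNG seed.
#' @return list of class `"sim_design"`.
#' @export
sim_design <- function(L = 30L,
                       global_truth = c(mu_gamma = -6.82, sigma_b = 3.78,
                                        sigma_w = 2.56, t_div = 4.38),
                       theta_s_range = c(0.5, 5), theta_r_range = c(0.5, 5),
                       m_range = c(5L, 12L), n_range = c(5L, 12L),
                       seed = 1L) {
  gt <- as.list(global_truth)
  stopifnot(L >= 1L,
            all(c("mu_gamma", "sigma_b", "sigma_w", "t_div") %in% names(gt)),
            gt$sigma_b > 0, gt$sigma_w >= 0, gt$t_div >= 0,
            diff(theta_s_range) >= 0, theta_s_range[1] >= 0,
            diff(theta_r_range) >= 0, theta_r_range[1] >= 0,
            m_range[1] >= 1, m_range[2] >= m_range[1],
            n_range[1] >= 1, n_range[2] >= n_range[1])
  structure(list(L = as.integer(L), global_truth = gt,
                 theta_s_range = theta_s_range, theta_r_range = theta_r_range,
                 m_range = as.integer(m_range), n_range = as.integer(n_range),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate a synthetic polymorphism/divergence dataset
#'
#' Per locus: `theta_s, theta_r` from the design's uniforms; `m, n` from the
#' discrete uniforms; `gamma_m ~ N(mu_gamma, sigma_b^2)`; the six counts from
#' independent Poissons with means `expected_table(theta_s, theta_r, gamma_m,
#' sigma_w, t_div, m, n)` (silent means at gamma = 0). `mode = "fixed"` is
#' the literal sensitivity variant: a single per-locus gamma is drawn from
#' `N(gamma_m, sigma_w^2)` and the fixed-effects means (`sigma_w = 0`) at
#' that gamma are used instead.
#'
#' @param design a [sim_design()].
#' @param ctrl optional [prf_control()].
#' @param cache optional [lambda_cache()] (built on the fly when missing and
#'   `L` is large enough to warrant it).
#' @param mode `"marginal"` (default, model-consistent) or `"fixed"`.
#' @return list with `data` (counts data frame as from
#'   [read_counts_table()]) and `truth` (global truth plus the per-locus
#'   `theta_s`, `theta_r`, `gamma_m` record).
#' @export
generate_dataset <- function(design, ctrl = NULL, cache = NULL,
                             mode = c("marginal", "fixed")) {
  mode <- match.arg(mode)
  ctrl <- as_prf_control(ctrl)
  set.seed(design$seed)
  gt <- design$global_truth
  L <- design$L
  theta_s <- runif(L, design$theta_s_range[1], design$theta_s_range[2])
  theta_r <- runif(L, design$theta_r_range[1], design$theta_r_range[2])
  # sample.int avoids the sample(x) scalar pitfall for degenerate ranges
  m <- design$m_range[1] +
    sample.int(design$m_range[2] - design$m_range[1] + 1L, L, replace = TRUE) - 1L
  n <- design$n_range[1] +
    sample.int(design$n_range[2] - design$n_range[1] + 1L, L, replace = TRUE) - 1L
  gamma_m <- rnorm(L, gt$mu_gamma, gt$sigma_b)
  if (is.null(cache) && L >= 10L)
    cache <- lambda_cache(cbind(m, n), t_max = max(gt$t_div * 2, 1),
                          ctrl = ctrl)
  counts <- matrix(0L, L, 6)
  gamma_used <- gamma_m
  for (i in seq_len(L)) {
    if (mode == "fixed") {
      gamma_used[i] <- rnorm(1, gamma_m[i], gt$sigma_w)
      e <- expected_table(theta_s[i], theta_r[i], gamma_used[i], 0,
                          gt$t_div, m[i], n[i], ctrl, cache)
    } else {
      e <- expected_table(theta_s[i], theta_r[i], gamma_m[i], gt$sigma_w,
                          gt$t_div, m[i], n[i], ctrl, cache)
    }
    if (!all(is.finite(e))) stop("non-finite Poisson mean at locus ", i)
    counts[i, ] <- rpois(6, e[c("e_Ks", "e_Os", "e_Hs",
                                "e_Kr", "e_Or", "e_Hr")])
  }
  data <- data.frame(m = m, n = n,
                     Ks = counts[, 1], Os = counts[, 2], Hs = counts[, 3],
                     Kr = counts[, 4], Or = counts[, 5], Hr = counts[, 6],
                     locus = sprintf("sim%03d", seq_len(L)),
                     class = "unknown",
                     stringsAsFactors = FALSE)
  truth <- list(global = gt,
                loci = data.frame(locus = data$locus, theta_s = theta_s,
                                  theta_r = theta_r, gamma_m = gamma_m,
                                  gamma_used = gamma_used,
                                  stringsAsFactors = FALSE),
                mode = mode, seed = design$seed)
  list(data = data, truth = truth)
}
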