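## Precomputed (gamma, t) table of nu_j = Lambda_j / s(1).
##
## One Crank-Nicolson march per gamma node covers the whole divergence-time
## range (intermediate times are recorded along the way), after which every
## likelihood evaluation in the MCMC reduces to local-cubic interpolation.
## The uncached expected_table() path remains the reference implementation;
## tests bound the interpolation error against it.

#' Precompute the Lambda table used by the sampler
#'
#' Builds a dense table of `Lambda_j(gamma, t, m, n) / s(1)` over a uniform
#' `(gamma, t)` grid for every distinct sample-size pair in the data, to be
#' queried by [nu_eval()] via bicubic (Catmull-Rom) interpolation. Queries
#' beyond the gamma range are linearly extrapolated and floored at zero.
#'
#' @param pairs two-column matrix (or data frame) of sample sizes `(m, n)`;
#'   order within a pair is irrelevant (the Lambdas are symmetric).
#' @param t_max upper end of the divergence-time range (lower end is 0).
#' @param ctrl optional [prf_control()]; its `grid_points` and quadrature
#'   orders govern the underlying solves, and `time_steps` the total number
#'   of Crank-Nicolson steps across `[0, t_max]`.
#' @param gamma_range range of the gamma grid.
#' @param n_gamma,n_t numbers of gamma and time nodes.
#' @return object of class `"lambda_cache"`.
#' @export
lambda_cache <- function(pairs, t_max, ctrl = NULL,
                         gamma_range = c(-100, 100), n_gamma = 241L,
                         n_t = 81L) {
  ctrl <- as_prf_control(ctrl)
  stopifnot(t_max > 0, n_gamma >= 4L, n_t >= 4L,
            gamma_range[2] > gamma_range[1])
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]),
               sep = ":")
  ukey <- unique(key)
  upairs <- do.call(rbind, lapply(strsplit(ukey, ":"), as.integer))
  gamma_grid <- seq(gamma_range[1], gamma_range[2], length.out = n_gamma)
  t_grid <- seq(0, t_max, length.out = n_t)
  substeps <- max(1L, as.integer(ceiling(ctrl$time_steps / (n_t - 1L))))
  dt <- t_max / ((n_t - 1L) * substeps)
  grid <- diffusion_grid(ctrl$grid_points)
  tbl <- array(0, dim = c(n_gamma, n_t, nrow(upairs), 3L))
  for (i in seq_len(n_gamma)) {
    blk <- .lambda_nu_block(gamma_grid[i], t_grid, upairs, ctrl, grid, dt)
    tbl[i, , , ] <- aperm(blk, c(3, 1, 2))
  }
  # stored in log space: nu_1 is near-exponential in gamma and nu_3 in t, so
  # local cubics in log coordinates are far more accurate than in the raw
  # values; exact zeros become exp(-690) ~ 0 after interpolation
  tbl <- log(pmax(tbl, 1e-300))
  structure(list(tbl = as.numeric(tbl), dims = dim(tbl),
                 gamma_grid = gamma_grid, t_grid = t_grid,
                 pair_key = ukey, pairs = upairs, ctrl = ctrl),
            class = "lambda_cache")
}

#' Pair index of a sample-size pair inside a Lambda cache
#' @param cache a [lambda_cache()].
#' @param m,n sample sizes.
#' @return integer index for use with [nu_eval()].
#' @export
cache_pair_index <- function(cache, m, n) {
  i <- match(paste(min(m, n), max(m, n), sep = ":"), cache$pair_key)
  if (is.na(i)) stop("sample-size pair (", m, ",", n, ") not in cache")
  i
}

#' Interpolate cached nu values
#'
#' @param cache a [lambda_cache()].
#' @param gamma_vec gamma values (vectorized).
#' @param t divergence time (within `[0, t_max]`).
#' @param pair pair index from [cache_pair_index()].
#' @return `length(gamma_vec) x 3` matrix of `Lambda_j / s(1)` values.
#' @export
nu_eval <- function(cache, gamma_vec, t, pair) {
  g <- cache$gamma_grid
  tg <- cache$t_grid
  nu_interp_cpp(cache$tbl, as.integer(cache$dims[1:3]),
                g[1], g[2] - g[1], tg[1], tg[2] - tg[1],
                as.numeric(gamma_vec), t, as.integer(pair) - 1L)
}
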