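## Wright-Fisher diffusion numerics: scale function, speed density and the
## Crank-Nicolson transition-density solver.  The diffusion is
##   du/dt = x(1-x) u'' + gamma x(1-x) u'
## with absorbing boundaries, time measured in units of N_e generations and
## gamma = N_e * s the scaled (genic) selection coefficient.

#' Scale function of the selective Wright-Fisher diffusion
#'
#' `s(x) = (1 - exp(-gamma * x)) / gamma`, with the neutral limit `s(x) = x`.
#' `s(x)/s(1)` is the fixation probability from initial frequency `x`.
#'
#' @param x frequency in `[0,1]` (vectorized).
#' @param gamma scaled selection coefficient.
#' @param gamma_tol series-branch threshold on `|gamma|`.
#' @return scale-function values.
#' @export
scale_function <- function(x, gamma, gamma_tol = 1e-8) {
  stopifnot(all(x >= 0 & x <= 1))
  if (abs(gamma) < gamma_tol) {
    # series: x - gamma x^2/2 + gamma^2 x^3/6
    x * (1 - gamma * x / 2 + gamma^2 * x^2 / 6)
  } else {
    -expm1(-gamma * x) / gamma
  }
}

# s(1), stable for all gamma
.s1 <- function(gamma, gamma_tol = 1e-8) {
  if (abs(gamma) < gamma_tol) 1 - gamma / 2 + gamma^2 / 6 else -expm1(-gamma) / gamma
}

# s(x)/s(1), stable for large |gamma|
.sratio <- function(x, gamma, gamma_tol = 1e-8) {
  if (abs(gamma) < gamma_tol) {
    x * (1 - gamma * x / 2 + gamma^2 * x^2 / 6) / (1 - gamma / 2 + gamma^2 / 6)
  } else {
    expm1(-gamma * x) / expm1(-gamma)
  }
}

# (s(1) - s(x)) * speed_density(x): the PRF equilibrium weight, computed in a
# form stable for large |gamma|:
#   (1 - exp(-gamma*(1-x))) / (gamma * x * (1-x))          ["gamma_x"]
.wx <- function(x, gamma, ctrl) {
  if (ctrl$speed_exponent == "gamma_x") {
    if (abs(gamma) < ctrl$gamma_tol) {
      (1 - gamma * (1 - x) / 2 + gamma^2 * (1 - x)^2 / 6) / x
    } else {
      -expm1(-gamma * (1 - x)) / (gamma * x * (1 - x))
    }
  } else {
    s1 <- .s1(gamma, ctrl$gamma_tol)
    (s1 - scale_function(x, gamma, ctrl$gamma_tol)) * exp(gamma) / (x * (1 - x))
  }
}

#' Speed density of the Wright-Fisher diffusion
#'
#' Default form `exp(gamma * x) / (x * (1 - x))` (the exponent `gamma * x` is
#' the one consistent with the drift `gamma x(1-x)` and the scale function; a
#' literal constant exponent `exp(gamma)` is available through
#' `prf_control(speed_exponent = "gamma_const")`). Neutral case:
#' `1 / (x * (1 - x))`.
#'
#' @param x frequency strictly inside (0,1) (vectorized).
#' @param gamma scaled selection coefficient.
#' @param ctrl optional [prf_control()].
#' @return speed-density values.
#' @export
speed_density <- function(x, gamma, ctrl = NULL) {
  ctrl <- as_prf_control(ctrl)
  if (any(x <= 0 | x >= 1)) stop("speed_density is defined on the open interval (0,1)")
  if (ctrl$speed_exponent == "gamma_x") {
    exp(gamma * x) / (x * (1 - x))
  } else {
    exp(gamma) / (x * (1 - x))
  }
}

#' Uniform interior frequency grid for the Crank-Nicolson solver
#'
#' @param n number of interior points.
#' @param time_step optional positive PDE time increment stored with the grid
#'   (when `NULL` the solver derives it as `t / time_steps`).
#' @return object of class `"diffusion_grid"` with elements `x` (interior
#'   points), `h` (spacing) and `time_step`.
#' @export
diffusion_grid <- function(n = 400L, time_step = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 3L, is.null(time_step) || time_step > 0)
  h <- 1 / (n + 1)
  structure(list(x = seq_len(n) * h, h = h, time_step = time_step),
            class = "diffusion_grid")
}

.check_grid <- function(grid) {
  if (!inherits(grid, "diffusion_grid")) stop("invalid grid: use diffusion_grid()")
  x <- grid$x
  if (length(x) < 3L || any(diff(x) <= 0) || x[1] <= 0 || x[length(x)] >= 1)
    stop("invalid grid: points must be strictly increasing inside (0,1)")
  if (max(abs(diff(x) - grid$h)) > 1e-12 * grid$h)
    stop("invalid grid: the Crank-Nicolson solver requires uniform spacing")
  invisible(grid)
}

# internal driver: march K initial columns to the times in t_vec (multiples of
# dt), optionally accumulating the fixation flux integral for column flux_col
# (1-based; that column must hold the action of s(y)/s(1)).  phi_state
# carries (Phi, phi_prev) across segmented marches.
.cn_march_seg <- function(gamma, grid, F, t_vec, dt, flux_col, t_off,
                          phi_state) {
  steps <- as.integer(round((t_vec - t_off) / dt))
  if (length(steps) && max(abs(steps * dt - (t_vec - t_off))) >
        1e-8 * max(dt, t_vec))
    stop("recording times must be multiples of the time step")
  aux <- c(0, 0, 1, phi_state)
  if (flux_col > 0) {
    s1 <- .s1(gamma)
    aux <- c(1 / scale_function(grid$x[1], gamma),
             1 / scale_function(grid$x[2], gamma), s1, phi_state)
  }
  cn_march_cpp(gamma, grid$x, F, steps, dt, flux_col - 1L, aux)
}

# single- or two-segment march: when the time range extends well beyond 1,
# the initial transient (boundary-incompatible data, fast legacy decay) is
# resolved with an 8x finer step on [0, ~1] before switching to the coarse
# step.  Recording times must be multiples of dt.
.cn_march <- function(gamma, grid, F, t_vec, dt, flux_col = -1L) {
  .check_grid(grid)
  tmax <- max(t_vec)
  t_b <- dt * floor(min(1, tmax / 2) / dt)
  if (tmax <= 2 * dt || t_b < dt || dt <= 0.02) {
    return(.cn_march_seg(gamma, grid, F, t_vec, dt, flux_col, 0, c(0, 1)))
  }
  early <- t_vec[t_vec <= t_b]
  late <- t_vec[t_vec > t_b]
  r1 <- .cn_march_seg(gamma, grid, F, sort(unique(c(early, t_b))), dt / 8,
                      flux_col, 0, c(0, 1))
  n1 <- dim(r1$u)[3]
  F2 <- matrix(r1$u[, , n1], nrow(F), ncol(F))
  r2 <- .cn_march_seg(gamma, grid, F2, late, dt, flux_col, t_b, r1$phi_state)
  keep <- seq_len(length(early))
  u <- array(0, dim = c(dim(F), length(t_vec)))
  if (length(early)) u[, , keep] <- r1$u[, , keep, drop = FALSE]
  if (length(late)) u[, , length(early) + seq_along(late)] <- r2$u
  list(u = u, Phi = c(r1$Phi[keep], r2$Phi), phi_state = r2$phi_state)
}

#' Solve for the transition-density action of the diffusion
#'
#' Returns `u(t, x) = integral p(t, x, y) f(y) m(dy)` on the grid, obtained as
#' the Crank-Nicolson solution of the diffusion equation with absorbing
#' boundary conditions `u(t,0) = u(t,1) = 0` and initial value `u(0,x) = f(x)`.
#' At `t = 0` the initial condition is returned exactly.
#'
#' @param gamma scaled selection coefficient.
#' @param t elapsed time in units of N_e generations (>= 0).
#' @param f continuous function on `[0,1]`, or a numeric vector of values on
#'   `grid$x`.
#' @param grid a [diffusion_grid()]; defaults to `ctrl$grid_points` points.
#' @param ctrl optional [prf_control()]; `ctrl$time_steps` sets the number of
#'   time steps (step `t / time_steps`) unless the grid carries a `time_step`.
#' @return numeric vector of `u(t, x)` on `grid$x`.
#' @export
solve_transition <- function(gamma, t, f, grid = NULL, ctrl = NULL) {
  ctrl <- as_prf_control(ctrl)
  if (is.null(grid)) grid <- diffusion_grid(ctrl$grid_points)
  .check_grid(grid)
  stopifnot(t >= 0)
  f0 <- if (is.function(f)) f(grid$x) else as.numeric(f)
  if (length(f0) != length(grid$x)) stop("initial values must match the grid")
  if (!all(is.finite(f0))) stop("non-finite initial values")
  if (t == 0) return(f0)
  dt <- if (!is.null(grid$time_step)) grid$time_step else t / ctrl$time_steps
  n_steps <- max(1L, as.integer(ceiling(t / dt - 1e-9)))
  dt <- t / n_steps
  res <- .cn_march(gamma, grid, matrix(f0, ncol = 1), t, dt)
  u <- res$u[, 1, 1]
  if (!all(is.finite(u))) stop("tridiagonal solve failed: non-finite solution")
  u
}

#' Fixation flux kernel
#'
#' The limit `lim_{x -> 0} p(u, x, y) / s(x)`, the rate kernel with which
#' newly arisen mutations (entering at frequency `0+`) are found at frequency
#' `y` a time `u` later. Computed by representing `p(u, ., y)` as the solution
#' started from a grid delta at `y` (the transition density is symmetric in
#' its space arguments with respect to the speed measure), evaluating
#' `p(u, x0, y)/s(x0)` at the first grid points and extrapolating linearly to
#' `x0 = 0`. A warning of class `"tprf_flux_extrapolation"` is signalled when
#' the two- and three-point extrapolations disagree beyond `ctrl$flux_rtol`.
#'
#' @param gamma scaled selection coefficient.
#' @param u elapsed time (>= 0) in N_e generations.
#' @param y frequency strictly inside (0,1).
#' @param grid optional [diffusion_grid()].
#' @param ctrl optional [prf_control()].
#' @return nonnegative kernel value.
#' @export
fixation_flux_kernel <- function(gamma, u, y, grid = NULL, ctrl = NULL) {
  ctrl <- as_prf_control(ctrl)
  if (is.null(grid)) grid <- diffusion_grid(ctrl$grid_points)
  .check_grid(grid)
  stopifnot(u >= 0, y > 0, y < 1)
  x <- grid$x
  k <- which.min(abs(x - y))
  f0 <- numeric(length(x))
  # delta with respect to the speed measure: mass 1 at node k
  f0[k] <- 1 / (speed_density(x[k], gamma, ctrl) * grid$h)
  if (u == 0) {
    # delta at y carries no mass near 0 for y in the interior
    return(0)
  }
  uu <- solve_transition(gamma, u, f0, grid, ctrl)
  p <- uu[1:3] / scale_function(x[1:3], gamma, ctrl$gamma_tol)
  v12 <- 2 * p[1] - p[2]
  v23 <- 3 * p[2] - 2 * p[3]
  v <- max(v12, 0)
  ref <- max(abs(v12), abs(v23), 1e-12)
  if (abs(v12 - v23) > 10 * ctrl$flux_rtol * ref) {
    warning(warningCondition(
      sprintf("flux extrapolations disagree: %.6g vs %.6g", v12, v23),
      class = "tprf_flux_extrapolation"))
  }
  v
}

## interpolation matrix from grid values (with implicit zero boundaries) to
## arbitrary points, via natural cubic splines; memoised.
.interp_cache <- new.env(parent = emptyenv())

.interp_matrix <- function(grid, xout) {
  key <- paste0("B", length(grid$x), "_", length(xout), "_",
                format(sum(xout), digits = 17))
  B <- .interp_cache[[key]]
  if (!is.null(B)) return(B)
  G <- length(grid$x)
  xs <- c(0, grid$x, 1)
  B <- matrix(0, length(xout), G)
  e <- numeric(G + 2)
  for (j in seq_len(G)) {
    e[j + 1] <- 1
    B[, j] <- stats::splinefun(xs, e, method = "natural")(xout)
    e[j + 1] <- 0
  }
  .interp_cache[[key]] <- B
  B
}
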