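#' Numerical control parameters
#'
#' Collects every tunable numerical knob of the diffusion/expected-count
#' machinery in one validated list. Defaults follow the package's reference
#' configuration: 400 interior Crank-Nicolson grid points with time step
#' `t/400`, Gauss-Legendre order 64 on (0,1) and Gauss-Hermite order 32 over
#' the real line.
#'
#' @param grid_points number of interior frequency-grid points (uniform in
#'   (0,1)) for the Crank-Nicolson solver.
#' @param time_steps number of time steps used when solving to a single time
#'   `t` (the step is `t/time_steps`).
#' @param gl_order Gauss-Legendre order for integrals over (0,1).
#' @param gh_order Gauss-Hermite order for expectations over the selection
#'   coefficient.
#' @param gamma_tol threshold on `|gamma|` below which series branches of the
#'   scale function and related ratios are used (guards the neutral limit).
#' @param flux_rtol relative tolerance for the two-point extrapolation of the
#'   fixation flux kernel.
#' @param clip lower floor applied to expected counts before they enter
#'   Poisson log-likelihoods.
#' @param speed_exponent `"gamma_x"` for the speed density
#'   `exp(gamma*x)/(x(1-x))` (the default, consistent with the diffusion
#'   drift), or `"gamma_const"` for the literal constant-exponent variant
#'   `exp(gamma)/(x(1-x))`.
#' @param s1_inside logical; if `TRUE` (default) the `1/s(1)` normalization of
#'   the replacement Poisson means is evaluated inside the Gauss-Hermite
#'   expectation over gamma (it depends on gamma), otherwise outside at the
#'   locus mean.
#' @return a list of class `"prf_control"`.
#' @export
prf_control <- function(grid_points = 400L, time_steps = 400L,
                        gl_order = 64L, gh_order = 32L,
                        gamma_tol = 1e-8, flux_rtol = 1e-3,
                        clip = 1e-12,
                        speed_exponent = c("gamma_x", "gamma_const"),
                        s1_inside = TRUE) {
  speed_exponent <- match.arg(speed_exponent)
  grid_points <- as.integer(grid_points)
  time_steps <- as.integer(time_steps)
  stopifnot(grid_points >= 3L, time_steps >= 1L,
            gl_order >= 2L, gh_order >= 1L,
            gamma_tol > 0, flux_rtol > 0, clip >= 0)
  structure(list(grid_points = grid_points, time_steps = time_steps,
                 gl_order = as.integer(gl_order),
                 gh_order = as.integer(gh_order),
                 gamma_tol = gamma_tol, flux_rtol = flux_rtol,
                 clip = clip, speed_exponent = speed_exponent,
                 s1_inside = s1_inside),
            class = "prf_control")
}

as_prf_control <- function(ctrl) {
  if (is.null(ctrl)) return(prf_control())
  if (inherits(ctrl, "prf_control")) return(ctrl)
  stop("`ctrl` must be NULL or a prf_control() object")
}
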