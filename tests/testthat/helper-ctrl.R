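# shared test fixtures: reduced numerical settings (tests that probe
# numerical accuracy tighten these locally)

test_ctrl <- function(...) {
  prf_control(grid_points = 120L, time_steps = 240L, gl_order = 48L,
              gh_order = 16L, ...)
}

# small deterministic counts dataset (hand-written, not simulated)
tiny_data <- function() {
  data.frame(m = c(8L, 10L), n = c(10L, 7L),
             Ks = c(12L, 5L), Os = c(9L, 7L), Hs = c(1L, 0L),
             Kr = c(4L, 15L), Or = c(6L, 11L), Hr = c(0L, 1L),
             locus = c("locA", "locB"), class = c("male-biased", "unknown"),
             stringsAsFactors = FALSE)
}

# memoised lambda cache shared across test files (built once per run)
.test_env <- new.env()

tiny_cache <- function(ctrl = test_ctrl()) {
  if (is.null(.test_env$cache))
    .test_env$cache <- lambda_cache(cbind(c(8L, 10L), c(10L, 7L)),
                                    t_max = 20, ctrl = ctrl)
  .test_env$cache
}

tiny_state <- function(data = tiny_data()) {
  list(global = list(mu_gamma = 0, sigma_b = 2, sigma_w = 1, t_div = 2),
       loci = data.frame(theta_s = rep(2, nrow(data)),
                         theta_r = rep(2, nrow(data)),
                         gamma_i = rep(0, nrow(data))))
}
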