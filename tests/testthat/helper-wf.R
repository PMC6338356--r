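# Brute-force discrete Wright-Fisher oracle for the expected 2x3 table.
#
# Haploid WF population of N individuals, fitness 1+s for the mutant with
# s = gamma/(2N); one unit of the model's diffusion time corresponds to 2N
# discrete generations (this matches the drift gamma*x*(1-x) and diffusion
# coefficient x*(1-x) of the model's generator); mutation influx
# Poisson(theta/2 * (1/N)/s(1/N)) new mutant lineages per generation (s the
# diffusion scale function), each starting at frequency 1/N: matching the
# equilibrium site-frequency intensity theta*(s(1)-s(x))*m(x)/s(1) requires
# influx rate theta/(2*s(1/N)) per unit diffusion time of 2N generations,
# which reduces to theta/2 per generation in the neutral case.
#
# The oracle simulates the full generative process: an ancestral population
# at mutation-selection-drift equilibrium, a split into two daughter
# populations evolved independently for round(2*N*t) generations with
# continued mutation influx, binomial sampling of m and n sequences, and
# classification of every site by its sample configuration:
#   fixed difference:     monomorphic in both samples, different alleles
#   new polymorphism:     polymorphic in exactly one sample
#   legacy polymorphism:  polymorphic in both samples
# It shares no code with the package's diffusion/quadrature machinery.

wf_step <- function(x, N, s) {
  if (!length(x)) return(x)
  p <- (x / N) * (1 + s) / (1 + s * x / N)
  rbinom(length(x), N, p)
}

# advance the segregating-site list of a single population by `gens`
# generations with mutation influx; used for the ancestral equilibrium
wf_advance <- function(x, N, s, gens, influx) {
  for (g in seq_len(gens)) {
    x <- wf_step(x, N, s)
    x <- x[x > 0L & x < N]
    k <- rpois(1, influx)
    if (k) x <- c(x, rep(1L, k))
  }
  x
}

# evolve one daughter lineage for `gens` generations; returns the final
# frequency (0 lost, 1 fixed, interior otherwise) of every ancestral input
# site, and of every lineage-private new mutation
wf_track <- function(x, N, s, gens, influx) {
  yanc <- numeric(length(x))          # default 0 = lost
  alive <- seq_along(x)
  anc <- x
  ynew <- numeric(0)
  new <- integer(0)
  for (g in seq_len(gens)) {
    anc <- wf_step(anc, N, s)
    if (length(anc)) {
      fixed <- anc == N
      if (any(fixed)) yanc[alive[fixed]] <- 1
      keep <- anc > 0L & anc < N
      alive <- alive[keep]
      anc <- anc[keep]
    }
    new <- wf_step(new, N, s)
    if (length(new)) {
      nfix <- sum(new == N)
      if (nfix) ynew <- c(ynew, rep(1, nfix))
      new <- new[new > 0L & new < N]
    }
    k <- rpois(1, influx)
    if (k) new <- c(new, rep(1L, k))
  }
  yanc[alive] <- anc / N
  list(anc = yanc, new = c(ynew, new / N))
}

wf_classify <- function(y1, y2, m, n, N) {
  # m (resp. n) distinct individuals drawn without replacement
  s1 <- rhyper(length(y1), round(y1 * N), N - round(y1 * N), m)
  s2 <- rhyper(length(y2), round(y2 * N), N - round(y2 * N), n)
  poly1 <- s1 > 0L & s1 < m
  poly2 <- s2 > 0L & s2 < n
  c(K = sum(!poly1 & !poly2 & (s1 / m) != (s2 / n)),
    O = sum(xor(poly1, poly2)),
    H = sum(poly1 & poly2))
}

wf_table_replicate <- function(x, N, s, gens, influx, m, n) {
  l1 <- wf_track(x, N, s, gens, influx)
  l2 <- wf_track(x, N, s, gens, influx)
  y1 <- c(l1$anc, l1$new, rep(0, length(l2$new)))
  y2 <- c(l2$anc, rep(0, length(l1$new)), l2$new)
  wf_classify(y1, y2, m, n, N)
}

# Monte-Carlo estimate of the expected (K, O, H) counts with standard errors
wf_oracle <- function(gamma, theta, t, m, n, N = 50L, reps = 2000L,
                      burn_mult = 20L, snap_every = 2L) {
  s <- gamma / (2 * N)
  gens <- as.integer(round(2 * N * t))
  sd1N <- if (gamma == 0) 1 / N else (1 - exp(-gamma / N)) / gamma
  influx <- theta / 2 * (1 / N) / sd1N
  x <- wf_advance(integer(0), N, s, burn_mult * N, influx)
  acc <- matrix(0, reps, 3)
  for (r in seq_len(reps)) {
    x <- wf_advance(x, N, s, snap_every * N, influx)
    acc[r, ] <- wf_table_replicate(x, N, s, gens, influx, m, n)
  }
  # batch-means SE: consecutive replicates share the ancestral snapshot
  # stream, so plain per-replicate SEs would be slightly optimistic
  nb <- max(10L, reps %/% 50L)
  bsz <- reps %/% nb
  bm <- sapply(seq_len(nb), function(b)
    colMeans(acc[((b - 1L) * bsz + 1L):(b * bsz), , drop = FALSE]))
  list(mean = colMeans(acc), se = apply(bm, 1, sd) / sqrt(nb))
}
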