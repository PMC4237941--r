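# Independent oracles for the binding chemistry.  These deliberately avoid
# the closed-form/fixed-point algebra used by the implementation.

# bisection on the mass-action residual ka*(A - C)*(I - C) - C over
# C in [0, min(A, I)]
oracle_pair_complex <- function(total_a, total_i, ka, iters = 200L) {
  if (ka == 0 || total_a == 0 || total_i == 0) return(0)
  resid <- function(C) ka * (total_a - C) * (total_i - C) - C
  lo <- 0
  hi <- min(total_a, total_i)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# competitive analog equilibrium via the cubic polynomial in free_i, solved
# with polyroot (a solver the implementation does not use)
oracle_analog <- function(total_a, total_i, total_d, ka, kd) {
  if (total_i == 0) {
    return(list(free_a = total_a, free_i = 0, free_analog = total_d,
                complex_ai = 0, complex_di = 0))
  }
  a <- ka; d <- kd; A <- total_a; D <- total_d; I <- total_i
  c3 <- a * d
  c2 <- (a + d) + a * d * (A + D - I)
  c1 <- 1 + a * A + d * D - I * (a + d)
  c0 <- -I
  roots <- polyroot(c(c0, c1, c2, c3))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * Mod(roots) + 1e-30])
  fi <- real[real >= 0 & real <= I * (1 + 1e-9)]
  stopifnot(length(fi) >= 1)
  fi <- min(fi)
  fa <- A / (1 + a * fi)
  fd <- D / (1 + d * fi)
  list(free_a = fa, free_i = fi, free_analog = fd,
       complex_ai = a * fa * fi, complex_di = d * fd * fi)
}

# a tiny world for engine-level tests: 5 + 5 cells, pool at steady state
small_couplet_config <- function(seed = 1, steps = 20L, ...) {
  rates <- rate_config()
  n <- 5
  ss <- n * rates$secretion_rate / rates$degradation_rate
  sim_config(
    initial_cells = list(list(type = "A", n = n), list(type = "I", n = n)),
    initial_pool = pool_state(total_a = ss, total_i = ss),
    steps = steps, seed = seed, ...
  )
}

# explicit end-of-run mass-ledger closure check, per species
expect_ledger_closed <- function(run, tol = 1e-9) {
  state <- run$final
  ab <- if (identical(run$config$binding$analog_mimics, "a")) "i" else "a"
  for (sp in c("a", "i", "d")) {
    sources <- state$ledger$added[[sp]] + state$ledger$secreted[[sp]]
    pool_total <- switch(sp, a = state$pool$total_a, i = state$pool$total_i,
                         d = state$pool$total_analog)
    stores <- sum(vapply(state$cells, ctcsim:::cell_store_total, numeric(1),
                         species = sp, analog_bound = ab))
    holdings <- pool_total + stores + state$ledger$degraded[[sp]]
    expect_lt(abs(sources - holdings), tol * max(sources, 1e-30))
  }
}
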