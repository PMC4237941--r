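test_that("equilibrate_pair handles the degenerate no-binding cases", {
  eq <- equilibrate_pair(1e-8, 1e-8, 0)
  expect_equal(eq$complex_ai, 0)
  expect_equal(eq$free_a, 1e-8)
  expect_equal(eq$free_i, 1e-8)

  eq <- equilibrate_pair(0, 1e-8, 1e10)
  expect_equal(eq$complex_ai, 0)
  expect_equal(eq$free_i, 1e-8)
})

test_that("equilibrate_pair reproduces the bisection oracle on worked cases", {
  # equal totals at Ka = 1e10: almost everything is bound
  eq <- equilibrate_pair(1e-8, 1e-8, 1e10)
  oc <- oracle_pair_complex(1e-8, 1e-8, 1e10)
  expect_equal(eq$complex_ai, oc, tolerance = 1e-9)
  expect_equal(eq$complex_ai, 9.049e-9, tolerance = 1e-3)
  expect_equal(eq$free_a, 9.51e-10, tolerance = 1e-3)
  expect_equal(eq$free_a, eq$free_i)

  # asymmetric totals
  eq <- equilibrate_pair(2e-8, 1e-8, 1e10)
  oc <- oracle_pair_complex(2e-8, 1e-8, 1e10)
  expect_equal(eq$complex_ai, oc, tolerance = 1e-9)
  expect_equal(eq$complex_ai, 9.90e-9, tolerance = 1e-3)
  expect_equal(eq$free_i, 9.8e-11, tolerance = 2e-3)
})

test_that("equilibrate_pair rejects negative input, naming the argument", {
  expect_error(equilibrate_pair(-1e-9, 1e-8, 1e10), "total_a")
  expect_error(equilibrate_pair(1e-8, -1, 1e10), "total_i")
  expect_error(equilibrate_pair(1e-8, 1e-8, -5), "ka")
})

test_that("closed form matches the oracle over random instances", {
  set.seed(42)
  n <- 300
  ta <- 10^runif(n, -12, -6)
  ti <- 10^runif(n, -12, -6)
  ka <- 10^runif(n, 6, 12)
  for (k in seq_len(n)) {
    eq <- equilibrate_pair(ta[k], ti[k], ka[k])
    oc <- oracle_pair_complex(ta[k], ti[k], ka[k])
    expect_lt(abs(eq$complex_ai - oc), 1e-7 * max(oc, 1e-30))
  }
})

test_that("equilibrium satisfies mass balance and the law of mass action", {
  set.seed(7)
  for (k in 1:100) {
    ta <- 10^runif(1, -12, -6); ti <- 10^runif(1, -12, -6)
    ka <- 10^runif(1, 6, 12)
    eq <- equilibrate_pair(ta, ti, ka)
    expect_lt(abs(eq$free_a + eq$complex_ai - ta), 1e-9 * ta)
    expect_lt(abs(eq$free_i + eq$complex_ai - ti), 1e-9 * ti)
    expect_lt(abs(eq$complex_ai - ka * eq$free_a * eq$free_i),
              1e-7 * max(eq$complex_ai, 1e-30))
  }
})

test_that("complex is monotone in ka and totals; free_a nonincreasing in total_i", {
  set.seed(11)
  for (k in 1:50) {
    ta <- 10^runif(1, -11, -7); ti <- 10^runif(1, -11, -7)
    ka <- 10^runif(1, 7, 11)
    base <- equilibrate_pair(ta, ti, ka)$complex_ai
    expect_gte(equilibrate_pair(ta * 2, ti, ka)$complex_ai, base)
    expect_gte(equilibrate_pair(ta, ti * 2, ka)$complex_ai, base)
    expect_gte(equilibrate_pair(ta, ti, ka * 10)$complex_ai, base)
    expect_lte(equilibrate_pair(ta, ti * 2, ka)$free_a,
               equilibrate_pair(ta, ti, ka)$free_a)
  }
})

test_that("tight binding saturates at min(total_a, total_i)", {
  eq <- equilibrate_pair(3e-8, 1e-8, 1e16)
  expect_equal(eq$complex_ai, 1e-8, tolerance = 1e-4)
  eq <- equilibrate_pair(1e-9, 5e-8, 1e16)
  expect_equal(eq$complex_ai, 1e-9, tolerance = 1e-4)
})

test_that("equilibrate_pair is symmetric in its two species", {
  set.seed(3)
  for (k in 1:25) {
    ta <- 10^runif(1, -11, -7); ti <- 10^runif(1, -11, -7)
    ka <- 10^runif(1, 7, 11)
    e1 <- equilibrate_pair(ta, ti, ka)
    e2 <- equilibrate_pair(ti, ta, ka)
    expect_equal(e1$complex_ai, e2$complex_ai)
    expect_equal(e1$free_a, e2$free_i)
    expect_equal(e1$free_i, e2$free_a)
  }
})

test_that("analog equilibrium reduces to the binary case without analog", {
  bs <- binding_system(1e10, 1e7)
  eq <- equilibrate_with_analog(1e-8, 1e-8, 0, bs)
  ref <- equilibrate_pair(1e-8, 1e-8, 1e10)
  expect_equal(eq$complex_ai, ref$complex_ai, tolerance = 1e-12)
  expect_equal(eq$complex_di, 0)

  # a non-binding analog forms no complex at all
  bs0 <- binding_system(1e10, 0)
  eq <- equilibrate_with_analog(0, 1e-8, 1e-8, bs0)
  expect_equal(eq$complex_ai, 0)
  expect_equal(eq$complex_di, 0)
  expect_equal(eq$free_analog, 1e-8)
})

test_that("analog equilibrium matches the polyroot oracle and desIGF ordering", {
  bs <- binding_system(1e10, 1e7)
  eq <- equilibrate_with_analog(1e-8, 1e-8, 1e-8, bs)
  oc <- oracle_analog(1e-8, 1e-8, 1e-8, 1e10, 1e7)
  expect_equal(eq$complex_ai, oc$complex_ai, tolerance = 1e-7)
  expect_equal(eq$complex_di, oc$complex_di, tolerance = 1e-7)
  expect_equal(eq$free_i, oc$free_i, tolerance = 1e-7)
  # the low-affinity analog is sequestered far less than the genuine Trefone
  expect_lt(eq$complex_di, eq$complex_ai / 10)
  expect_gt(eq$free_analog / 1e-8, eq$free_a / 1e-8)

  # mass balance for all three species
  expect_lt(abs(eq$free_a + eq$complex_ai - 1e-8), 1e-9 * 1e-8)
  expect_lt(abs(eq$free_i + eq$complex_ai + eq$complex_di - 1e-8),
            1e-9 * 1e-8)
  expect_lt(abs(eq$free_analog + eq$complex_di - 1e-8), 1e-9 * 1e-8)
})

test_that("analog equilibrium matches the oracle over random instances", {
  set.seed(21)
  for (k in 1:50) {
    ta <- 10^runif(1, -11, -7); ti <- 10^runif(1, -11, -7)
    td <- 10^runif(1, -11, -7)
    ka <- 10^runif(1, 8, 11); kd <- ka * 10^runif(1, -4, 0)
    eq <- equilibrate_with_analog(ta, ti, td, binding_system(ka, kd))
    oc <- oracle_analog(ta, ti, td, ka, kd)
    expect_lt(abs(eq$complex_ai - oc$complex_ai),
              1e-6 * max(oc$complex_ai, 1e-30))
    expect_lt(abs(eq$complex_di - oc$complex_di),
              1e-6 * max(oc$complex_di, 1e-30))
  }
})

test_that("the mirrored analog orientation swaps the couplet roles exactly", {
  fwd <- binding_system(1e10, 1e7, analog_mimics = "a")
  rev <- binding_system(1e10, 1e7, analog_mimics = "i")
  e1 <- equilibrate_with_analog(3e-8, 1e-8, 2e-8, fwd)
  e2 <- equilibrate_with_analog(1e-8, 3e-8, 2e-8, rev)
  expect_equal(e1$free_a, e2$free_i)
  expect_equal(e1$free_i, e2$free_a)
  expect_equal(e1$complex_ai, e2$complex_ai)
  expect_equal(e1$complex_di, e2$complex_di)
})

test_that("discretize_level bins are half-open with upper-bin boundaries", {
  expect_equal(discretize_level(0, 1e-10, 1e-8), "Lo")
  expect_equal(discretize_level(1e-10, 1e-10, 1e-8), "Mid")
  expect_equal(discretize_level(2e-8, 1e-10, 1e-8), "Hi")
  expect_equal(discretize_level(1e-8, 1e-10, 1e-8), "Hi")
  expect_error(discretize_level(-1e-9, 1e-10, 1e-8), "conc")
  expect_error(discretize_level(1e-9, 1e-8, 1e-10), "theta_hi")
})
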