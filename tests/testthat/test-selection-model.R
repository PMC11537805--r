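test_that("founding states match the reciprocal cross design", {
  s1 <- initial_state("I")
  expect_equal(c(s1$p1, s1$p2, s1$Q11, s1$Q12, s1$Q22), c(0, 1, 0, 1, 0))
  s2 <- initial_state("II")
  expect_equal(c(s2$p1, s2$p2, s2$Q11, s2$Q12, s2$Q22), c(1, 0, 0, 1, 0))
  expect_equal(s1$generation, 1L)
  expect_error(initial_state("III"), "arg")
})

test_that("ratio recursion reproduces hand-evaluated steps", {
  # from the all-zero founding ratios, one step yields (mu, 0, epsilon)
  r <- step_ratios(ratio_state(0, 0, 0), neutral_fitness())
  expect_equal(c(r$R1, r$R2, r$R3), c(1, 0, 1))
  r <- step_ratios(ratio_state(0, 0, 0), fitness_ratios(mu = 2, epsilon = 3))
  expect_equal(c(r$R1, r$R2, r$R3), c(2, 0, 3))
  # symmetric interior state, neutral: R2' = R3' = 3/6 (denominator
  # 2*1*1 + 2*1 + 1 + 1), frozen from independent symbolic evaluation
  r <- step_ratios(ratio_state(1, 1, 1), neutral_fitness())
  expect_equal(c(r$R1, r$R2, r$R3), c(1, 1 / 2, 1 / 2))
  expect_error(step_ratios(ratio_state(Inf, 0, 0), neutral_fitness()),
               "step_frequencies")
})

test_that("frequency recursion handles boundary founding states", {
  s <- step_frequencies(initial_state("I"), neutral_fitness())
  expect_equal(c(s$p1, s$Q11, s$Q12, s$Q22), c(0.5, 0, 0.5, 0.5))
  expect_equal(s$generation, 2L)
  # marked-male founding state with male and female viability selection
  s <- step_frequencies(initial_state("II"), fitness_ratios(mu = 2, nu = 3))
  expect_equal(s$p1, 2 / 3)
  expect_equal(s$Q11 / s$Q12, 3)
  expect_equal(s$Q22, 0)
})

test_that("ratio and frequency maps invert each other", {
  expect_equal(ratios_to_frequencies(ratio_state(1, 1, 1)),
               c(p1 = 0.5, Q11 = 1 / 3))
  expect_equal(ratios_to_frequencies(ratio_state(Inf, 0, 0)),
               c(p1 = 1, Q11 = 0))
  expect_equal(ratios_to_frequencies(ratio_state(2, 0, 3)),
               c(p1 = 2 / 3, Q11 = 0))
  expect_error(ratio_state(NaN, 0, 0), "NA")

  expect_equal(
    unclass(frequencies_to_ratios(
      population_state(0.5, 0.25, 0.5, 0.25)))[c("R1", "R2", "R3")],
    list(R1 = 1, R2 = 0.5, R3 = 0.5))
  r <- frequencies_to_ratios(initial_state("II"))
  expect_equal(c(r$R1, r$R2, r$R3), c(Inf, 0, 0))
  # 0/0 convention: an all-A1A1 female pool has no het or A2A2 females
  expect_warning(
    r <- frequencies_to_ratios(population_state(0.5, 1, 0, 0)),
    "0/0")
  expect_equal(r$R3, 0)

  set.seed(42)
  for (i in 1:25) {
    s <- random_interior_state()
    fr <- ratios_to_frequencies(frequencies_to_ratios(s))
    expect_equal(unname(fr["p1"]), s$p1, tolerance = 1e-12)
    expect_equal(unname(fr["Q11"]), s$Q11, tolerance = 1e-12)
  }
})

test_that("trajectory iterates the recursion and stays normalised", {
  tr <- trajectory("I", neutral_fitness(), 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$p1, 0)
  expect_error(trajectory("I", neutral_fitness(), 0), "t_max")

  set.seed(7)
  for (i in 1:5) {
    tr <- trajectory(sample(c("I", "II"), 1), random_fitness(), 15)
    expect_true(all(abs(tr$p1 + tr$p2 - 1) < 1e-12))
    expect_true(all(abs(tr$Q11 + tr$Q12 + tr$Q22 - 1) < 1e-12))
    expect_true(all(tr[c("p1", "p2", "Q11", "Q12", "Q22")] >= 0))
  }
})

test_that("neutral dynamics conserve the pooled allele frequency and damp the sex gap", {
  for (setup in c("I", "II")) {
    tr <- trajectory(setup, neutral_fitness(), 20)
    qf <- tr$Q11 + tr$Q12 / 2
    pooled <- (2 * qf + tr$p1) / 3
    expect_true(all(abs(pooled - pooled[1]) < 1e-12))
    # the female-male frequency gap halves and flips sign each generation
    gap <- qf - tr$p1
    expect_equal(gap[-1], -gap[-20] / 2, tolerance = 1e-12)
  }
  # conservation also holds from interior states
  set.seed(11)
  s <- random_interior_state()
  q0 <- (2 * (s$Q11 + s$Q12 / 2) + s$p1) / 3
  for (i in 1:2) s <- step_frequencies(s, neutral_fitness())
  expect_equal((2 * (s$Q11 + s$Q12 / 2) + s$p1) / 3, q0, tolerance = 1e-12)
})

test_that("neutral trajectories converge to the random-mating equilibrium", {
  expect_equal(neutral_equilibrium("I"), c(p1 = 1 / 3, Q11 = 1 / 9))
  expect_equal(neutral_equilibrium("II"), c(p1 = 2 / 3, Q11 = 4 / 9))
  for (setup in c("I", "II")) {
    tr <- trajectory(setup, neutral_fitness(), 20)
    eq <- neutral_equilibrium(setup)
    expect_lt(abs(tr$p1[20] - eq["p1"]), 1e-5)
    expect_lt(abs(tr$Q11[20] - eq["Q11"]), 1e-5)
  }
})

test_that("relabeling the alleles commutes with the recursion", {
  swap_state <- function(s)
    population_state(p1 = s$p2, Q11 = s$Q22, Q12 = s$Q12, Q22 = s$Q11,
                     generation = s$generation)
  set.seed(99)
  for (i in 1:20) {
    s <- random_interior_state()
    f <- random_fitness()
    a <- swap_state(step_frequencies(s, f))
    b <- step_frequencies(swap_state(s), swap_alleles(f))
    expect_equal(c(a$p1, a$Q11, a$Q12, a$Q22),
                 c(b$p1, b$Q11, b$Q12, b$Q22), tolerance = 1e-12)
  }
  # setup relabeling: I under f corresponds to II under the swapped ratios
  trI <- trajectory("I", true_fitness(), 10)
  trII <- trajectory("II", swap_alleles(true_fitness()), 10)
  expect_equal(trI$p1, trII$p2, tolerance = 1e-12)
  expect_equal(trI$Q11, trII$Q22, tolerance = 1e-12)
})

test_that("male frequency responds monotonically to male viability", {
  for (t in c(2, 5, 12)) {
    p1_at <- vapply(c(0.5, 0.8, 1, 1.5, 2.5), function(mu)
      trajectory("I", fitness_ratios(mu = mu), t)$p1[t], numeric(1))
    expect_true(all(diff(p1_at) > 0))
  }
})
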