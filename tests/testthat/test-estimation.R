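test_that("generation-2 viability estimators pool counts as binomial MLEs", {
  v <- estimate_viability(g2_table(50, 50, 50, 50))
  expect_equal(v$mu, 1)
  # pooled across setups: (60+40)/(30+20)
  v <- estimate_viability(g2_table(60, 30, 40, 20,
                                   n_white_II = 60, n_other_II = 50,
                                   het_I = 40, hom2_I = 10))
  expect_equal(v$mu, 2)
  expect_equal(v$nu, 60 / 50)
  expect_equal(v$epsilon, 10 / 40)

  # replicate rows pool with the same weights
  two_reps <- rbind(g2_table(30, 15, 20, 10),
                    g2_table(30, 15, 20, 10))
  two_reps$replicate <- rep(1:2, each = 2)
  expect_equal(estimate_viability(two_reps)$mu, 2)
})

test_that("viability estimation fails loudly on unidentifiable input", {
  g2 <- g2_table(50, 50, 50, 50)
  g2$females_het <- NA_integer_
  g2$females_hom2 <- NA_integer_
  expect_error(estimate_viability(g2), "genotype-resolved")
  expect_error(estimate_viability(g2_table(50, 50, 50, 50, het_I = 0,
                                           hom2_I = 40)),
               "inestimable")
  expect_error(estimate_viability(g2_table(50, 0, 50, 0)), "inestimable")
  expect_error(estimate_viability(obs_row("I", 2, 10, 5, 10, 0,
                                          het = 5, hom2 = 5)),
               "both setups")
})

test_that("noiseless generation-2 counts recover viability to rounding error", {
  f <- fitness_ratios(mu = 0.8, nu = 1.2, epsilon = 0.7)
  d <- experiment_design(census_min = 1e6, census_max = 1e6,
                         generations = c(1, 2))
  v <- estimate_viability(generate_noiseless_counts(d, f))
  expect_equal(v$mu, 0.8, tolerance = 1e-3)
  expect_equal(v$nu, 1.2, tolerance = 1e-3)
  expect_equal(v$epsilon, 0.7, tolerance = 1e-3)
})

test_that("Clopper-Pearson viability intervals bracket the point estimates", {
  v <- estimate_viability(g2_table(60, 30, 40, 20))
  ci <- viability_ci(v)
  expect_equal(ci$parameter, c("mu", "nu", "epsilon"))
  expect_true(all(ci$lo < ci$estimate & ci$estimate < ci$hi))
  wider <- viability_ci(v, level = 0.99)
  expect_true(all(wider$lo < ci$lo & wider$hi > ci$hi))
})

test_that("composite log-likelihood matches hand-computed kernels and boundary rules", {
  # neutral setup I has p1(2) = 1/2 and Q11(2) = 0 exactly
  obs <- obs_row("I", 2, M = 2, m = 1, N = 0, n = 0)
  expect_equal(composite_loglik(neutral_fitness(), obs, fit_generations = 2),
               2 * log(0.5))
  # observed count on a predicted boundary contributes zero...
  obs <- obs_row("II", 1, M = 30, m = 30, N = 10, n = 0)
  expect_equal(composite_loglik(neutral_fitness(), obs, fit_generations = 1),
               0)
  # ...but data the model calls impossible score -Inf
  obs <- obs_row("I", 1, M = 30, m = 3, N = 10, n = 0)
  expect_equal(composite_loglik(neutral_fitness(), obs, fit_generations = 1),
               -Inf)
  expect_error(composite_loglik(neutral_fitness(),
                                obs_row("I", 2, 10, 5, 10, 0),
                                fit_generations = 8),
               "no observations")
})

test_that("binomial coefficients shift the likelihood by a parameter-free constant", {
  d <- experiment_design(seed = 3)
  cts <- generate_counts(d, true_fitness())
  full_lnL <- function(f) {
    gens <- c(3, 8, 12, 20)
    obs <- cts[cts$generation %in% gens, ]
    tot <- 0
    for (setup in c("I", "II")) {
      rows <- obs[obs$setup == setup, ]
      tr <- trajectory(setup, f, 20)
      for (i in seq_len(nrow(rows))) {
        pr <- tr[tr$generation == rows$generation[i], ]
        tot <- tot +
          stats::dbinom(rows$males_white[i], rows$males_total[i], pr$p1,
                        log = TRUE) +
          stats::dbinom(rows$females_white[i], rows$females_total[i],
                        pr$Q11, log = TRUE)
      }
    }
    tot
  }
  f1 <- true_fitness(); f2 <- random_fitness(0.5, 2)
  const1 <- full_lnL(f1) - composite_loglik(f1, cts)
  const2 <- full_lnL(f2) - composite_loglik(f2, cts)
  expect_equal(const1, const2, tolerance = 1e-8)
})

test_that("grid specifications validate their bounds", {
  expect_error(grid_spec("linear", 1, 0.5, 0.01), "lo < hi")
  expect_error(grid_spec("linear", -0.5, 1.5, 0.01), "positive")
  expect_error(grid_spec("linear", 0.5, 1.5, 0), "step")
  expect_equal(length(default_coarse_grid()$values), 201L)
  expect_equal(length(default_fine_grid()$values), 101L)
  expect_equal(range(default_coarse_grid()$values), c(0.1, 10),
               tolerance = 1e-12)
  expect_equal(default_fine_grid()$values[c(1, 51, 101)], c(0.5, 1, 1.5))
})

test_that("compiled grid evaluator agrees with the interpreted likelihood", {
  d <- experiment_design(seed = 5, census_min = 400, census_max = 600)
  cts <- generate_counts(d, true_fitness())
  g <- grid_spec("linear", 0.7, 1.3, 0.3)   # 3 points per axis
  viab <- true_viability()
  fit <- fit_fertility(cts, viab, coarse = NULL, fine = g)
  vals <- g$values
  brute <- array(NA_real_, dim = c(3, 3, 3))
  for (ia in 1:3) for (ib in 1:3) for (ig in 1:3)
    brute[ia, ib, ig] <- composite_loglik(
      fitness_ratios(alpha = vals[ia], beta = vals[ib], gamma = vals[ig],
                     mu = viab$mu, nu = viab$nu, epsilon = viab$epsilon),
      cts)
  expect_equal(fit$fine_lnL, brute, tolerance = 1e-9)
  idx <- which(brute == max(brute), arr.ind = TRUE)
  expect_equal(c(fit$alpha_hat, fit$beta_hat, fit$gamma_hat),
               c(vals[idx[1]], vals[idx[2]], vals[idx[3]]))
})

test_that("the fertility fit never alters the viability plug-in", {
  d <- experiment_design(seed = 8, census_min = 500, census_max = 700)
  cts <- generate_counts(d, true_fitness())
  viab <- estimate_viability(cts)
  fit <- fit_fertility(cts, viab, coarse = NULL,
                       fine = grid_spec("linear", 0.5, 1.5, 0.05))
  expect_identical(fit$viability, viab)
  expect_true(all(fit$fine_lnL <= fit$lnL_max))
  for (p in c("alpha", "beta", "gamma")) {
    ci <- fit$ci[[p]]
    expect_true(ci$lo <= fit[[paste0(p, "_hat")]] &&
                  fit[[paste0(p, "_hat")]] <= ci$hi)
  }
})

test_that("profiling flags an uninformative likelihood as grid-wide", {
  # a single tiny observation at one generation carries almost no
  # information about the fertility ratios
  obs <- obs_row("I", 3, M = 2, m = 1, N = 2, n = 0)
  fit <- fit_fertility(obs, list(mu = 1, nu = 1, epsilon = 1),
                       coarse = NULL, fit_generations = 3)
  ci <- fit$ci$alpha
  expect_equal(c(ci$lo, ci$hi), c(0.5, 1.5))
  expect_true(ci$at_lower && ci$at_upper)
  expect_error(profile_ci(fit, "delta"), "arg")
})

test_that("fertility estimates sharpen as the census grows", {
  alpha_err <- list(); width <- list()
  for (census in c(700, 20000)) {
    key <- as.character(census)
    alpha_err[[key]] <- numeric(0); width[[key]] <- numeric(0)
    for (seed in 1:12) {
      d <- experiment_design(census_min = census, census_max = census,
                             seed = 4000 + seed)
      cts <- generate_counts(d, true_fitness())
      fit <- fit_fertility(cts, true_viability(), coarse = NULL)
      alpha_err[[key]] <- c(alpha_err[[key]], abs(fit$alpha_hat - 0.8))
      width[[key]] <- c(width[[key]], fit$ci$alpha$hi - fit$ci$alpha$lo)
    }
  }
  expect_lt(median(alpha_err[["20000"]]), median(alpha_err[["700"]]))
  expect_lt(mean(width[["20000"]]), mean(width[["700"]]))
})
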