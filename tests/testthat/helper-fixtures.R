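# On-grid truth used by recovery and coverage checks: every fertility ratio
# sits on the fine grid, viability ratios are off-unity in both directions.
true_fitness <- function() {
  fitness_ratios(alpha = 0.8, beta = 1.1, gamma = 1.3,
                 mu = 0.9, nu = 1.2, epsilon = 0.8)
}

true_viability <- function() list(mu = 0.9, nu = 1.2, epsilon = 0.8)

# A single count-table row with sane defaults, for hand-built fixtures.
obs_row <- function(setup, generation, M, m, N, n,
                    het = NA_integer_, hom2 = NA_integer_, replicate = 1L) {
  tibble::tibble(setup = setup, replicate = as.integer(replicate),
                 generation = as.integer(generation),
                 males_total = as.integer(M), males_white = as.integer(m),
                 females_total = as.integer(N), females_white = as.integer(n),
                 females_het = as.integer(het),
                 females_hom2 = as.integer(hom2))
}

# Generation-2 counts for both setups with all classes resolvable, letting
# the male white/non-white split be chosen per competition.
g2_table <- function(m_white_I, m_other_I, m_white_II, m_other_II,
                     n_white_II = 50, n_other_II = 50,
                     het_I = 50, hom2_I = 40) {
  rbind(
    obs_row("I", 2, m_white_I + m_other_I, m_white_I,
            het_I + hom2_I, 0, het = het_I, hom2 = hom2_I),
    obs_row("II", 2, m_white_II + m_other_II, m_white_II,
            n_white_II + n_other_II, n_white_II)
  )
}

# Uniform-random interior population state (all five classes present).
random_interior_state <- function() {
  p1 <- stats::runif(1, 0.05, 0.95)
  q <- stats::runif(3, 0.05, 1)
  q <- q / sum(q)
  population_state(p1 = p1, Q11 = q[1], Q12 = q[2], Q22 = q[3])
}

random_fitness <- function(lo = 0.2, hi = 5) {
  v <- stats::runif(6, lo, hi)
  fitness_ratios(alpha = v[1], beta = v[2], gamma = v[3],
                 mu = v[4], nu = v[5], epsilon = v[6])
}
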