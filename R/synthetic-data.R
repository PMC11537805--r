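#' Design of a synthetic allelic-competition experiment
#'
#' Describes the bottle experiment the generator emulates: reciprocal
#' setups scored at a fixed set of discrete generations, replicate bottles,
#' and per-sex census sizes drawn uniformly per bottle and generation.  The
#' defaults mirror a 20-generation competition: both setups, two replicate
#' bottles each, scoring at generations 1, 2, 3, 8, 12 and 20, and 250-400
#' adults of each sex per bottle (bottle totals 500-800).
#'
#' @param setups Subset of `c("I", "II")`.
#' @param replicates Replicate bottles per setup.
#' @param generations Scored generations.
#' @param census_min,census_max Bounds of the per-sex uniform census draw.
#' @param mode `"observation"` — binomial sampling of phenotype counts
#'   around the deterministic trajectory (the assumption the composite
#'   likelihood makes); or `"drift"` — a finite population whose genotype
#'   frequencies themselves wander by multinomial resampling each
#'   generation.
#' @param genotyped_g2 Emit genotype-resolved female counts at generation 2
#'   (required downstream for `epsilon`); set `FALSE` to exercise the
#'   identifiability error.
#' @param seed Integer seed; every draw is made by one seeded generator in
#'   a fixed order (setup, then replicate, then generation, males before
#'   females), so output is reproducible.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(setups = c("I", "II"), replicates = 2,
                              generations = c(1, 2, 3, 8, 12, 20),
                              census_min = 250, census_max = 400,
                              mode = c("observation", "drift"),
                              genotyped_g2 = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  setups <- match.arg(setups, c("I", "II"), several.ok = TRUE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  generations <- sort(unique(as.integer(generations)))
  if (any(generations < 1)) stop("generations must be >= 1", call. = FALSE)
  if (census_min < 1 || census_max < census_min)
    stop("census bounds must satisfy 1 <= census_min <= census_max",
         call. = FALSE)
  structure(list(setups = setups, replicates = as.integer(replicates),
                 generations = generations,
                 census_min = as.integer(census_min),
                 census_max = as.integer(census_max),
                 mode = mode, genotyped_g2 = isTRUE(genotyped_g2),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

empty_counts <- function() {
  tibble::tibble(setup = character(), replicate = integer(),
                 generation = integer(), males_total = integer(),
                 males_white = integer(), females_total = integer(),
                 females_white = integer(), females_het = integer(),
                 females_hom2 = integer())
}

count_row <- function(setup, rep, gen, M, m, N, nQ, genotyped) {
  tibble::tibble(setup = setup, replicate = as.integer(rep),
                 generation = as.integer(gen),
                 males_total = as.integer(M), males_white = as.integer(m),
                 females_total = as.integer(N),
                 females_white = as.integer(nQ[1]),
                 females_het = if (genotyped) as.integer(nQ[2]) else NA_integer_,
                 females_hom2 = if (genotyped) as.integer(nQ[3]) else NA_integer_)
}

#' Generate synthetic scored adult counts
#'
#' In `"observation"` mode each scored bottle-generation draws its
#' white-male count from Binomial(M, p1(t)) and its female class counts
#' from Multinomial(N, (Q11, Q12, Q22)) around the deterministic
#' trajectory — exactly the sampling model the composite likelihood
#' assumes, with counts independent across generations given the
#' trajectory.  In `"drift"` mode each replicate bottle is a finite
#' population: each generation the realised adult genotype counts are
#' resampled (binomial males, multinomial females) around the
#' selection-updated frequencies of the realised previous generation, so
#' scored counts are serially dependent and the trajectory itself varies
#' between replicates.
#'
#' Genotype-resolved female counts are reported at generation 2 (unless
#' suppressed in the design); at other generations only the white-eyed
#' (A1A1) female count is scored, matching what eye colour can distinguish.
#'
#' @param design An [experiment_design()].
#' @param f A [fitness_ratios] object.
#' @return A count table passing [validate_counts()].
#' @export
generate_counts <- function(design, f) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(f, "fitness_ratios"))
  set.seed(design$seed)
  t_max <- max(design$generations)
  rows <- list()
  for (setup in design$setups) {
    traj <- trajectory(setup, f, t_max)
    for (rep in seq_len(design$replicates)) {
      if (design$mode == "observation") {
        for (gen in design$generations) {
          st <- traj[traj$generation == gen, ]
          M <- sample(design$census_min:design$census_max, 1)
          m <- rbinom(1, M, st$p1)
          N <- sample(design$census_min:design$census_max, 1)
          nQ <- drop(rmultinom(1, N, c(st$Q11, st$Q12, st$Q22)))
          rows[[length(rows) + 1L]] <- count_row(
            setup, rep, gen, M, m, N, nQ,
            genotyped = design$genotyped_g2 && gen == 2L)
        }
      } else {
        s <- initial_state(setup)
        for (gen in seq_len(t_max)) {
          M <- sample(design$census_min:design$census_max, 1)
          N <- sample(design$census_min:design$census_max, 1)
          if (gen == 1L) {
            m <- rbinom(1, M, s$p1)
            nQ <- drop(rmultinom(1, N, c(s$Q11, s$Q12, s$Q22)))
          } else {
            s_next <- step_frequencies(s, f)
            m <- rbinom(1, M, s_next$p1)
            nQ <- drop(rmultinom(1, N, c(s_next$Q11, s_next$Q12,
                                         s_next$Q22)))
          }
          # realised adult frequencies become the parents of the next step
          s <- population_state(p1 = m / M, Q11 = nQ[1] / N,
                                Q12 = nQ[2] / N, Q22 = nQ[3] / N,
                                generation = gen)
          if (gen %in% design$generations)
            rows[[length(rows) + 1L]] <- count_row(
              setup, rep, gen, M, m, N, nQ,
              genotyped = design$genotyped_g2 && gen == 2L)
        }
      }
    }
  }
  do.call(rbind, c(list(empty_counts()), rows))
}

#' Expected (noise-free) scored counts
#'
#' Rounds the deterministic trajectory's expected class counts at a fixed
#' census — the midpoint of the design's census bounds per sex — with the
#' female classes constrained to sum to the census.  Used for exact
#' parameter-recovery checks, where any discrepancy is rounding alone
#' (at most 0.5/census on each frequency).
#'
#' @inheritParams generate_counts
#' @return A count table passing [validate_counts()].
#' @export
generate_noiseless_counts <- function(design, f) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(f, "fitness_ratios"))
  t_max <- max(design$generations)
  census <- as.integer(floor((design$census_min + design$census_max) / 2))
  rows <- list()
  for (setup in design$setups) {
    traj <- trajectory(setup, f, t_max)
    for (rep in seq_len(design$replicates)) {
      for (gen in design$generations) {
        st <- traj[traj$generation == gen, ]
        m <- round(census * st$p1)
        n11 <- round(census * st$Q11)
        n12 <- round(census * st$Q12)
        n22 <- census - n11 - n12
        rows[[length(rows) + 1L]] <- count_row(
          setup, rep, gen, census, m, census, c(n11, n12, n22),
          genotyped = design$genotyped_g2 && gen == 2L)
      }
    }
  }
  do.call(rbind, c(list(empty_counts()), rows))
}
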