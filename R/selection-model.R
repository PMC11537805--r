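#' Adult genotype-frequency state of an X-linked two-allele population
#'
#' One generation's adult frequencies at a single X-linked locus: among
#' males the hemizygous classes A1 (`p1`) and A2 (`p2`); among females the
#' diploid classes A1A1 (`Q11`), A1A2 (`Q12`) and A2A2 (`Q22`).  Each sex's
#' frequencies sum to one.
#'
#' @param p1 Frequency of A1 males among males.
#' @param Q11,Q12,Q22 Female genotype frequencies among females.
#' @param generation Integer generation index, starting at 1 for the founding
#'   adults.
#' @return An object of class `population_state`.
#' @examples
#' population_state(p1 = 0.5, Q11 = 0.25, Q12 = 0.5, Q22 = 0.25)
#' @export
population_state <- function(p1, Q11, Q12, Q22, generation = 1L) {
  tol <- 1e-9
  vals <- c(p1 = p1, Q11 = Q11, Q12 = Q12, Q22 = Q22)
  if (any(!is.finite(vals)) || any(vals < -tol) || any(vals > 1 + tol))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  if (abs(Q11 + Q12 + Q22 - 1) > 1e-8)
    stop("female genotype frequencies must sum to 1", call. = FALSE)
  if (!is.numeric(generation) || generation < 1)
    stop("generation must be an integer >= 1", call. = FALSE)
  structure(list(generation = as.integer(generation),
                 p1 = p1, p2 = 1 - p1,
                 Q11 = Q11, Q12 = Q12, Q22 = Q22),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "generation %d: males p1 = %.4f, p2 = %.4f | females Q11 = %.4f, Q12 = %.4f, Q22 = %.4f\n",
    x$generation, x$p1, x$p2, x$Q11, x$Q12, x$Q22))
  invisible(x)
}

#' Ratio-space recursion state
#'
#' The state used by the printed form of the recursion: `R1 = p1/p2`,
#' `R2 = Q11/Q12`, `R3 = Q22/Q12`.  Components are nonnegative and may be
#' infinite — a population founded entirely by A1 males has `R1 = Inf`.
#'
#' @param R1,R2,R3 Nonnegative (possibly infinite) frequency ratios.
#' @return An object of class `ratio_state`.
#' @export
ratio_state <- function(R1, R2, R3) {
  v <- c(R1 = R1, R2 = R2, R3 = R3)
  if (any(is.na(v)) || any(v < 0))
    stop("ratio components must be nonnegative (Inf allowed), not NA/NaN",
         call. = FALSE)
  structure(list(R1 = R1, R2 = R2, R3 = R3), class = "ratio_state")
}

#' @export
print.ratio_state <- function(x, ...) {
  cat(sprintf("R1 = %g, R2 = %g, R3 = %g\n", x$R1, x$R2, x$R3))
  invisible(x)
}

#' Founding adult state of the two reciprocal competition setups
#'
#' The two reciprocal crosses place the marked allele either on the maternal
#' X (setup I: all generation-1 males carry A2, `p1 = 0`) or on the paternal
#' X (setup II: all generation-1 males carry A1, `p1 = 1`).  In both setups
#' every generation-1 female is heterozygous (`Q12 = 1`).
#'
#' @param setup `"I"` or `"II"`.
#' @return A [population_state] at generation 1.
#' @examples
#' initial_state("I")
#' initial_state("II")
#' @export
initial_state <- function(setup) {
  setup <- match.arg(as.character(setup), c("I", "II"))
  p1 <- if (setup == "I") 0 else 1
  population_state(p1 = p1, Q11 = 0, Q12 = 1, Q22 = 0, generation = 1L)
}

#' One generation of X-linked selection, ratio form
#'
#' Advances the ratio state by one discrete generation using the printed
#' recursion:
#' \deqn{R_1' = \frac{(2 R_2 \beta + 1)\,\mu}{2 R_3 \gamma + 1},\qquad
#'       R_2' = \frac{(2 R_2 \beta + 1)\, R_1 \alpha \nu}{D},\qquad
#'       R_3' = \frac{(2 R_3 \gamma + 1)\,\epsilon}{D},}
#' with \eqn{D = 2 R_1 R_3 \alpha\gamma + 2 R_2 \beta + R_1 \alpha + 1}.
#'
#' The literal ratio recursion is only defined on interior (finite) states;
#' boundary states such as setup II's founding generation (`R1 = Inf`) must
#' be advanced in frequency space via [step_frequencies()].
#'
#' @param r A [ratio_state] with all components finite.
#' @param f A [fitness_ratios] object.
#' @return The next generation's [ratio_state].
#' @examples
#' step_ratios(ratio_state(0, 0, 0), fitness_ratios(mu = 2, epsilon = 3))
#' @export
step_ratios <- function(r, f) {
  stopifnot(inherits(r, "ratio_state"), inherits(f, "fitness_ratios"))
  if (!all(is.finite(c(r$R1, r$R2, r$R3))))
    stop("ratio recursion requires finite components; ",
         "advance boundary states with step_frequencies()", call. = FALSE)
  D <- 2 * r$R1 * r$R3 * f$alpha * f$gamma + 2 * r$R2 * f$beta +
    r$R1 * f$alpha + 1
  ratio_state(
    R1 = (2 * r$R2 * f$beta + 1) * f$mu / (2 * r$R3 * f$gamma + 1),
    R2 = (2 * r$R2 * f$beta + 1) * r$R1 * f$alpha * f$nu / D,
    R3 = (2 * r$R3 * f$gamma + 1) * f$epsilon / D
  )
}

#' One generation of X-linked selection, frequency form
#'
#' Algebraically equivalent to [step_ratios()] but expressed on genotype
#' frequencies, so boundary states (fixed males, absent female classes) are
#' handled without special cases.  Sons inherit their X from the mother;
#' the male recursion therefore weighs maternal classes by fertility and the
#' resulting hemizygotes by male viability:
#' \deqn{p_1' = \frac{(2 Q_{11}\beta + Q_{12})\,\mu}
#'                   {(2 Q_{11}\beta + Q_{12})\,\mu + 2 Q_{22}\gamma + Q_{12}}.}
#' Daughters combine a paternal and a maternal X; the three female classes
#' get zygote weights
#' \deqn{W_{11} = p_1\alpha (2 Q_{11}\beta + Q_{12})\,\nu,\quad
#'       W_{12} = p_1\alpha (2 Q_{22}\gamma + Q_{12})
#'              + p_2 (2 Q_{11}\beta + Q_{12}),\quad
#'       W_{22} = p_2 (2 Q_{22}\gamma + Q_{12})\,\epsilon,}
#' normalised to the next generation's `Q` frequencies.
#'
#' @param s A [population_state].
#' @param f A [fitness_ratios] object.
#' @return The [population_state] of the next generation (generation index
#'   incremented).
#' @examples
#' step_frequencies(initial_state("I"), neutral_fitness())
#' @export
step_frequencies <- function(s, f) {
  stopifnot(inherits(s, "population_state"), inherits(f, "fitness_ratios"))
  m1 <- 2 * s$Q11 * f$beta + s$Q12    # A1-bearing maternal output
  m2 <- 2 * s$Q22 * f$gamma + s$Q12   # A2-bearing maternal output
  p1n <- m1 * f$mu / (m1 * f$mu + m2)
  W11 <- s$p1 * f$alpha * m1 * f$nu
  W12 <- s$p1 * f$alpha * m2 + s$p2 * m1
  W22 <- s$p2 * m2 * f$epsilon
  W <- W11 + W12 + W22
  if (W <= 0)
    stop("all female zygote weights are zero; invalid population state",
         call. = FALSE)
  population_state(p1 = p1n, Q11 = W11 / W, Q12 = W12 / W, Q22 = W22 / W,
                   generation = s$generation + 1L)
}

#' Map a ratio state to male and homozygous-female frequencies
#'
#' `p1 = R1 / (R1 + 1)` and `Q11 = R2 / (R2 + R3 + 1)`, with the limit
#' conventions `p1 = 1` when `R1` is infinite and `Q11 = 1` (or `0`) when
#' `R2` (or `R3`) alone is infinite.
#'
#' @param r A [ratio_state].
#' @return Named numeric vector with components `p1` and `Q11`.
#' @export
ratios_to_frequencies <- function(r) {
  stopifnot(inherits(r, "ratio_state"))
  p1 <- if (is.infinite(r$R1)) 1 else r$R1 / (r$R1 + 1)
  if (is.infinite(r$R2) && is.infinite(r$R3))
    stop("Q11 undefined when R2 and R3 are both infinite", call. = FALSE)
  Q11 <- if (is.infinite(r$R2)) 1
         else if (is.infinite(r$R3)) 0
         else r$R2 / (r$R2 + r$R3 + 1)
  c(p1 = p1, Q11 = Q11)
}

#' Map a population state to the ratio representation
#'
#' `R1 = p1/p2` (infinite when males are fixed for A1), `R2 = Q11/Q12`,
#' `R3 = Q22/Q12` (infinite when the heterozygote class is absent but the
#' numerator class is present).  A 0/0 ratio — both classes absent — is
#' returned as 0 with a warning; such states never arise from the
#' experimental initial conditions.
#'
#' @param s A [population_state].
#' @return A [ratio_state].
#' @export
frequencies_to_ratios <- function(s) {
  stopifnot(inherits(s, "population_state"))
  safe_ratio <- function(num, den, what) {
    if (den > 0) return(num / den)
    if (num > 0) return(Inf)
    warning("ratio ", what, " is 0/0 (both classes absent); returning 0",
            call. = FALSE)
    0
  }
  ratio_state(R1 = safe_ratio(s$p1, s$p2, "R1 = p1/p2"),
              R2 = safe_ratio(s$Q11, s$Q12, "R2 = Q11/Q12"),
              R3 = safe_ratio(s$Q22, s$Q12, "R3 = Q22/Q12"))
}

#' Deterministic multi-generation trajectory
#'
#' Iterates the frequency-space recursion from a setup's founding state,
#' returning one row per generation.  Generation 1 is the founding adults;
#' `t_max = 20` reproduces the horizon of a 20-generation competition
#' experiment.
#'
#' @param setup `"I"` or `"II"`.
#' @param f A [fitness_ratios] object.
#' @param t_max Last generation to compute (integer >= 1).
#' @return A tibble with columns `setup`, `generation`, `p1`, `p2`, `Q11`,
#'   `Q12`, `Q22`.
#' @examples
#' trajectory("I", neutral_fitness(), 20)
#' @export
trajectory <- function(setup, f, t_max) {
  setup <- match.arg(as.character(setup), c("I", "II"))
  stopifnot(inherits(f, "fitness_ratios"))
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max < 1)
    stop("t_max must be an integer >= 1", call. = FALSE)
  t_max <- as.integer(t_max)
  s <- initial_state(setup)
  rows <- vector("list", t_max)
  rows[[1L]] <- s
  if (t_max > 1L) for (t in 2:t_max) rows[[t]] <- s <- step_frequencies(s, f)
  tibble::tibble(
    setup = setup,
    generation = vapply(rows, `[[`, integer(1), "generation"),
    p1 = vapply(rows, `[[`, numeric(1), "p1"),
    p2 = vapply(rows, `[[`, numeric(1), "p2"),
    Q11 = vapply(rows, `[[`, numeric(1), "Q11"),
    Q12 = vapply(rows, `[[`, numeric(1), "Q12"),
    Q22 = vapply(rows, `[[`, numeric(1), "Q22")
  )
}

#' Neutral long-run expectations for a setup
#'
#' With no selection the population allele frequency of A1 — two thirds
#' carried by females, one third by males — is conserved, and genotype
#' frequencies approach the random-mating equilibrium at that frequency:
#' `p1` tends to q and `Q11` to q^2, where
#' `q = (2 q_female(1) + q_male(1)) / 3`.  For the reciprocal setups this
#' gives q = 1/3 (setup I) and q = 2/3 (setup II).
#'
#' @param setup `"I"` or `"II"`.
#' @return Named numeric vector with components `p1` and `Q11`.
#' @examples
#' neutral_equilibrium("I")   # c(p1 = 1/3, Q11 = 1/9)
#' @export
neutral_equilibrium <- function(setup) {
  s <- initial_state(setup)
  q_f <- s$Q11 + s$Q12 / 2
  q_m <- s$p1
  q <- (2 * q_f + q_m) / 3
  c(p1 = q, Q11 = q^2)
}
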