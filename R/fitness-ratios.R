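#' Sex-specific fitness ratios for two X-linked alleles
#'
#' Bundle of the six dimensionless selection parameters of the two-allele
#' X-linked model.  Every quantity is a ratio of allele-1 (A1) to allele-2
#' (A2) effects; the underlying absolute fertilities and viabilities are
#' unidentifiable from adult frequency data and are never represented.
#'
#' Fertility ratios compare expected zygote output of parental genotypes;
#' viability ratios compare egg-to-adult survival.  Because the sex ratio is
#' assumed independent of maternal genotype, a single `beta`/`gamma` pair
#' serves both son and daughter production.
#'
#' @param alpha Male fertility ratio a1/a2 (A1 males vs A2 males).
#' @param beta Female fertility ratio of A1A1 vs A1A2 mothers.
#' @param gamma Female fertility ratio of A2A2 vs A1A2 mothers.
#' @param mu Male viability ratio u1/u2.
#' @param nu Female viability ratio of A1A1 vs A1A2.
#' @param epsilon Female viability ratio of A2A2 vs A1A2.
#'
#' @return An object of class `fitness_ratios`: a named list with the six
#'   components, all strictly positive and finite.
#' @examples
#' fitness_ratios(mu = 2)        # A1 males survive twice as well
#' neutral_fitness()             # all six ratios equal to 1
#' @export
fitness_ratios <- function(alpha = 1, beta = 1, gamma = 1,
                           mu = 1, nu = 1, epsilon = 1) {
  f <- list(alpha = alpha, beta = beta, gamma = gamma,
            mu = mu, nu = nu, epsilon = epsilon)
  for (nm in names(f)) {
    v <- f[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("fitness ratio '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  structure(f, class = "fitness_ratios")
}

#' @rdname fitness_ratios
#' @export
neutral_fitness <- function() fitness_ratios()

#' @export
print.fitness_ratios <- function(x, ...) {
  cat("X-linked fitness ratios (A1 : A2)\n")
  cat(sprintf("  fertility  alpha = %-8.4g beta = %-8.4g gamma = %-8.4g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  viability  mu    = %-8.4g nu   = %-8.4g epsilon = %-8.4g\n",
              x$mu, x$nu, x$epsilon))
  invisible(x)
}

#' Relabel the two alleles
#'
#' Swapping the labels A1 and A2 inverts the male ratios (`alpha`, `mu`,
#' which compare A1 directly to A2) and exchanges the two homozygote-vs-
#' heterozygote female ratios (`beta` with `gamma`, `nu` with `epsilon`,
#' which are both referenced to the label-symmetric heterozygote).  Used for
#' the label-swap symmetry property of the recursion.
#'
#' @param f A [fitness_ratios] object.
#' @return A [fitness_ratios] object describing the same biology with the
#'   allele labels exchanged.
#' @export
swap_alleles <- function(f) {
  stopifnot(inherits(f, "fitness_ratios"))
  fitness_ratios(alpha = 1 / f$alpha, beta = f$gamma, gamma = f$beta,
                 mu = 1 / f$mu, nu = f$epsilon, epsilon = f$nu)
}
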