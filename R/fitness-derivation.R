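#' Six sex-specific fitness differences between two gene variants
#'
#' Two parallel competitions share the reference allele A1 (wild type);
#' competition "plus" pits it against the functional variant and
#' competition "one" against the defective variant.  Because every fitted
#' ratio compares A1 to its competitor, the variant-vs-variant effect in
#' each sex/genotype class is a ratio of the two fits' ratios:
#'
#' \deqn{\Delta V_{male} = 1 - \mu_+/\mu_1 \qquad
#'       \Delta V_{het} = 1 - \nu_+/\nu_1 \qquad
#'       \Delta V_{hom} = 1 - (\epsilon_1/\nu_1) / (\epsilon_+/\nu_+)}
#' \deqn{\Delta F_{male} = 1 - \alpha_+/\alpha_1 \qquad
#'       \Delta F_{het} = 1 - \beta_+/\beta_1 \qquad
#'       \Delta F_{hom} = 1 - (\gamma_1/\beta_1) / (\gamma_+/\beta_+)}
#'
#' The homozygote contrasts are re-referenced through the heterozygote
#' class because `epsilon` and `gamma` compare the competitor homozygote to
#' the heterozygote, not to A1A1.  Positive values mean the functional
#' variant confers the advantage.
#'
#' @param fit_plus,fit_one [fit_fertility()] results (or any list carrying
#'   `alpha_hat`, `beta_hat`, `gamma_hat` and a `viability` element) for the
#'   functional-variant and defective-variant competitions.
#' @return A tibble with columns `component` (e.g. `"male_viability"`),
#'   `type` (`"viability"`/`"fertility"`) and `increase`.
#' @export
derive_differences <- function(fit_plus, fit_one) {
  vp <- fit_plus$viability; vo <- fit_one$viability
  rat <- function(num, den, what) {
    if (!is.finite(den) || den == 0)
      stop("zero or non-finite denominator in ", what, call. = FALSE)
    num / den
  }
  tibble::tibble(
    component = c("male_viability", "het_female_viability",
                  "hom_female_viability", "male_fertility",
                  "het_female_fertility", "hom_female_fertility"),
    type = rep(c("viability", "fertility"), each = 3),
    increase = c(
      1 - rat(vp$mu, vo$mu, "mu_one"),
      1 - rat(vp$nu, vo$nu, "nu_one"),
      1 - rat(rat(vo$epsilon, vo$nu, "nu_one"),
              rat(vp$epsilon, vp$nu, "nu_plus"), "epsilon_plus/nu_plus"),
      1 - rat(fit_plus$alpha_hat, fit_one$alpha_hat, "alpha_one"),
      1 - rat(fit_plus$beta_hat, fit_one$beta_hat, "beta_one"),
      1 - rat(rat(fit_one$gamma_hat, fit_one$beta_hat, "beta_one"),
              rat(fit_plus$gamma_hat, fit_plus$beta_hat, "beta_plus"),
              "gamma_plus/beta_plus")
    )
  )
}

#' Interval propagation for a fertility difference
#'
#' Propagates the two fits' profile-likelihood intervals through the
#' corresponding difference formula by worst-case interval arithmetic: for
#' `D = 1 - r_plus/r_one` the interval is
#' `[1 - hi_plus/lo_one, 1 - lo_plus/hi_one]`, and for the homozygote
#' ratio-of-ratios the four constituent bounds are combined the analogous
#' way.  Worst-case propagation is conservative — it assumes nothing about
#' the joint behaviour of the two independent fits.
#'
#' @param fit_plus,fit_one [fit_fertility()] results carrying profile CIs.
#' @param param `"alpha"`, `"beta"` or `"gamma"` (the latter giving the
#'   homozygote fertility contrast).
#' @return A list with `lo` and `hi`.
#' @export
fertility_difference_ci <- function(fit_plus, fit_one, param) {
  param <- match.arg(param, c("alpha", "beta", "gamma"))
  get_ci <- function(fit, p) {
    ci <- fit$ci[[p]]
    if (is.null(ci) || any(!is.finite(c(ci$lo, ci$hi))))
      stop("fit does not carry a finite profile CI for ", p, call. = FALSE)
    if (ci$lo <= 0)
      stop("nonpositive CI bound for ", p, call. = FALSE)
    ci
  }
  if (param != "gamma") {
    cp <- get_ci(fit_plus, param); co <- get_ci(fit_one, param)
    list(lo = 1 - cp$hi / co$lo, hi = 1 - cp$lo / co$hi)
  } else {
    gp <- get_ci(fit_plus, "gamma"); go <- get_ci(fit_one, "gamma")
    bp <- get_ci(fit_plus, "beta"); bo <- get_ci(fit_one, "beta")
    # D = 1 - (g1/b1)/(g+/b+) = 1 - g1*b+ / (b1*g+)
    rho_hi <- go$hi * bp$hi / (bo$lo * gp$lo)
    rho_lo <- go$lo * bp$lo / (bo$hi * gp$hi)
    list(lo = 1 - rho_hi, hi = 1 - rho_lo)
  }
}

#' Chi-squared tests for viability differences between two competitions
#'
#' For each viability component, compares the generation-2 class counts of
#' the two competitions in a 2x2 contingency table with Pearson's
#' chi-squared test (1 d.f., no continuity correction): white vs non-white
#' G2 males pooled over setups (`mu`), white vs non-white setup-II G2
#' females (`nu`), and genotype-resolved A2A2 vs A1A2 setup-I G2 females
#' (`epsilon`).
#'
#' @param g2_plus,g2_one Count tables for the two competitions; only
#'   generation-2 rows are used.
#' @return A tibble with one row per component: `component`, `statistic`,
#'   `p_value` (`NA` with a warning when a table margin is zero).
#' @export
viability_significance <- function(g2_plus, g2_one) {
  tabs <- function(counts) {
    v <- estimate_viability(counts)
    v$counts
  }
  tp <- tabs(g2_plus); to <- tabs(g2_one)
  one_test <- function(comp) {
    tab <- rbind(plus = tp[[comp]], one = to[[comp]])
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("zero margin in the ", comp, " table; test inestimable",
              call. = FALSE)
      return(c(statistic = NA_real_, p_value = NA_real_))
    }
    ct <- stats::chisq.test(tab, correct = FALSE)
    c(statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  res <- t(vapply(c("mu", "nu", "epsilon"), one_test, numeric(2)))
  tibble::tibble(
    component = c("male_viability", "het_female_viability",
                  "hom_female_viability"),
    statistic = unname(res[, "statistic"]),
    p_value = unname(res[, "p_value"]))
}

#' Full six-component difference table for two competitions
#'
#' Convenience wrapper combining [derive_differences()],
#' [fertility_difference_ci()] and (when generation-2 counts are supplied)
#' [viability_significance()] into the six-row summary table.
#'
#' @inheritParams derive_differences
#' @param counts_plus,counts_one Optional count tables with generation-2
#'   rows, enabling the viability chi-squared tests.
#' @return A tibble with columns `component`, `type`, `increase`,
#'   `ci_lo`, `ci_hi` (fertility rows), `p_value` (viability rows).
#' @export
fitness_difference_table <- function(fit_plus, fit_one,
                                     counts_plus = NULL, counts_one = NULL) {
  out <- derive_differences(fit_plus, fit_one)
  out$ci_lo <- NA_real_; out$ci_hi <- NA_real_; out$p_value <- NA_real_
  for (p in c("alpha", "beta", "gamma")) {
    ci <- fertility_difference_ci(fit_plus, fit_one, p)
    row <- match(p, c("alpha", "beta", "gamma")) + 3L
    out$ci_lo[row] <- ci$lo; out$ci_hi[row] <- ci$hi
  }
  if (!is.null(counts_plus) && !is.null(counts_one)) {
    vs <- viability_significance(counts_plus, counts_one)
    out$p_value[1:3] <- vs$p_value
  }
  out
}
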