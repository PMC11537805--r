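#' Validate a table of scored adult counts
#'
#' Count tables hold one row per (setup, replicate, generation): total and
#' white-eyed males (`males_total`, `males_white`), total and white-eyed
#' females (`females_total`, `females_white`), and — where female genotypes
#' were resolved, which the pipeline requires at setup-I generation 2 —
#' heterozygous and marked-homozygote female counts (`females_het`,
#' `females_hom2`).  White-eyed males carry A1; white-eyed females are A1A1.
#'
#' @param counts A data frame with the columns above.
#' @param file Optional file name used in error messages.
#' @return The validated table as a tibble (invisibly usable downstream).
#' @export
validate_counts <- function(counts, file = NULL) {
  required <- c("setup", "replicate", "generation", "males_total",
                "males_white", "females_total", "females_white",
                "females_het", "females_hom2")
  where <- if (is.null(file)) "" else paste0(" in '", file, "'")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0)
    stop("count table", where, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  counts <- tibble::as_tibble(counts)[required]
  # optional columns read from CSV come back logical when entirely empty
  for (cc in c("females_het", "females_hom2"))
    if (is.logical(counts[[cc]]) && all(is.na(counts[[cc]])))
      counts[[cc]] <- NA_integer_
  bad_row <- function(i, msg)
    stop("count table", where, ", row ", i, ": ", msg, call. = FALSE)
  if (!all(counts$setup %in% c("I", "II")))
    bad_row(which(!counts$setup %in% c("I", "II"))[1],
            "setup must be 'I' or 'II'")
  int_cols <- setdiff(required, "setup")
  for (cc in int_cols) {
    v <- counts[[cc]]
    if (!is.numeric(v)) bad_row(1, paste0("column ", cc, " must be numeric"))
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad) > 0)
      bad_row(bad[1], paste0(cc, " must be a nonnegative integer"))
  }
  for (cc in c("replicate", "generation", "males_total", "males_white",
               "females_total", "females_white")) {
    bad <- which(is.na(counts[[cc]]))
    if (length(bad) > 0) bad_row(bad[1], paste0(cc, " may not be missing"))
  }
  bad <- which(counts$males_white > counts$males_total)
  if (length(bad) > 0) bad_row(bad[1], "males_white exceeds males_total")
  bad <- which(counts$females_white > counts$females_total)
  if (length(bad) > 0) bad_row(bad[1], "females_white exceeds females_total")
  res <- !is.na(counts$females_het) & !is.na(counts$females_hom2)
  bad <- which(res & counts$females_white + counts$females_het +
                 counts$females_hom2 != counts$females_total)
  if (length(bad) > 0)
    bad_row(bad[1],
            "females_white + females_het + females_hom2 != females_total")
  key <- paste(counts$setup, counts$replicate, counts$generation)
  bad <- which(duplicated(key))
  if (length(bad) > 0)
    bad_row(bad[1], "duplicate (setup, replicate, generation) row")
  counts
}

# Pool replicate counts within setup and generation; rows sorted by
# setup then generation (the order the likelihood kernels expect).
pool_counts <- function(counts, generations = NULL) {
  if (!is.null(generations))
    counts <- counts[counts$generation %in% generations, , drop = FALSE]
  key <- interaction(counts$setup, counts$generation, drop = TRUE)
  agg <- function(col) as.numeric(tapply(counts[[col]], key, sum))
  out <- tibble::tibble(
    setup = as.character(tapply(counts$setup, key, `[`, 1)),
    generation = as.integer(tapply(counts$generation, key, `[`, 1)),
    males_total = agg("males_total"),
    males_white = agg("males_white"),
    females_total = agg("females_total"),
    females_white = agg("females_white")
  )
  out[order(out$setup, out$generation), , drop = FALSE]
}

#' Estimate viability ratios from generation-2 adult counts
#'
#' At generation 2 the recursion reduces to closed forms that identify the
#' three viability ratios from class counts alone: in both setups the male
#' ratio satisfies `R1(2) = mu`, so `mu` is estimated by pooling white vs
#' non-white generation-2 males across setups and replicates; in setup II
#' only the A1A1 and A1A2 female classes exist and `R2(2) = nu`, estimated
#' as white vs non-white setup-II females; in setup I only the A1A2 and
#' A2A2 classes exist and `R3(2) = epsilon`, which requires the setup-I
#' generation-2 females to be genotype-resolved (`females_het`,
#' `females_hom2`) because the two classes share the non-white phenotype.
#'
#' Pooling counts before taking the ratio is the binomial MLE (as opposed
#' to averaging per-bottle ratios).
#'
#' @param counts A count table (see [validate_counts()]); only generation-2
#'   rows are used.
#' @return An object of class `viability_estimate` with elements `mu`,
#'   `nu`, `epsilon` and the source counts retained for significance tests.
#' @export
estimate_viability <- function(counts) {
  counts <- validate_counts(counts)
  g2 <- counts[counts$generation == 2L, , drop = FALSE]
  if (!any(g2$setup == "I") || !any(g2$setup == "II"))
    stop("viability estimation needs generation-2 counts from both setups",
         call. = FALSE)
  ratio_or_stop <- function(num, den, what)
    if (den == 0)
      stop(what, " is inestimable: pooled denominator count is 0",
           call. = FALSE)
    else num / den

  m_white <- sum(g2$males_white)
  m_other <- sum(g2$males_total - g2$males_white)
  mu_hat <- ratio_or_stop(m_white, m_other, "mu (white/non-white G2 males)")

  s2 <- g2[g2$setup == "II", , drop = FALSE]
  f_white <- sum(s2$females_white)
  f_other <- sum(s2$females_total - s2$females_white)
  nu_hat <- ratio_or_stop(f_white, f_other,
                          "nu (white/non-white setup-II G2 females)")

  s1 <- g2[g2$setup == "I", , drop = FALSE]
  if (any(is.na(s1$females_het)) || any(is.na(s1$females_hom2)))
    stop("epsilon is identifiable only from genotype-resolved setup-I ",
         "generation-2 female counts (females_het, females_hom2); ",
         "these are missing", call. = FALSE)
  hom2 <- sum(s1$females_hom2)
  het <- sum(s1$females_het)
  eps_hat <- ratio_or_stop(hom2, het,
                           "epsilon (A2A2/A1A2 setup-I G2 females)")
  if (mu_hat == 0 || nu_hat == 0 || eps_hat == 0)
    stop("a pooled numerator count of 0 puts a viability ratio on the ",
         "boundary; the ratio is inestimable", call. = FALSE)
  structure(
    list(mu = mu_hat, nu = nu_hat, epsilon = eps_hat,
         counts = list(
           mu = c(white = m_white, nonwhite = m_other),
           nu = c(white = f_white, nonwhite = f_other),
           epsilon = c(hom2 = hom2, het = het))),
    class = "viability_estimate")
}

#' @export
print.viability_estimate <- function(x, ...) {
  cat(sprintf(
    "viability ratios from G2 counts: mu = %.4f, nu = %.4f, epsilon = %.4f\n",
    x$mu, x$nu, x$epsilon))
  invisible(x)
}

#' Exact binomial confidence intervals for the viability ratios
#'
#' The generation-2 estimators are count ratios k1/k2; a Clopper-Pearson
#' interval on the underlying proportion k1/(k1+k2) transforms monotonically
#' to an interval on the ratio via r = p/(1-p).  This uncertainty summary is
#' an extension of the G2 point-estimation procedure, which itself carries
#' no interval.
#'
#' @param v A [estimate_viability()] result.
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per ratio: `parameter`, `estimate`, `lo`,
#'   `hi`.
#' @export
viability_ci <- function(v, level = 0.95) {
  stopifnot(inherits(v, "viability_estimate"))
  one <- function(k) {
    ci <- stats::binom.test(k[1], sum(k), conf.level = level)$conf.int
    c(lo = ci[1] / (1 - ci[1]), hi = ci[2] / (1 - ci[2]))
  }
  out <- t(vapply(v$counts, one, numeric(2)))
  tibble::tibble(parameter = c("mu", "nu", "epsilon"),
                 estimate = c(v$mu, v$nu, v$epsilon),
                 lo = out[, "lo"], hi = out[, "hi"])
}

# log-likelihood kernel with the boundary convention shared with the
# compiled grid evaluator
binom_loglik_term <- function(k, total, p) {
  if (p <= 0) return(if (k > 0) -Inf else 0)
  if (p >= 1) return(if (k < total) -Inf else 0)
  k * log(p) + (total - k) * log(1 - p)
}

#' Composite binomial log-likelihood of adult counts under the model
#'
#' Treats the scored generations as independent binomial samples around the
#' deterministic trajectory: white-male counts around `p1(t)` and
#' white-female counts around `Q11(t)`, summed over setups, replicates and
#' scored generations.  The binomial coefficients are a parameter-free
#' constant and are omitted, so values are comparable only within a dataset.
#'
#' @param f A [fitness_ratios] object (all six ratios).
#' @param counts A count table (see [validate_counts()]).
#' @param fit_generations Generations entering the sum (default
#'   `c(3, 8, 12, 20)`; generation 1 is fixed by design and generation 2 is
#'   reserved for viability estimation).
#' @return The log-likelihood (may be `-Inf` when the model makes observed
#'   counts impossible).
#' @export
composite_loglik <- function(f, counts, fit_generations = c(3, 8, 12, 20)) {
  stopifnot(inherits(f, "fitness_ratios"))
  counts <- validate_counts(counts)
  obs <- counts[counts$generation %in% fit_generations, , drop = FALSE]
  if (nrow(obs) == 0)
    stop("no observations at the requested fit generations", call. = FALSE)
  lnL <- 0
  for (setup in unique(obs$setup)) {
    rows <- obs[obs$setup == setup, , drop = FALSE]
    traj <- trajectory(setup, f, max(rows$generation))
    for (i in seq_len(nrow(rows))) {
      pred <- traj[traj$generation == rows$generation[i], , drop = FALSE]
      if (any(is.na(c(pred$p1, pred$Q11))))
        stop("internal error: NaN model prediction", call. = FALSE)
      lnL <- lnL +
        binom_loglik_term(rows$males_white[i], rows$males_total[i], pred$p1) +
        binom_loglik_term(rows$females_white[i], rows$females_total[i],
                          pred$Q11)
    }
  }
  lnL
}

#' Specify a one-dimensional search grid for a fertility ratio
#'
#' @param scale `"linear"` (values `lo, lo+step, ..., hi`) or `"log10"`
#'   (values `10^k` for `k` from `log10(lo)` to `log10(hi)` in steps of
#'   `step` log10-units).
#' @param lo,hi Grid bounds on the ratio scale (both positive).
#' @param step Grid spacing: on the ratio scale for `"linear"`, on the
#'   log10 scale for `"log10"`.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec("log10", 0.1, 10, 0.01)    # 201-point coarse screen
#' grid_spec("linear", 0.5, 1.5, 0.01)  # 101-point fine grid
#' @export
grid_spec <- function(scale = c("linear", "log10"), lo, hi, step) {
  scale <- match.arg(scale)
  if (!is.numeric(c(lo, hi, step)) || lo >= hi || step <= 0)
    stop("grid requires lo < hi and step > 0", call. = FALSE)
  if (lo <= 0)
    stop("fertility ratios are positive; grid bounds must be > 0",
         call. = FALSE)
  values <- if (scale == "linear") seq(lo, hi, by = step)
            else 10^seq(log10(lo), log10(hi), by = step)
  if (length(values) < 2)
    stop("grid must contain at least 2 points", call. = FALSE)
  structure(list(scale = scale, lo = lo, hi = hi, step = step,
                 values = values),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @export
default_coarse_grid <- function() grid_spec("log10", 0.1, 10, 0.01)

#' @rdname grid_spec
#' @export
default_fine_grid <- function() grid_spec("linear", 0.5, 1.5, 0.01)

# Prepare pooled per-setup observation vectors for the compiled kernel.
prep_kernel_data <- function(counts, fit_generations) {
  pooled <- pool_counts(counts, fit_generations)
  if (nrow(pooled) == 0)
    stop("no observations at the requested fit generations", call. = FALSE)
  setups <- sort(unique(pooled$setup))
  list(
    setups = setups,
    p1_init = vapply(setups, function(s) initial_state(s)$p1, numeric(1)),
    gens = lapply(setups, function(s)
      as.integer(pooled$generation[pooled$setup == s])),
    m = lapply(setups, function(s) pooled$males_white[pooled$setup == s]),
    M = lapply(setups, function(s) pooled$males_total[pooled$setup == s]),
    n = lapply(setups, function(s) pooled$females_white[pooled$setup == s]),
    N = lapply(setups, function(s) pooled$females_total[pooled$setup == s]),
    pooled = pooled
  )
}

# Evaluate the composite log-likelihood over a full 3-parameter grid.
# Returns an array dim (n_alpha, n_beta, n_gamma).
eval_grid <- function(grids, viability, kd) {
  lnL <- grid_loglik_cpp(grids$alpha, grids$beta, grids$gamma,
                         viability$mu, viability$nu, viability$epsilon,
                         kd$p1_init, kd$gens, kd$m, kd$M, kd$n, kd$N)
  array(lnL, dim = c(length(grids$alpha), length(grids$beta),
                     length(grids$gamma)))
}

as_grid_triple <- function(g, what) {
  if (is.null(g)) return(NULL)
  if (inherits(g, "grid_spec")) g <- list(alpha = g, beta = g, gamma = g)
  if (!is.list(g) || length(g) != 3 ||
      !all(vapply(g, inherits, logical(1), "grid_spec")))
    stop(what, " grid must be a grid_spec or a list of three grid_specs",
         call. = FALSE)
  names(g) <- c("alpha", "beta", "gamma")
  lapply(g, `[[`, "values")
}

# All grid triples attaining the array maximum, in lexicographic
# (alpha, beta, gamma) order.
grid_argmax <- function(lnL_arr, grids) {
  mx <- max(lnL_arr)
  idx <- which(lnL_arr == mx, arr.ind = TRUE)
  hits <- tibble::tibble(alpha = grids$alpha[idx[, 1]],
                         beta = grids$beta[idx[, 2]],
                         gamma = grids$gamma[idx[, 3]],
                         lnL = mx)
  hits[order(hits$alpha, hits$beta, hits$gamma), , drop = FALSE]
}

#' Grid-search maximum-likelihood fit of the fertility ratios
#'
#' With the viability ratios fixed at their generation-2 estimates
#' (plugged in, never re-estimated), exhaustively evaluates the composite
#' binomial log-likelihood over a coarse log-spaced screen (default
#' `10^k`, k = -1.00, -0.99, ..., 1.00) and a fine linear grid (default
#' 0.50 to 1.50 by 0.01) for each of `alpha`, `beta`, `gamma`, and returns
#' the argmax over the union of both grids.  Exact ties are recorded and
#' broken by the lexicographically smallest (alpha, beta, gamma) triple.
#' Profile-likelihood confidence intervals (see [profile_ci()]) are
#' computed on the fine grid for each fertility parameter.
#'
#' @param counts A count table (see [validate_counts()]).
#' @param viability A `viability_estimate` (or any list with `mu`, `nu`,
#'   `epsilon`).
#' @param coarse,fine A [grid_spec] applied to all three parameters, or a
#'   list of three; `coarse = NULL` searches the fine grid only.
#' @param fit_generations Generations entering the likelihood (default
#'   `c(3, 8, 12, 20)`).
#' @param ci_level Confidence level for the profile intervals.
#' @return An object of class `fertility_fit`.
#' @export
fit_fertility <- function(counts, viability,
                          coarse = default_coarse_grid(),
                          fine = default_fine_grid(),
                          fit_generations = c(3, 8, 12, 20),
                          ci_level = 0.95) {
  counts <- validate_counts(counts)
  if (!all(c("mu", "nu", "epsilon") %in% names(viability)))
    stop("viability must provide mu, nu and epsilon", call. = FALSE)
  if (is.null(fine))
    stop("a fine grid is required (profile intervals live on it)",
         call. = FALSE)
  coarse_grids <- as_grid_triple(coarse, "coarse")
  fine_grids <- as_grid_triple(fine, "fine")
  kd <- prep_kernel_data(counts, fit_generations)

  fine_lnL <- eval_grid(fine_grids, viability, kd)
  hits <- grid_argmax(fine_lnL, fine_grids)
  if (!is.null(coarse_grids)) {
    coarse_lnL <- eval_grid(coarse_grids, viability, kd)
    coarse_hits <- grid_argmax(coarse_lnL, coarse_grids)
    if (coarse_hits$lnL[1] > hits$lnL[1]) hits <- coarse_hits
    else if (coarse_hits$lnL[1] == hits$lnL[1])
      hits <- rbind(hits, coarse_hits)
  }
  # dedupe triples present in both grids, keep lexicographic order
  hits <- hits[!duplicated(hits[c("alpha", "beta", "gamma")]), , drop = FALSE]
  hits <- hits[order(hits$alpha, hits$beta, hits$gamma), , drop = FALSE]

  fit <- structure(
    list(viability = viability,
         alpha_hat = hits$alpha[1], beta_hat = hits$beta[1],
         gamma_hat = hits$gamma[1],
         lnL_max = hits$lnL[1],
         ties = hits,
         fine_grid = fine_grids, fine_lnL = fine_lnL,
         coarse_spec = coarse, fine_spec = fine,
         fit_generations = sort(unique(fit_generations)),
         setups = kd$setups, pooled_counts = kd$pooled,
         ci_level = ci_level),
    class = "fertility_fit")
  fit$ci <- lapply(stats::setNames(nm = c("alpha", "beta", "gamma")),
                   function(p) profile_ci(fit, p, level = ci_level))
  fit
}

#' @export
print.fertility_fit <- function(x, ...) {
  cat("Fertility-ratio fit (composite binomial likelihood, grid search)\n")
  cat(sprintf("  viability plug-in: mu = %.4f, nu = %.4f, epsilon = %.4f\n",
              x$viability$mu, x$viability$nu, x$viability$epsilon))
  for (p in c("alpha", "beta", "gamma")) {
    ci <- x$ci[[p]]
    cat(sprintf("  %-5s = %.3f  [%s, %s] (%.0f%% profile)\n", p,
                x[[paste0(p, "_hat")]],
                formatC(ci$lo, format = "f", digits = 3),
                formatC(ci$hi, format = "f", digits = 3),
                100 * x$ci_level))
  }
  cat(sprintf("  lnL_max = %.4f over generations {%s}, setups {%s}\n",
              x$lnL_max, paste(x$fit_generations, collapse = ", "),
              paste(x$setups, collapse = ", ")))
  if (nrow(x$ties) > 1)
    cat("  note:", nrow(x$ties), "grid points tie at the maximum\n")
  invisible(x)
}

#' Profile-likelihood confidence interval for a fertility ratio
#'
#' For each fine-grid value of the parameter, re-maximises the
#' log-likelihood over the other two fertility parameters; the interval is
#' the range of values whose profile stays within half the chi-squared
#' quantile (1 d.f.; 3.841/2 = 1.9207 at 95%) of the fitted maximum.
#' Intervals are clipped to the fine grid; `at_lower`/`at_upper` flag an
#' interval that abuts a grid bound (the data do not bound the parameter
#' within the searched range).
#'
#' @param fit A [fit_fertility()] result.
#' @param param One of `"alpha"`, `"beta"`, `"gamma"`.
#' @param level Confidence level (default 0.95).
#' @return A list with `lo`, `hi`, `at_lower`, `at_upper`, `level`.
#' @export
profile_ci <- function(fit, param, level = 0.95) {
  stopifnot(inherits(fit, "fertility_fit"))
  param <- match.arg(param, c("alpha", "beta", "gamma"))
  margin <- match(param, c("alpha", "beta", "gamma"))
  prof <- apply(fit$fine_lnL, margin, max)
  drop <- stats::qchisq(level, df = 1) / 2
  keep <- prof >= fit$lnL_max - drop
  vals <- fit$fine_grid[[param]]
  if (!any(keep)) {
    warning("profile for ", param, " never reaches within the drop of the ",
            "maximum on the fine grid (maximum lies elsewhere); returning NA",
            call. = FALSE)
    return(list(lo = NA_real_, hi = NA_real_, at_lower = FALSE,
                at_upper = FALSE, level = level))
  }
  list(lo = min(vals[keep]), hi = max(vals[keep]),
       at_lower = keep[1], at_upper = keep[length(keep)],
       level = level)
}
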