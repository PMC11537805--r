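#' Read a scored-count table from CSV
#'
#' Expects the documented header `setup,replicate,generation,males_total,
#' males_white,females_total,females_white,females_het,females_hom2`
#' (the last two columns may be empty except where genotype-resolved
#' counts are needed).  Validation failures report the file and row.
#'
#' @param path Path to a CSV file.
#' @return A validated count tibble.
#' @examples
#' # a small synthetic competition dataset ships with the package
#' path <- system.file("extdata", "synthetic_counts_example.csv",
#'                     package = "xlinksel")
#' head(read_counts(path))
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(setup = "character"))
  validate_counts(df, file = path)
}

#' Write a scored-count table to CSV
#'
#' @param counts A count table (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  utils::write.csv(counts, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a fertility fit as a structured JSON report
#'
#' Persists the estimates, viability plug-in, profile CIs, maximised
#' log-likelihood, tie list, grid metadata and the generations/setups
#' actually used.  The full fine-grid likelihood surface is not stored.
#'
#' @param fit A [fit_fertility()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "fertility_fit"))
  spec_meta <- function(sp) {
    if (is.null(sp)) return(NULL)
    if (inherits(sp, "grid_spec")) sp <- list(sp)
    lapply(sp, function(g)
      list(scale = g$scale, lo = g$lo, hi = g$hi, step = g$step,
           n = length(g$values)))
  }
  report <- list(
    viability = list(mu = fit$viability$mu, nu = fit$viability$nu,
                     epsilon = fit$viability$epsilon),
    fertility = list(alpha = fit$alpha_hat, beta = fit$beta_hat,
                     gamma = fit$gamma_hat),
    lnL_max = fit$lnL_max,
    ci = fit$ci,
    ci_level = fit$ci_level,
    ties = as.list(fit$ties[c("alpha", "beta", "gamma")]),
    grids = list(coarse = spec_meta(fit$coarse_spec),
                 fine = spec_meta(fit$fine_spec)),
    fit_generations = fit$fit_generations,
    setups = fit$setups)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit report back as a lightweight fit object
#'
#' Reconstructs enough of a [fit_fertility()] result (estimates, viability,
#' profile CIs) to drive [derive_differences()] and
#' [fertility_difference_ci()]; the likelihood surface is not restored.
#'
#' @param path Path written by [write_fit_report()].
#' @return A list of class `fertility_fit_summary`.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(viability = rep$viability,
         alpha_hat = rep$fertility$alpha, beta_hat = rep$fertility$beta,
         gamma_hat = rep$fertility$gamma,
         lnL_max = rep$lnL_max, ci = rep$ci, ci_level = rep$ci_level,
         fit_generations = rep$fit_generations, setups = rep$setups),
    class = "fertility_fit_summary")
}

#' Resolve a pipeline run configuration
#'
#' Materialises every default so the configuration echoed into the output
#' directory is fully explicit.  `counts_one` is optional: with a single
#' competition the difference stage is skipped.
#'
#' @param counts_plus Path to (or in-memory table of) the
#'   functional-variant competition counts.
#' @param counts_one Optional counts for the defective-variant competition.
#' @param fit_generations Generations entering the fertility likelihood.
#' @param coarse,fine Grid specifications passed to [fit_fertility()].
#' @param ci_level Profile-CI confidence level.
#' @param out_dir Output directory (created if absent).
#' @param make_plots Write the frequency-vs-generation diagnostic plot
#'   (needs ggplot2).
#' @param seed Seed recorded in the run log (the deterministic pipeline
#'   itself draws no random numbers).
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts_plus, counts_one = NULL,
                       fit_generations = c(3, 8, 12, 20),
                       coarse = default_coarse_grid(),
                       fine = default_fine_grid(),
                       ci_level = 0.95, out_dir = "xlinksel-run",
                       make_plots = FALSE, seed = 1L) {
  structure(list(counts_plus = counts_plus, counts_one = counts_one,
                 fit_generations = sort(unique(as.integer(fit_generations))),
                 coarse = coarse, fine = fine,
                 ci_level = ci_level, out_dir = out_dir,
                 make_plots = isTRUE(make_plots), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts the keys of [run_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML document.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  keys <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(keys), allowed)
  if (length(unknown) > 0)
    stop("unknown config keys in '", path, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (g in intersect(c("coarse", "fine"), names(keys)))
    if (!is.null(keys[[g]])) keys[[g]] <- do.call(grid_spec, keys[[g]])
  do.call(run_config, keys)
}

resolve_counts <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_counts(x) else validate_counts(x, file = what)
}

#' Run the full fitness-component pipeline
#'
#' Per competition: generation-2 viability estimation, fertility grid fit
#' with profile CIs, JSON fit report.  With two competitions, the
#' six-component fitness-difference table (CSV) is derived as well.
#' Optionally writes a frequency-vs-generation diagnostic plot (observed
#' points, fitted and neutral curves per setup) and always writes a run
#' log with the resolved configuration.
#'
#' @param config A [run_config()] (or path handled by [read_run_config()]).
#' @return Invisibly, a list with the fits, the difference table (or
#'   `NULL`) and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts_plus <- resolve_counts(config$counts_plus, "counts_plus")
  counts_one <- resolve_counts(config$counts_one, "counts_one")
  max_gen_avail <- max(counts_plus$generation,
                       if (!is.null(counts_one)) counts_one$generation)
  if (max(config$fit_generations) > max_gen_avail)
    stop("config requests generation ", max(config$fit_generations),
         " but data stop at generation ", max_gen_avail, call. = FALSE)

  fit_one_comp <- function(counts, label) {
    viab <- tryCatch(estimate_viability(counts),
                     error = function(e) stop("[viability:", label, "] ",
                                              conditionMessage(e),
                                              call. = FALSE))
    fit <- tryCatch(fit_fertility(counts, viab,
                                  coarse = config$coarse, fine = config$fine,
                                  fit_generations = config$fit_generations,
                                  ci_level = config$ci_level),
                    error = function(e) stop("[fertility:", label, "] ",
                                             conditionMessage(e),
                                             call. = FALSE))
    path <- file.path(config$out_dir, paste0("fit_", label, ".json"))
    write_fit_report(fit, path)
    list(fit = fit, path = path, counts = counts)
  }
  res_plus <- fit_one_comp(counts_plus, "plus")
  res_one <- if (!is.null(counts_one)) fit_one_comp(counts_one, "one")

  diff_tab <- NULL
  if (!is.null(res_one)) {
    diff_tab <- fitness_difference_table(res_plus$fit, res_one$fit,
                                         counts_plus, counts_one)
    utils::write.csv(diff_tab,
                     file.path(config$out_dir, "fitness_differences.csv"),
                     row.names = FALSE, na = "")
  } else {
    message("single competition supplied; difference stage skipped")
  }
  if (config$make_plots)
    plot_trajectory_fit(res_plus$fit, counts_plus,
                        file.path(config$out_dir, "trajectories.pdf"))
  log_path <- file.path(config$out_dir, "run_log.json")
  spec_meta <- function(sp)
    if (inherits(sp, "grid_spec"))
      list(scale = sp$scale, lo = sp$lo, hi = sp$hi, step = sp$step)
    else NULL
  counts_prov <- function(x)
    if (is.character(x)) x else if (is.null(x)) NULL else "<in-memory table>"
  jsonlite::write_json(
    list(config = list(counts_plus = counts_prov(config$counts_plus),
                       counts_one = counts_prov(config$counts_one),
                       fit_generations = config$fit_generations,
                       coarse = spec_meta(config$coarse),
                       fine = spec_meta(config$fine),
                       ci_level = config$ci_level,
                       out_dir = config$out_dir, seed = config$seed),
         package_version = as.character(utils::packageVersion("xlinksel")),
         competitions = if (is.null(res_one)) "plus" else c("plus", "one")),
    log_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(list(fit_plus = res_plus$fit,
                 fit_one = if (!is.null(res_one)) res_one$fit,
                 differences = diff_tab,
                 paths = c(fit_plus = res_plus$path,
                           fit_one = if (!is.null(res_one)) res_one$path,
                           log = log_path)))
}

#' Diagnostic plot of observed and fitted frequencies
#'
#' Plots observed white-male (`p1`) and white-female (`Q11`) frequencies
#' per setup against generation, with the fitted-model and neutral-model
#' trajectories overlaid.
#'
#' @param fit A [fit_fertility()] result.
#' @param counts The count table the fit used.
#' @param path Optional output file (PDF); when `NULL` the plot object is
#'   returned.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_trajectory_fit <- function(fit, counts, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  counts <- validate_counts(counts)
  t_max <- max(counts$generation)
  f_hat <- fitness_ratios(alpha = fit$alpha_hat, beta = fit$beta_hat,
                          gamma = fit$gamma_hat, mu = fit$viability$mu,
                          nu = fit$viability$nu,
                          epsilon = fit$viability$epsilon)
  curves <- do.call(rbind, lapply(unique(counts$setup), function(s) {
    rbind(cbind(trajectory(s, f_hat, t_max), model = "fitted"),
          cbind(trajectory(s, neutral_fitness(), t_max), model = "neutral"))
  }))
  long_c <- rbind(
    data.frame(setup = curves$setup, generation = curves$generation,
               model = curves$model, stat = "p1", value = curves$p1),
    data.frame(setup = curves$setup, generation = curves$generation,
               model = curves$model, stat = "Q11", value = curves$Q11))
  obs <- rbind(
    data.frame(setup = counts$setup, generation = counts$generation,
               stat = "p1",
               value = counts$males_white / counts$males_total),
    data.frame(setup = counts$setup, generation = counts$generation,
               stat = "Q11",
               value = counts$females_white / counts$females_total))
  p <- ggplot2::ggplot(long_c,
                       ggplot2::aes(x = generation, y = value,
                                    linetype = model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs,
                        mapping = ggplot2::aes(x = generation, y = value),
                        inherit.aes = FALSE, shape = 17, colour = "#2166ac") +
    ggplot2::facet_grid(stat ~ setup,
                        labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "frequency of the A1 class",
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 7, height = 5)
  invisible(p)
}
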