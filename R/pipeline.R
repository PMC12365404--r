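# End-to-end pipeline runners. Each writes delimited outputs plus a
# manifest (inputs, their md5 sums, settings, seed, package version)
# sufficient to reproduce the run.

write_manifest <- function(out_dir, step, inputs = character(0), settings = list()) {
  sums <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    step = step,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package = "cwtstray",
    version = as.character(utils::packageVersion("cwtstray")),
    inputs = sums,
    settings = settings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the recovery-to-rates pipeline on files
#'
#' Reads releases, recoveries and the river map, classifies and expands
#' every recovery, tabulates donor and recipient rates per hatchery-year
#' and the per-hatchery summary, and writes `rates.csv`, `summary.csv`,
#' `label_counts.csv` and a manifest to `out_dir`. Counts per label and
#' per exclusion reason are reported via `message()`.
#'
#' @param releases,recoveries,river_map paths to the three input files.
#' @param out_dir output directory (created if needed).
#' @param dialect a [cwt_dialect()].
#' @param scope recipient attribution, see [rate_table()].
#' @return invisibly, a list with `classified`, `rates`, `summary`.
#' @export
run_rates_pipeline <- function(releases, recoveries, river_map, out_dir,
                               dialect = cwt_dialect(),
                               scope = c("hatchery", "river")) {
  scope <- match.arg(scope)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rel <- read_releases(releases, dialect)
  rec <- read_recoveries(recoveries, dialect)
  rivers <- read_river_map(river_map, dialect)
  cls <- classify_recoveries(rec, rel, rivers)
  label_counts <- as.data.frame(table(label = cls$label), stringsAsFactors = FALSE)
  excl <- cls$exclusion_reason[!is.na(cls$exclusion_reason)]
  for (i in seq_len(nrow(label_counts)))
    message(sprintf("label %s: %d recoveries", label_counts$label[i],
                    label_counts$Freq[i]))
  if (length(excl) > 0)
    for (r in names(table(excl)))
      message(sprintf("  excluded (%s): %d", r, table(excl)[[r]]))
  exp <- expand_recoveries(cls)
  rates <- rate_table(exp, rivers, scope = scope)
  smry <- if (nrow(rates) > 0) summarize_rates(rates) else rates
  write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
  write.csv(smry, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(label_counts, file.path(out_dir, "label_counts.csv"), row.names = FALSE)
  write_manifest(out_dir, "rates",
                 inputs = c(releases, recoveries, river_map),
                 settings = list(scope = scope))
  invisible(list(classified = cls, rates = rates, summary = smry))
}

#' Fit one or more model structures and write coefficient tables
#'
#' Builds the design for each specification, fits the joint
#' donor/recipient ZOIB model, and writes a coefficient table
#' (`coefficients_<name>.csv`, in the published-table layout) and an R-hat
#' report per model. With more than one specification, a LOO ranking
#' (`loo_ranking.csv`) is written - but only if every fit converged at the
#' R-hat < 1.01 threshold; otherwise ranking is refused with a warning.
#'
#' @param rates rate data.frame (or path to `rates.csv`).
#' @param covariates covariate data.frame (or path).
#' @param specs named list of [zoib_spec()] objects.
#' @param out_dir output directory.
#' @param chains,iterations,warmup,seed MCMC settings, see [fit_zoib()].
#' @return invisibly, a list with `fits` (named), `ranking` (or NULL).
#' @export
run_fit_pipeline <- function(rates, covariates, specs, out_dir,
                             chains = 6, iterations = 4000,
                             warmup = floor(iterations / 2), seed = 1) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  if (is.character(rates)) { paths <- c(paths, rates); rates <- read.csv(rates) }
  if (is.character(covariates)) {
    paths <- c(paths, covariates); covariates <- read_covariates(covariates)
  }
  if (inherits(specs, "zoib_spec")) specs <- list(model = specs)
  nm <- names(specs) %||% paste0("model", seq_along(specs))
  fits <- list()
  for (i in seq_along(specs)) {
    design <- build_design(rates, covariates, specs[[i]])
    dat <- zoib_data(rates, design)
    fit <- fit_zoib(dat, specs[[i]], chains = chains, iterations = iterations,
                    warmup = warmup, seed = seed + i - 1L)
    write.csv(coef_table(fit),
              file.path(out_dir, sprintf("coefficients_%s.csv", nm[i])),
              row.names = FALSE)
    write.csv(data.frame(parameter = names(fit$rhat), rhat = unname(fit$rhat)),
              file.path(out_dir, sprintf("rhat_%s.csv", nm[i])),
              row.names = FALSE)
    if (!fit$converged)
      warning(sprintf("model '%s' did not reach R-hat < 1.01 (max %.3f)",
                      nm[i], max(fit$rhat, na.rm = TRUE)))
    fits[[nm[i]]] <- fit
  }
  ranking <- NULL
  if (length(fits) > 1) {
    if (all(vapply(fits, `[[`, logical(1), "converged"))) {
      ranking <- loo_compare(fits)
      write.csv(ranking, file.path(out_dir, "loo_ranking.csv"), row.names = FALSE)
    } else {
      warning("refusing to rank models: not all fits converged")
    }
  }
  write_manifest(out_dir, "fit", inputs = paths,
                 settings = list(models = nm, chains = chains,
                                 iterations = iterations, warmup = warmup,
                                 seed = seed))
  invisible(list(fits = fits, ranking = ranking))
}

#' Closed-loop simulation and parameter-recovery report
#'
#' Simulates rates from known true parameters, refits the model, and
#' writes a per-parameter recovery report (truth, posterior median, 95%
#' interval, coverage indicator, bias) to `recovery.csv`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param chains,iterations,warmup MCMC settings for the refit.
#' @return invisibly, a list with `sim`, `fit`, `report`.
#' @export
run_recovery_study <- function(config, out_dir, chains = 3,
                               iterations = 1500, warmup = 750) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_rates(config)
  fit <- fit_zoib(sim$data, config$spec, chains = chains,
                  iterations = iterations, warmup = warmup,
                  seed = config$seed, compute_log_lik = FALSE)
  report <- recovery_report(fit, sim$params)
  write.csv(report, file.path(out_dir, "recovery.csv"), row.names = FALSE)
  write_manifest(out_dir, "recover",
                 settings = list(n_populations = config$n_populations,
                                 n_years = config$n_years,
                                 covariates = config$spec$covariates,
                                 chains = chains, iterations = iterations,
                                 warmup = warmup, seed = config$seed))
  invisible(list(sim = sim, fit = fit, report = report))
}

#' Compare fixed-effect posteriors to known truth
#'
#' @param fit a `zoib_fit`.
#' @param truth the `zoib_params` the data were simulated from.
#' @return data.frame: one row per fixed effect with the true value,
#'   posterior median, 95% interval, interval coverage of the truth, and
#'   bias (median minus truth).
#' @export
recovery_report <- function(fit, truth) {
  ct <- coef_table(fit)
  ct <- ct[ct$submodel %in% c("mu", "p"), ]
  covs <- fit$spec$covariates
  tr <- function(sub, resp, par) {
    r <- match(resp, c("donor", "recipient"))
    if (par == "intercept") {
      if (sub == "mu") truth$beta0[r] else truth$gamma0[r]
    } else {
      c. <- match(par, covs)
      if (sub == "mu") truth$beta1[r, c.] else truth$gamma1[r, c.]
    }
  }
  ct$truth <- mapply(tr, ct$submodel, ct$response, ct$parameter)
  ct$covered <- ct$q2.5 <= ct$truth & ct$truth <= ct$q97.5
  ct$bias <- ct$median - ct$truth
  ct
}
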