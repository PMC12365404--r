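# Synthetic data with known ground truth, at every level of the pipeline:
# covariate tables and donor/recipient rates drawn from the generative ZOIB
# model, and raw release/recovery files whose classification and expansion
# reproduce chosen rates.

#' Configuration of the rate simulator
#'
#' Defaults mirror the study conditions: 19 hatchery populations observed
#' over 23 return years, the two responses (donor, recipient) generated
#' jointly, covariates whose marginal means and spreads echo the packaged
#' river table, and true coefficients anchored at the published posterior
#' medians (see [default_true_params()]).
#'
#' @param n_populations,n_years problem dimensions.
#' @param spec a [zoib_spec()]; defaults to the model-1 covariate set.
#' @param params optional [zoib_params()] of true values; defaults to
#'   [default_true_params()]. Random-effect deviations are redrawn from
#'   their scales unless `draw_random_effects = FALSE`.
#' @param draw_random_effects draw population deviations from the scale
#'   hyperparameters (TRUE) or use those stored in `params` (FALSE).
#' @param seed mandatory RNG seed; the same seed gives bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 19, n_years = 23,
                       spec = zoib_spec(model_covariates(1)),
                       params = NULL, draw_random_effects = TRUE, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_populations >= 1, n_years >= 1, inherits(spec, "zoib_spec"))
  structure(list(n_populations = n_populations, n_years = n_years,
                 spec = spec, params = params,
                 draw_random_effects = isTRUE(draw_random_effects),
                 seed = as.integer(seed)), class = "sim_config")
}

#' True parameter values anchored at the published coefficient scale
#'
#' Fixed-effect slopes are set, per covariate and response, to the
#' posterior medians of the best-supported model structure (escapement
#' -0.40/-0.43 on the mean sub-model, and so on); covariates without a
#' published value default to zero. Intercepts, dispersion and
#' random-effect scales are chosen to reproduce realistic study-scale
#' data: a baseline conditional stray rate of a few percent, roughly forty
#' percent structural-zero years, and population spreads of under one
#' logit. See the methods vignette for the rationale of each value.
#'
#' @param spec a [zoib_spec()].
#' @param n_populations number of populations.
#' @return a [zoib_params()] with zero random-effect deviations (drawn
#'   later by the simulator).
#' @export
default_true_params <- function(spec, n_populations = 19) {
  mu_slopes <- list(
    donor = c(area = -0.41, isolation = -0.11, distance = 0.12, flow = 0.15,
              escapement = -0.40, diff_temp = -0.08, confluence_temp = 0.15,
              local_temp = 0.19),
    recipient = c(area = -0.25, isolation = -0.02, distance = -0.05, flow = 0.40,
                  escapement = -0.43, diff_temp = -0.04, confluence_temp = 0.06,
                  local_temp = 0.16))
  p_slopes <- list(
    donor = c(area = 0.58, isolation = -0.28, distance = -0.64, flow = -1.44,
              escapement = -0.37, diff_temp = -0.25, confluence_temp = -0.89,
              local_temp = -0.71),
    recipient = c(area = -0.44, isolation = -0.30, distance = 0.88, flow = -2.57,
                  escapement = -1.23, diff_temp = 1.14, confluence_temp = -1.32,
                  local_temp = -1.77))
  covs <- spec$covariates
  P <- length(covs)
  pick <- function(tab) {
    m <- rbind(tab$donor[covs], tab$recipient[covs])
    m[is.na(m)] <- 0
    unname(m)
  }
  Pa <- length(spec$random_slopes)
  zoib_params(
    covariates = covs, random_slopes = spec$random_slopes,
    n_populations = n_populations,
    beta0 = c(-3.2, -3.5),
    beta1 = if (P > 0) pick(mu_slopes) else NULL,
    gamma0 = c(-0.4, -0.4),
    gamma1 = if (P > 0) pick(p_slopes) else NULL,
    log_phi = c(log(8), log(8)),
    sigma_b0 = c(0.8, 0.8),
    sigma_b1 = if (Pa > 0) matrix(0.3, 2, Pa) else NULL,
    sigma_u0 = c(1, 1),
    sigma_u1 = if (Pa > 0) matrix(0.3, 2, Pa) else NULL,
    sigma_eps = if (spec$include_eps) c(0.3, 0.3) else NULL)
}

# Covariate table whose marginals echo the packaged river table: static
# covariates lognormal across populations, annual covariates drawn yearly
# around population means. Independent draws: no spatial correlation.
simulate_covariate_table <- function(G, n_years) {
  t1 <- chinook_rivers()
  ln <- function(col, n) rlnorm(n, mean(log(col)), sd(log(col)))
  pops <- sprintf("hatchery_%02d", seq_len(G))
  area <- ln(t1$area_km2, G)
  isolation <- pmax(ln(t1$isolation_km, G), 1)
  distance <- ln(t1$distance_km, G)
  flow_mu <- ln(t1$flow_mean, G)
  esc_mu <- ln(t1$escapement_mean, G)
  lt_mu <- rnorm(G, mean(t1$local_temp_mean), sd(t1$local_temp_mean))
  ct_mu <- rnorm(G, mean(t1$confluence_temp_mean), sd(t1$confluence_temp_mean))
  lt_sd <- mean(t1$local_temp_sd)
  ct_sd <- mean(t1$confluence_temp_sd)
  out <- do.call(rbind, lapply(seq_len(G), function(g) {
    data.frame(
      hatchery = pops[g], year = seq_len(n_years),
      area = area[g], isolation = isolation[g], distance = distance[g],
      flow = pmax(flow_mu[g] * exp(rnorm(n_years, 0, 0.25)), 0.1),
      local_temp = rnorm(n_years, lt_mu[g], lt_sd),
      confluence_temp = rnorm(n_years, ct_mu[g], ct_sd),
      escapement = pmax(esc_mu[g] * exp(rnorm(n_years, 0, 0.5)), 1),
      stringsAsFactors = FALSE)
  }))
  out$diff_temp <- diff_temperature(out$local_temp, out$confluence_temp)
  rownames(out) <- NULL
  out
}

#' Simulate donor/recipient rates from the generative ZOIB model
#'
#' Draws covariates, population random effects and then, for every
#' population-year and response, a zero indicator with probability `p` and
#' otherwise a Beta(mu * phi, (1 - mu) * phi) rate through the model's link
#' functions. Rates of exactly one cannot occur when one-inflation is
#' disabled (positive draws are kept strictly inside the unit interval).
#'
#' @param config a [sim_config()].
#' @return list: `rates` (hatchery/year/donor_rate/recipient_rate),
#'   `covariates` (the drawn table), `design` (standardized), `data` (a
#'   ready [zoib_data()]), `params` (truth, with the drawn random-effect
#'   deviations), `config`.
#' @export
simulate_rates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_populations; Yr <- config$n_years
  spec <- config$spec
  covtab <- simulate_covariate_table(G, Yr)
  grid <- covtab[c("hatchery", "year")]
  design <- build_design(grid, covtab, spec)
  params <- config$params %||% default_true_params(spec, G)
  if (params$n_populations != G)
    stop("params$n_populations does not match the configuration", call. = FALSE)
  Pa <- length(params$random_slopes)
  if (config$draw_random_effects) {
    params$b0 <- matrix(rnorm(2 * G, 0, rep(params$sigma_b0, G)), 2, G)
    params$u0 <- matrix(rnorm(2 * G, 0, rep(params$sigma_u0, G)), 2, G)
    if (Pa > 0) {
      params$b1 <- array(0, c(2, G, Pa))
      params$u1 <- array(0, c(2, G, Pa))
      for (r in 1:2) for (a in seq_len(Pa)) {
        params$b1[r, , a] <- rnorm(G, 0, params$sigma_b1[r, a])
        params$u1[r, , a] <- rnorm(G, 0, params$sigma_u1[r, a])
      }
    }
  }
  n <- nrow(grid)
  g_row <- match(grid$hatchery, unique(grid$hatchery))
  rates <- matrix(NA_real_, n, 2)
  for (k in 1:2) {
    for (j in seq_len(n)) {
      eps <- if (spec$include_eps) rnorm(1, 0, params$sigma_eps[k]) else 0
      lp <- linked_predictors(design$X[j, ], params, k, g_row[j], eps = eps)
      if (rbinom(1, 1, lp$p) == 1) {
        rates[j, k] <- 0
      } else if (spec$include_one_inflation &&
                 rbinom(1, 1, plogis(params$delta0[k])) == 1) {
        rates[j, k] <- 1
      } else {
        sh <- beta_from_mean_dispersion(lp$mu, lp$phi)
        rates[j, k] <- min(max(rbeta(1, sh$alpha1, sh$alpha2), 1e-12), 1 - 1e-12)
      }
    }
  }
  rates_df <- data.frame(grid, donor_rate = rates[, 1],
                         recipient_rate = rates[, 2], stringsAsFactors = FALSE)
  list(rates = rates_df, covariates = covtab, design = design,
       data = zoib_data(rates_df, design), params = params, config = config)
}

#' Generate raw release/recovery files realizing a target rate table
#'
#' Builds a self-consistent set of release records, recovery records and a
#' river map which, pushed through classification, expansion and rate
#' estimation, reproduce the target donor and recipient rates. Each focal
#' hatchery-year gets one tagged release group recovered partly at home and
#' partly in an external sink river (the donor strays), plus strays from an
#' external non-focal programme recovered at the hatchery (the recipient
#' strays). Integer fish counts are obtained by nearest-integer
#' (largest-remainder) rounding, so the realized rates - returned alongside
#' the files - equal the targets whenever `target * n` is integral.
#' Expansion is uniform within a hatchery-year, so the realized rates are
#' invariant to the sampling fraction and the tagged fraction.
#'
#' @param rates data.frame with `hatchery`, `year`, `donor_rate`,
#'   `recipient_rate` in \[0, 1); NA rates skip the cell.
#' @param recoveries_per_cell home-or-stray fish per hatchery-year on the
#'   donor side.
#' @param sampling_fraction sampling fraction written on every recovery.
#' @param tagged_fraction tagged share of each release group in (0, 1].
#' @param ambiguous_per_cell extra fish per cell recovered in the river
#'   the group was reared (but not released) in; they must not move either
#'   rate.
#' @param n_experimental extra fish per cell from an experimental-flagged
#'   release; they must be excluded outright.
#' @param dir optional directory; if given, `releases.csv`,
#'   `recoveries.csv` and `river_map.csv` are written there.
#' @return list: `releases`, `recoveries`, `river_map` (data.frames),
#'   `rivers` (a [river_map()] object), `realized` (rate table with the
#'   integer-exact rates), and `paths` when `dir` is given.
#' @export
simulate_recovery_files <- function(rates, recoveries_per_cell = 200,
                                    sampling_fraction = 1, tagged_fraction = 1,
                                    ambiguous_per_cell = 0, n_experimental = 0,
                                    dir = NULL) {
  stopifnot(all(is.na(rates$donor_rate) | (rates$donor_rate >= 0 & rates$donor_rate < 1)),
            all(is.na(rates$recipient_rate) | (rates$recipient_rate >= 0 & rates$recipient_rate < 1)),
            tagged_fraction > 0, tagged_fraction <= 1)
  pops <- unique(rates$hatchery)
  tagged <- 100L
  untagged <- as.integer(floor(tagged * (1 / tagged_fraction - 1) + 0.5))
  rel <- list(); rec <- list(); realized <- rates
  realized$donor_rate <- NA_real_; realized$recipient_rate <- NA_real_
  add_rec <- function(code, site, year, n) {
    if (n <= 0) return(NULL)
    data.frame(tag_code = code, recovery_site = site, return_year = year,
               sampling_fraction = sampling_fraction,
               recovery_context = "hatchery", stringsAsFactors = FALSE)[rep(1, n), ]
  }
  for (i in seq_len(nrow(rates))) {
    h <- rates$hatchery[i]; yr <- rates$year[i]
    dr <- rates$donor_rate[i]; rr <- rates$recipient_rate[i]
    if (is.na(dr) && is.na(rr)) next
    river <- paste(h, "river")
    code <- sprintf("F-%s-%d", h, yr)
    rearing <- if (ambiguous_per_cell > 0) paste(h, "rearing river") else ""
    rel[[length(rel) + 1]] <- data.frame(
      tag_code = code, release_river = river, release_site = h,
      rearing_rivers = rearing, brood_year = yr - 4L,
      tagged_count = tagged, untagged_count = untagged,
      experimental = FALSE, stringsAsFactors = FALSE)
    n <- recoveries_per_cell
    n_stray <- if (is.na(dr)) 0L else as.integer(floor(dr * n + 0.5))
    n_home <- n - n_stray
    rec[[length(rec) + 1]] <- add_rec(code, h, yr, n_home)
    rec[[length(rec) + 1]] <- add_rec(code, "stray sink", yr, n_stray)
    if (!is.na(dr)) realized$donor_rate[i] <- n_stray / n
    if (!is.na(rr)) {
      m <- as.integer(floor(n_home * rr / (1 - rr) + 0.5))
      if (m > 0) {
        xcode <- sprintf("X-%s-%d", h, yr)
        rel[[length(rel) + 1]] <- data.frame(
          tag_code = xcode, release_river = "outside river",
          release_site = "outside hatchery", rearing_rivers = "",
          brood_year = yr - 4L, tagged_count = tagged,
          untagged_count = untagged, experimental = FALSE,
          stringsAsFactors = FALSE)
        rec[[length(rec) + 1]] <- add_rec(xcode, h, yr, m)
      }
      realized$recipient_rate[i] <- m / (n_home + m)
    }
    if (ambiguous_per_cell > 0)
      rec[[length(rec) + 1]] <- add_rec(code, paste(h, "rearing site"), yr,
                                        ambiguous_per_cell)
    if (n_experimental > 0) {
      ecode <- sprintf("E-%s-%d", h, yr)
      rel[[length(rel) + 1]] <- data.frame(
        tag_code = ecode, release_river = river, release_site = h,
        rearing_rivers = "", brood_year = yr - 4L, tagged_count = tagged,
        untagged_count = untagged, experimental = TRUE, stringsAsFactors = FALSE)
      rec[[length(rec) + 1]] <- add_rec(ecode, h, yr, n_experimental)
    }
  }
  releases <- do.call(rbind, rel); rownames(releases) <- NULL
  recoveries <- do.call(rbind, rec); rownames(recoveries) <- NULL
  map <- rbind(
    data.frame(site = pops, river = paste(pops, "river"), focal = TRUE,
               stringsAsFactors = FALSE),
    data.frame(site = "stray sink", river = "sink river", focal = FALSE,
               stringsAsFactors = FALSE),
    data.frame(site = "outside hatchery", river = "outside river",
               focal = FALSE, stringsAsFactors = FALSE),
    if (ambiguous_per_cell > 0)
      data.frame(site = paste(pops, "rearing site"),
                 river = paste(pops, "rearing river"), focal = FALSE,
                 stringsAsFactors = FALSE))
  out <- list(releases = releases, recoveries = recoveries, river_map = map,
              rivers = river_map(map), realized = realized)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("releases.csv", "recoveries.csv", "river_map.csv"))
    write.csv(releases, paths[1], row.names = FALSE)
    write.csv(recoveries, paths[2], row.names = FALSE)
    write.csv(map, paths[3], row.names = FALSE)
    out$paths <- setNames(paths, c("releases", "recoveries", "river_map"))
  }
  out
}
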