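# Shared fixtures: all data are built in code at test time.

toy_releases <- function() {
  data.frame(
    tag_code = c("A1", "A2", "B1", "C1"),
    release_river = c("Kalama", "Wind", "Wind", "Kalama"),
    release_site = c("Fallert Creek Hatchery", "Carson NFH", "Carson NFH",
                     "Kalama Falls Hatchery"),
    rearing_rivers = c("", "Klickitat", "", ""),
    brood_year = c(2000L, 2000L, 2001L, 2001L),
    tagged_count = c(100, 200, 50, 80),
    untagged_count = c(300, 0, 50, 20),
    experimental = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

toy_map <- function() {
  river_map(data.frame(
    site = c("Fallert Creek Hatchery", "Kalama Falls Hatchery", "Carson NFH",
             "Klickitat site", "Little White Salmon NFH"),
    river = c("Kalama", "Kalama", "Wind", "Klickitat", "Little White Salmon"),
    focal = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE))
}

toy_recovery <- function(tag, site, year = 2003L, sf = 1,
                         context = "hatchery") {
  data.frame(tag_code = tag, recovery_site = site, return_year = year,
             sampling_fraction = sf, recovery_context = context,
             stringsAsFactors = FALSE)
}

# Memoised MCMC fits shared across test files (each is built once per run).
.fit_cache <- new.env(parent = emptyenv())
cached <- function(name, maker) {
  if (!exists(name, envir = .fit_cache)) assign(name, maker(), envir = .fit_cache)
  get(name, envir = .fit_cache)
}

one_cov_params <- function(slope, G = 8) {
  zoib_params(
    covariates = "confluence_temp", random_slopes = "confluence_temp",
    n_populations = G,
    beta0 = c(-2, -2), beta1 = matrix(slope, 2, 1),
    gamma0 = c(-1.5, -1.5), gamma1 = matrix(0, 2, 1),
    log_phi = c(log(15), log(15)),
    sigma_b0 = c(0.3, 0.3), sigma_b1 = matrix(0.15, 2, 1),
    sigma_u0 = c(0.5, 0.5), sigma_u1 = matrix(0.15, 2, 1))
}

slope_sim <- function() cached("slope_sim", function() {
  spec <- zoib_spec("confluence_temp")
  simulate_rates(sim_config(n_populations = 8, n_years = 8, spec = spec,
                            params = one_cov_params(1.2), seed = 42))
})

slope_fit <- function() cached("slope_fit", function() {
  sim <- slope_sim()
  fit_zoib(sim$data, sim$config$spec, chains = 2, iterations = 1000,
           warmup = 500, seed = 42, compute_log_lik = FALSE)
})

flat_fit <- function() cached("flat_fit", function() {
  spec <- zoib_spec("confluence_temp")
  sim <- simulate_rates(sim_config(n_populations = 8, n_years = 8, spec = spec,
                                   params = one_cov_params(0), seed = 43))
  fit_zoib(sim$data, spec, chains = 2, iterations = 1000, warmup = 500,
           seed = 43, compute_log_lik = FALSE)
})

# Independent brute-force ZOIB log-density evaluator: loops and direct
# formulas only, no calls into the package's density code.
oracle_loglik <- function(data, params) {
  total <- 0
  pw <- numeric(length(data$y))
  P <- length(params$covariates)
  ann <- match(params$random_slopes, params$covariates)
  for (j in seq_along(data$y)) {
    k <- data$k[j]; g <- data$g[j]; x <- data$X[j, ]
    eta <- params$beta0[k] + params$b0[k, g]
    zeta <- params$gamma0[k] + params$u0[k, g]
    if (P > 0) {
      for (c. in seq_len(P)) {
        eta <- eta + params$beta1[k, c.] * x[c.]
        zeta <- zeta + params$gamma1[k, c.] * x[c.]
      }
    }
    for (a in seq_along(ann)) {
      eta <- eta + params$b1[k, g, a] * x[ann[a]]
      zeta <- zeta + params$u1[k, g, a] * x[ann[a]]
    }
    if (!is.null(params$eps)) eta <- eta + params$eps[j]
    mu <- 1 / (1 + exp(-eta))
    pz <- 1 / (1 + exp(-zeta))
    phi <- exp(params$log_phi[k])
    y <- data$y[j]
    pw[j] <- if (y == 0) log(pz)
    else log(1 - pz) + dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
  }
  list(total = sum(pw), pointwise = pw)
}
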