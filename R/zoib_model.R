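#' Specify a zero/one-inflated beta model structure
#'
#' Names the covariates of the design matrix, which of them carry
#' population-level random slopes (only covariates that vary annually
#' within a population are eligible; static river properties are fixed
#' effects), and the optional model components.
#'
#' @param covariates character vector of covariate names (see
#'   [model_covariates()]); empty gives an intercept-only model.
#' @param random_slopes subset of `covariates` receiving random slopes;
#'   defaults to the annual covariates among them.
#' @param include_eps include an observation-level normal residual on the
#'   logit-mean scale. Off by default: it is weakly identified jointly with
#'   the beta dispersion.
#' @param include_one_inflation model a point mass at one. Off by default:
#'   observed rates of exactly one do not occur.
#' @param phi_by_population let the log-dispersion vary by population
#'   around the response-level intercept (kept available for model
#'   comparison; tends to converge poorly).
#' @return list of class `zoib_spec`.
#' @export
zoib_spec <- function(covariates = character(0),
                      random_slopes = NULL,
                      include_eps = FALSE,
                      include_one_inflation = FALSE,
                      phi_by_population = FALSE) {
  covariates <- as.character(covariates)
  if (!all(covariates %in% .covariate_names))
    stop(sprintf("unknown covariate(s): %s",
                 paste(setdiff(covariates, .covariate_names), collapse = ", ")),
         call. = FALSE)
  if (is.null(random_slopes))
    random_slopes <- intersect(covariates, .annual_covariates)
  random_slopes <- as.character(random_slopes)
  if (!all(random_slopes %in% covariates))
    stop("random_slopes must be a subset of covariates", call. = FALSE)
  if (!all(random_slopes %in% .annual_covariates))
    stop("random slopes are only allowed on annual covariates", call. = FALSE)
  structure(list(covariates = covariates, random_slopes = random_slopes,
                 include_eps = isTRUE(include_eps),
                 include_one_inflation = isTRUE(include_one_inflation),
                 phi_by_population = isTRUE(phi_by_population)),
            class = "zoib_spec")
}

#' Full parameter set of the zero/one-inflated beta hierarchical model
#'
#' Containers for every estimated quantity: fixed effects of the mean
#' (`beta0`, `beta1`) and zero (`gamma0`, `gamma1`) sub-models on the logit
#' scale, the log-dispersion intercept per response, population random
#' intercepts and slopes of both sub-models with their scales, and the
#' optional observation residual. Index 1 is the donor response, 2 the
#' recipient response.
#'
#' @param covariates covariate names (columns of the design matrix).
#' @param random_slopes covariates with population random slopes.
#' @param n_populations number of populations G.
#' @param beta0,gamma0 length-2 intercepts (donor, recipient).
#' @param beta1,gamma1 2 x P matrices of fixed slopes.
#' @param log_phi length-2 log-dispersion intercepts.
#' @param sigma_b0,sigma_u0 length-2 random-intercept scales (> 0).
#' @param sigma_b1,sigma_u1 2 x Pa matrices of random-slope scales (> 0).
#' @param b0,u0 2 x G random intercept deviations.
#' @param b1,u1 2 x G x Pa random slope deviations.
#' @param sigma_eps optional length-2 residual scales.
#' @param eps optional per-observation residual vector.
#' @param include_one_inflation logical; if TRUE `delta0` gives the
#'   logit-scale intercept of the one-inflation probability.
#' @param delta0 length-2 one-inflation intercepts (ignored otherwise).
#' @return list of class `zoib_params`.
#' @export
zoib_params <- function(covariates = character(0),
                        random_slopes = intersect(covariates, .annual_covariates),
                        n_populations = 1,
                        beta0 = c(0, 0), beta1 = NULL,
                        gamma0 = c(0, 0), gamma1 = NULL,
                        log_phi = c(0, 0),
                        sigma_b0 = c(1, 1), sigma_b1 = NULL,
                        sigma_u0 = c(1, 1), sigma_u1 = NULL,
                        b0 = NULL, b1 = NULL, u0 = NULL, u1 = NULL,
                        sigma_eps = NULL, eps = NULL,
                        include_one_inflation = FALSE, delta0 = c(-20, -20)) {
  P <- length(covariates)
  Pa <- length(random_slopes)
  G <- n_populations
  if (!all(random_slopes %in% covariates))
    stop("random_slopes must be a subset of covariates", call. = FALSE)
  zmat <- function(x, nr, nc) {
    if (is.null(x)) matrix(0, nr, nc)
    else {x <- as.matrix(x); stopifnot(all(dim(x) == c(nr, nc))); x}
  }
  zarr <- function(x, d) {
    if (is.null(x)) array(0, d)
    else {stopifnot(all(dim(x) == d)); x}
  }
  p <- list(covariates = covariates, random_slopes = random_slopes,
            random_slopes_idx = match(random_slopes, covariates),
            n_populations = G,
            beta0 = beta0, beta1 = zmat(beta1, 2, P),
            gamma0 = gamma0, gamma1 = zmat(gamma1, 2, P),
            log_phi = log_phi,
            sigma_b0 = sigma_b0,
            sigma_b1 = if (is.null(sigma_b1)) matrix(1, 2, Pa) else zmat(sigma_b1, 2, Pa),
            sigma_u0 = sigma_u0,
            sigma_u1 = if (is.null(sigma_u1)) matrix(1, 2, Pa) else zmat(sigma_u1, 2, Pa),
            b0 = zmat(b0, 2, G), b1 = zarr(b1, c(2, G, Pa)),
            u0 = zmat(u0, 2, G), u1 = zarr(u1, c(2, G, Pa)),
            sigma_eps = sigma_eps, eps = eps,
            include_one_inflation = isTRUE(include_one_inflation),
            delta0 = delta0)
  stopifnot(length(p$beta0) == 2, length(p$gamma0) == 2, length(p$log_phi) == 2)
  if (any(c(p$sigma_b0, p$sigma_b1, p$sigma_u0, p$sigma_u1, p$sigma_eps) <= 0))
    stop("random-effect and residual scales must be positive", call. = FALSE)
  structure(p, class = "zoib_params")
}

#' Stack a rate table and design matrix into model-ready data
#'
#' The donor and recipient responses are fitted jointly: each non-missing
#' rate becomes one observation, indexed by response `k` (1 donor,
#' 2 recipient) and population `g`. Missing rate-years are dropped
#' row-wise per response.
#'
#' @param rates data.frame with `hatchery`, `year`, `donor_rate`,
#'   `recipient_rate` (e.g. from [rate_table()] or [simulate_rates()]).
#' @param design a `zoib_design` from [build_design()] aligned to `rates`.
#' @return list of class `zoib_data`: `y`, `k`, `g`, `X`, plus bookkeeping
#'   (`hatchery`, `year`, `populations`, covariate names, centres/scales).
#' @export
zoib_data <- function(rates, design) {
  stopifnot(inherits(design, "zoib_design"), nrow(design$X) == nrow(rates))
  populations <- unique(rates$hatchery)
  g_row <- match(rates$hatchery, populations)
  parts <- lapply(1:2, function(k) {
    rate <- if (k == 1) rates$donor_rate else rates$recipient_rate
    keep <- !is.na(rate)
    list(y = rate[keep], k = rep(k, sum(keep)), g = g_row[keep],
         X = design$X[keep, , drop = FALSE],
         hatchery = rates$hatchery[keep], year = rates$year[keep])
  })
  y <- c(parts[[1]]$y, parts[[2]]$y)
  if (any(y < 0 | y >= 1))
    stop("rates must lie in [0, 1); exactly-one rates should have been flagged upstream",
         call. = FALSE)
  structure(list(
    y = y,
    k = c(parts[[1]]$k, parts[[2]]$k),
    g = c(parts[[1]]$g, parts[[2]]$g),
    X = rbind(parts[[1]]$X, parts[[2]]$X),
    hatchery = c(parts[[1]]$hatchery, parts[[2]]$hatchery),
    year = c(parts[[1]]$year, parts[[2]]$year),
    populations = populations,
    covariates = design$covariates,
    annual = design$annual,
    centers = design$centers, scales = design$scales),
    class = "zoib_data")
}
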