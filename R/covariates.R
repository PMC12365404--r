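#' Centre and scale a covariate
#'
#' Subtracts the mean and divides by the standard deviation (denominator
#' n-1), keeping the centre and scale for back-transformation of fitted
#' effects and prediction grids.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return list with `z` (standardized vector), `center`, `scale`.
#' @export
standardize <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2)
    stop("cannot standardize: fewer than 2 distinct values", call. = FALSE)
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  list(z = (values - m) / s, center = m, scale = s)
}

#' Local-minus-confluence temperature difference
#'
#' The thermal contrast a returning adult experiences between the river
#' junction it must pass and the natal site itself (degrees C). Positive
#' values mean the natal reach is warmer than the confluence en route.
#'
#' @param local,confluence August water temperatures (degrees C).
#' @return `local - confluence`, NA where either is missing.
#' @export
diff_temperature <- function(local, confluence) {
  local - confluence
}

# Covariate vocabulary. "Annual" covariates vary by year within a hatchery
# and are eligible for population-level random slopes; static ones are
# properties of the river network and enter as fixed effects only.
.covariate_names <- c("area", "isolation", "distance", "flow",
                      "escapement", "diff_temp", "confluence_temp", "local_temp")
.annual_covariates <- c("flow", "escapement", "diff_temp",
                        "confluence_temp", "local_temp")

#' Covariate sets of the two best-supported model structures
#'
#' Both share watershed area, isolation (distance to the nearest potential
#' stray source), migration distance from the river mouth, August flow,
#' escapement and the local-minus-confluence temperature difference; model 1
#' adds the confluence temperature itself, model 2 the local temperature.
#'
#' @param model 1 or 2.
#' @return character vector of covariate names.
#' @export
model_covariates <- function(model = 1) {
  base <- c("area", "isolation", "distance", "flow", "escapement", "diff_temp")
  if (model == 1) c(base, "confluence_temp")
  else if (model == 2) c(base, "local_temp")
  else stop("model must be 1 or 2", call. = FALSE)
}

#' Read the per-hatchery-year habitat covariate table
#'
#' @param path CSV with columns `hatchery`, `year`, `area`, `isolation`,
#'   `distance`, `flow`, `local_temp`, `confluence_temp`, `escapement`.
#'   `diff_temp` is derived if absent.
#' @param dialect a [cwt_dialect()] (separator only).
#' @return data.frame of covariates, one row per hatchery-year.
#' @export
read_covariates <- function(path, dialect = cwt_dialect()) {
  need <- c("hatchery", "year", "area", "isolation", "distance", "flow",
            "local_temp", "confluence_temp", "escapement")
  df <- read_delim_checked(path, dialect, need, "covariates")
  if (!"diff_temp" %in% names(df))
    df$diff_temp <- diff_temperature(df$local_temp, df$confluence_temp)
  if (any(!is.na(df$area) & df$area <= 0))
    stop("area must be positive", call. = FALSE)
  if (any(!is.na(df$isolation) & df$isolation < 1))
    stop("isolation must be >= 1 km (1 km denotes intersecting rivers)", call. = FALSE)
  df
}

#' Build the standardized design matrix aligned to the rate table
#'
#' Looks up each rate row's covariates, derives the temperature difference,
#' and standardizes every column jointly over all included hatchery-year
#' rows (a single centring, not within-hatchery). Stores centres and scales
#' for back-transformation and flags which columns vary annually (eligible
#' for random slopes).
#'
#' @param rates data.frame from [rate_table()] (or any frame with
#'   `hatchery` and `year` columns).
#' @param covariates data.frame from [read_covariates()] or equivalent.
#' @param spec a [zoib_spec()] naming the covariates, or a character vector
#'   of covariate names; empty gives an intercept-only design.
#' @return list of class `zoib_design`: `X` (n x P standardized matrix),
#'   `centers`, `scales`, `annual` (logical per column), `covariates`.
#' @export
build_design <- function(rates, covariates, spec = zoib_spec()) {
  covs <- if (inherits(spec, "zoib_spec")) spec$covariates else as.character(spec)
  if (!all(covs %in% .covariate_names))
    stop(sprintf("unknown covariate(s): %s",
                 paste(setdiff(covs, .covariate_names), collapse = ", ")), call. = FALSE)
  n <- nrow(rates)
  if (length(covs) == 0) {
    return(structure(list(X = matrix(numeric(0), n, 0), centers = numeric(0),
                          scales = numeric(0), annual = logical(0),
                          covariates = character(0)), class = "zoib_design"))
  }
  if (!"diff_temp" %in% names(covariates))
    covariates$diff_temp <- diff_temperature(covariates$local_temp,
                                             covariates$confluence_temp)
  ck <- paste(canon_name(covariates$hatchery), covariates$year)
  rk <- paste(canon_name(rates$hatchery), rates$year)
  idx <- match(rk, ck)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("no covariate row for hatchery '%s', year %s",
                 rates$hatchery[bad], rates$year[bad]), call. = FALSE)
  }
  raw <- as.matrix(covariates[idx, covs, drop = FALSE])
  if (anyNA(raw)) {
    bad <- which(rowSums(is.na(raw)) > 0)[1]
    stop(sprintf("missing covariate value for hatchery '%s', year %s",
                 rates$hatchery[bad], rates$year[bad]), call. = FALSE)
  }
  std <- apply(raw, 2, standardize, simplify = FALSE)
  X <- vapply(std, `[[`, numeric(n), "z")
  if (n == 1) X <- matrix(X, 1)
  dimnames(X) <- list(NULL, covs)
  structure(list(X = X,
                 centers = vapply(std, `[[`, numeric(1), "center"),
                 scales = vapply(std, `[[`, numeric(1), "scale"),
                 annual = setNames(covs %in% .annual_covariates, covs),
                 covariates = covs),
            class = "zoib_design")
}
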