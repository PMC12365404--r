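#' Posterior predictive effect curves
#'
#' Pushes a grid of covariate values (on their original scales) through the
#' posterior draws and returns the median and a central credible band of
#' the predicted rate. For `population = "new"` the random intercept and
#' slopes of an unsampled population are drawn from their scale
#' hyperparameters at every posterior draw, so the band carries the full
#' between-population uncertainty; naming one of the fitted populations
#' uses its own posterior random effects instead, giving a narrower,
#' population-specific curve. Covariates absent from `newdata` are held at
#' their training means (standardized zero).
#'
#' @param fit a `zoib_fit`.
#' @param newdata data.frame whose columns are a subset of the fitted
#'   covariates, on the original (unstandardized) scales.
#' @param response `"donor"` or `"recipient"`.
#' @param population `"new"` for an unsampled population, or the name (or
#'   index) of a fitted population.
#' @param type `"mu"` (mean of the beta component, the conditional mean
#'   rate given straying occurs), `"p"` (probability of a zero year), or
#'   `"expected"` (the unconditional mean rate `(1 - p) * mu`).
#' @param prob width of the credible band (default 0.95).
#' @param seed optional seed for the new-population random-effect draws.
#' @return `newdata` with columns `median`, `lower`, `upper` appended.
#' @export
posterior_predict <- function(fit, newdata, response = "donor",
                              population = "new", type = c("mu", "p", "expected"),
                              prob = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "zoib_fit"))
  type <- match.arg(type)
  k <- response_index(response)
  covs <- fit$spec$covariates
  P <- length(covs)
  ann <- fit$spec$random_slopes
  ann_idx <- match(ann, covs)
  extra <- setdiff(names(newdata), covs)
  if (length(extra) > 0)
    stop(sprintf("newdata column(s) not among fitted covariates: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  ng <- nrow(newdata)
  Xg <- matrix(0, ng, P, dimnames = list(NULL, covs))
  for (cv in intersect(names(newdata), covs))
    Xg[, cv] <- (newdata[[cv]] - fit$data$centers[cv]) / fit$data$scales[cv]

  M <- fit$draws
  S <- nrow(M)
  new_pop <- identical(population, "new")
  if (!new_pop) {
    gi <- if (is.numeric(population)) as.integer(population)
    else match(population, fit$data$populations)
    if (is.na(gi) || gi < 1 || gi > length(fit$data$populations))
      stop(sprintf("unknown population: %s", format(population)), call. = FALSE)
  }
  if (new_pop && !is.null(seed)) set.seed(seed)

  need_mu <- type %in% c("mu", "expected")
  need_p <- type %in% c("p", "expected")
  pred_lin <- function(int0, slope, re0, re1sd_or_val) {
    eta <- matrix(M[, int0], S, ng)
    if (P > 0) eta <- eta + M[, sprintf("%s[%d,%d]", slope, k, seq_len(P)),
                              drop = FALSE] %*% t(Xg)
    eta + re0 + re1part(re1sd_or_val)
  }
  re1part <- function(mat) if (is.null(mat)) 0 else mat %*% t(Xg[, ann_idx, drop = FALSE])
  draw_re <- function(sd_cols) {
    sds <- M[, sd_cols, drop = FALSE]
    matrix(rnorm(length(sds), 0, as.vector(sds)), nrow = S)
  }
  out <- newdata
  comp <- function(int, slope, b0nm, b1nm, sb0nm, sb1nm) {
    if (new_pop) {
      re0 <- as.vector(draw_re(sprintf("%s[%d]", sb0nm, k)))
      re1 <- if (length(ann) > 0) draw_re(sprintf("%s[%d,%d]", sb1nm, k, seq_along(ann)))
      else NULL
    } else {
      re0 <- M[, sprintf("%s[%d,%d]", b0nm, k, gi)]
      re1 <- if (length(ann) > 0)
        M[, sprintf("%s[%d,%d,%d]", b1nm, k, gi, seq_along(ann)), drop = FALSE]
      else NULL
    }
    plogis(pred_lin(sprintf("%s[%d]", int, k), slope, re0, re1))
  }
  val <- NULL
  if (need_mu) val <- comp("beta0", "beta1", "b0", "b1", "sb0", "sb1")
  if (need_p) {
    pv <- comp("gamma0", "gamma1", "u0", "u1", "su0", "su1")
    val <- if (type == "p") pv else (1 - pv) * val
  }
  a <- (1 - prob) / 2
  qs <- apply(val, 2, quantile, probs = c(0.5, a, 1 - a), names = FALSE)
  out$median <- qs[1, ]
  out$lower <- qs[2, ]
  out$upper <- qs[3, ]
  out
}
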