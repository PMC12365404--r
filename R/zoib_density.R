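#' Beta shape parameters from a mean/dispersion parameterization
#'
#' The beta component is parameterized by its mean `mu` in (0,1) and a
#' dispersion (precision) `phi > 0`, with shapes `alpha1 = mu * phi` and
#' `alpha2 = (1 - mu) * phi`, so `alpha1 + alpha2 = phi` and the
#' conditional variance is `mu * (1 - mu) / (1 + phi)`.
#'
#' @param mu mean in (0,1); vectorized.
#' @param phi dispersion, > 0.
#' @return list with `alpha1`, `alpha2`.
#' @export
beta_from_mean_dispersion <- function(mu, phi) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly in (0, 1)", call. = FALSE)
  if (any(phi <= 0)) stop("phi must be positive", call. = FALSE)
  list(alpha1 = mu * phi, alpha2 = (1 - mu) * phi)
}

#' Log-density of the zero/one-inflated beta distribution
#'
#' A mixture with point mass `p` at zero, mass `(1 - p) * q` at one, and
#' the remaining mass `(1 - p) * (1 - q)` spread over (0,1) as a
#' Beta(alpha1, alpha2). With `q = 0` (the default; rates of exactly one do
#' not occur in these data) the one-inflation branch has density zero.
#'
#' @param y observation(s) in [0, 1].
#' @param p probability of a structural zero, in (0,1).
#' @param q conditional probability of a one given not zero, in [0,1).
#' @param alpha1,alpha2 beta shapes (see [beta_from_mean_dispersion()]).
#' @return log-density, vectorized over the longest argument.
#' @export
zoib_logpdf <- function(y, p, q = 0, alpha1, alpha2) {
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  n <- max(length(y), length(p), length(q), length(alpha1), length(alpha2))
  y <- rep_len(y, n); p <- rep_len(p, n); q <- rep_len(q, n)
  alpha1 <- rep_len(alpha1, n); alpha2 <- rep_len(alpha2, n)
  out <- numeric(n)
  at0 <- y == 0
  at1 <- y == 1
  mid <- !at0 & !at1
  out[at0] <- log(p[at0])
  out[at1] <- log1p(-p[at1]) + log(q[at1])
  out[mid] <- log1p(-p[mid]) + log1p(-q[mid]) +
    dbeta(y[mid], alpha1[mid], alpha2[mid], log = TRUE)
  out
}

#' Linear predictors through the model's link functions
#'
#' Maps one standardized design row through the mean, dispersion and
#' zero-inflation sub-models for response `k` and population `g`:
#' `logit(mu) = beta0_k + beta1_k x + b0_{k,g} + b1_{k,g} x_ann (+ eps)`,
#' `log(phi) = log_phi_k` (constant across populations), and
#' `logit(p) = gamma0_k + gamma1_k x + u0_{k,g} + u1_{k,g} x_ann`.
#'
#' @param x numeric vector: one standardized design row (length P).
#' @param params a [zoib_params()] object.
#' @param k response, `"donor"` or `"recipient"` (or index 1/2).
#' @param g population index.
#' @param eps observation-level residual on the logit-mean scale (default 0,
#'   i.e. marginal prediction).
#' @return list with `mu`, `phi`, `p`.
#' @export
linked_predictors <- function(x, params, k, g, eps = 0) {
  k <- response_index(k)
  P <- length(params$covariates)
  stopifnot(length(x) == P)
  ann <- params$random_slopes_idx
  eta <- params$beta0[k] + (if (P > 0) sum(params$beta1[k, ] * x) else 0) +
    params$b0[k, g] +
    (if (length(ann) > 0) sum(params$b1[k, g, ] * x[ann]) else 0) + eps
  zeta <- params$gamma0[k] + (if (P > 0) sum(params$gamma1[k, ] * x) else 0) +
    params$u0[k, g] +
    (if (length(ann) > 0) sum(params$u1[k, g, ] * x[ann]) else 0)
  list(mu = plogis(eta), phi = exp(params$log_phi[k]), p = plogis(zeta))
}

response_index <- function(k) {
  if (is.character(k)) match(match.arg(k, c("donor", "recipient")), c("donor", "recipient"))
  else as.integer(k)
}

#' Total and pointwise log-likelihood of a rate data set
#'
#' Composes the linked predictors and the zero/one-inflated beta density
#' over every observation of both responses. The pointwise vector is the
#' ingredient of leave-one-out model comparison.
#'
#' @param data a [zoib_data()] object (stacked donor/recipient rows).
#' @param params a [zoib_params()] object.
#' @return list with `total` and `pointwise` (length n).
#' @export
zoib_loglik <- function(data, params) {
  n <- length(data$y)
  pw <- numeric(n)
  q <- if (isTRUE(params$include_one_inflation)) plogis(params$delta0) else c(0, 0)
  for (j in seq_len(n)) {
    lp <- linked_predictors(data$X[j, ], params, data$k[j], data$g[j],
                            eps = if (!is.null(params$eps)) params$eps[j] else 0)
    sh <- beta_from_mean_dispersion(lp$mu, lp$phi)
    pw[j] <- zoib_logpdf(data$y[j], lp$p, q[data$k[j]], sh$alpha1, sh$alpha2)
  }
  if (any(!is.finite(pw))) {
    bad <- which(!is.finite(pw))[1]
    stop(sprintf("non-finite log-likelihood contribution at observation %d (y = %g)",
                 bad, data$y[bad]), call. = FALSE)
  }
  list(total = sum(pw), pointwise = pw)
}
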