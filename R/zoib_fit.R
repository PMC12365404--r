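# MCMC estimation of the zero/one-inflated beta hierarchical model.
#
# The ZOIB likelihood factorizes over the zero indicator (a Bernoulli with
# logit link) and the strictly positive rates (a beta with mean/dispersion
# links), so the joint model is expressed directly in the BUGS language and
# sampled with JAGS. Priors: normal(0, 5) on all logit/log-scale fixed
# effects, half-normal(2) on every random-effect and residual scale.

.prior_prec_fixed <- 1 / 25  # normal sd 5
.prior_prec_scale <- 1 / 4   # half-normal sd 2

zoib_jags_model <- function(spec, P, Pa) {
  fe <- function(base, arr) {
    if (P == 0) base else paste0(base, " + inprod(", arr, "[k[j],1:P], X[j,1:P])")
  }
  re <- function(base, arr) {
    if (Pa == 0) base else paste0(base, " + inprod(", arr, "[k[j],g[j],1:Pa], Xa[j,1:Pa])")
  }
  mu_line <- re(fe("beta0[k[j]]", "beta1"), "b1")
  mu_line <- paste0(mu_line, " + b0[k[j],g[j]]")
  if (spec$include_eps) mu_line <- paste0(mu_line, " + eps[j]")
  p_line <- re(fe("gamma0[k[j]]", "gamma1"), "u1")
  p_line <- paste0(p_line, " + u0[k[j],g[j]]")
  phi_line <- if (spec$phi_by_population)
    "exp(logphi[k[j]] + lphig[k[j],g[j]])" else "exp(logphi[k[j]])"

  lines <- c(
    "model {",
    "  for (j in 1:N) {",
    "    z[j] ~ dbern(p[j])",
    paste0("    logit(p[j]) <- ", p_line),
    paste0("    logit(mu[j]) <- ", mu_line),
    paste0("    phi_j[j] <- ", phi_line),
    if (spec$include_eps) "    eps[j] ~ dnorm(0, pow(sigeps[k[j]], -2))",
    "  }",
    if (spec$include_one_inflation) c(
      "  for (i in 1:Nnz) {",
      "    o[i] ~ dbern(q1[k[nz[i]]])",
      "  }",
      "  for (r in 1:2) { logit(q1[r]) <- delta0[r] }"),
    "  for (i in 1:Npos) {",
    "    ypos[i] ~ dbeta(mu[pos[i]] * phi_j[pos[i]], (1 - mu[pos[i]]) * phi_j[pos[i]])",
    "  }",
    "  for (r in 1:2) {",
    "    beta0[r] ~ dnorm(0, prec_fe)",
    "    gamma0[r] ~ dnorm(0, prec_fe)",
    "    logphi[r] ~ dnorm(0, prec_fe)",
    if (spec$include_one_inflation) "    delta0[r] ~ dnorm(0, prec_fe)",
    if (P > 0) c(
      "    for (c in 1:P) {",
      "      beta1[r,c] ~ dnorm(0, prec_fe)",
      "      gamma1[r,c] ~ dnorm(0, prec_fe)",
      "    }"),
    "    sb0[r] ~ dnorm(0, prec_sc) T(0,)",
    "    su0[r] ~ dnorm(0, prec_sc) T(0,)",
    if (spec$include_eps) "    sigeps[r] ~ dnorm(0, prec_sc) T(0,)",
    if (spec$phi_by_population) "    sphig[r] ~ dnorm(0, prec_sc) T(0,)",
    if (Pa > 0) c(
      "    for (a in 1:Pa) {",
      "      sb1[r,a] ~ dnorm(0, prec_sc) T(0,)",
      "      su1[r,a] ~ dnorm(0, prec_sc) T(0,)",
      "    }"),
    "    for (q in 1:G) {",
    "      b0[r,q] ~ dnorm(0, pow(sb0[r], -2))",
    "      u0[r,q] ~ dnorm(0, pow(su0[r], -2))",
    if (spec$phi_by_population) "      lphig[r,q] ~ dnorm(0, pow(sphig[r], -2))",
    if (Pa > 0) c(
      "      for (a in 1:Pa) {",
      "        b1[r,q,a] ~ dnorm(0, pow(sb1[r,a], -2))",
      "        u1[r,q,a] ~ dnorm(0, pow(su1[r,a], -2))",
      "      }"),
    "    }",
    "  }",
    "}")
  paste(unlist(lines), collapse = "\n")
}

#' Fit the zero/one-inflated beta hierarchical regression by MCMC
#'
#' Samples the joint donor/recipient model with JAGS: several chains, the
#' first half of each discarded as warm-up (which includes the sampler's
#' adaptation phase), the remainder kept for inference. Pointwise
#' log-likelihoods for every observation are recomputed from the draws for
#' leave-one-out model comparison, and split-chain Gelman-Rubin statistics
#' are attached. The seed fully determines the output.
#'
#' @param data a [zoib_data()] object.
#' @param spec a [zoib_spec()].
#' @param chains number of MCMC chains (at least 2 for diagnostics).
#' @param iterations total samples per chain, warm-up included.
#' @param warmup samples discarded from the start of each chain.
#' @param seed integer; seeds all chains reproducibly.
#' @param quiet suppress JAGS progress output.
#' @param compute_log_lik set FALSE to skip the pointwise log-likelihood
#'   matrix (saves time when LOO is not needed).
#' @return object of class `zoib_fit`: posterior draws (`samples` as a
#'   `coda::mcmc.list`, `draws` as one matrix), `rhat`, `converged`,
#'   `log_lik` (draws x observations), and the data/spec used.
#' @export
fit_zoib <- function(data, spec = zoib_spec(), chains = 6, iterations = 4000,
                     warmup = floor(iterations / 2), seed = 1, quiet = TRUE,
                     compute_log_lik = TRUE) {
  stopifnot(inherits(data, "zoib_data"), inherits(spec, "zoib_spec"))
  if (length(data$y) == 0) stop("no observations to fit", call. = FALSE)
  if (chains < 2) stop("at least 2 chains are required for convergence diagnostics",
                       call. = FALSE)
  if (warmup < 2 || warmup >= iterations)
    stop("warmup must lie in [2, iterations)", call. = FALSE)
  if (!setequal(spec$covariates, data$covariates) ||
      !identical(spec$covariates, data$covariates))
    stop("spec covariates do not match the design matrix columns", call. = FALSE)

  P <- length(spec$covariates)
  Pa <- length(spec$random_slopes)
  ann_idx <- match(spec$random_slopes, spec$covariates)
  G <- length(data$populations)
  N <- length(data$y)
  pos <- which(data$y > 0 & data$y < 1)
  jd <- list(N = N, G = G, z = as.numeric(data$y == 0),
             k = data$k, g = data$g,
             pos = pos, Npos = length(pos), ypos = data$y[pos],
             prec_fe = .prior_prec_fixed, prec_sc = .prior_prec_scale)
  if (P > 0) { jd$P <- P; jd$X <- data$X }
  if (Pa > 0) { jd$Pa <- Pa; jd$Xa <- data$X[, ann_idx, drop = FALSE] }
  if (spec$include_one_inflation) {
    nz <- which(data$y > 0)
    jd$nz <- nz; jd$Nnz <- length(nz); jd$o <- as.numeric(data$y[nz] == 1)
  }

  model_str <- zoib_jags_model(spec, P, Pa)
  inits <- lapply(seq_len(chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) + 7919L * i) %% 2147483629L + 1L))
  adapt <- max(2L, min(1000L, floor(warmup / 2)))
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = jd,
                            inits = inits, n.chains = chains,
                            n.adapt = adapt, quiet = quiet)
    burn_left <- warmup - adapt
    if (burn_left > 0) update(jm, burn_left, progress.bar = "none")
    monitors <- c("beta0", "gamma0", "logphi", "b0", "u0", "sb0", "su0")
    if (P > 0) monitors <- c(monitors, "beta1", "gamma1")
    if (Pa > 0) monitors <- c(monitors, "b1", "u1", "sb1", "su1")
    if (spec$include_eps) monitors <- c(monitors, "eps", "sigeps")
    if (spec$include_one_inflation) monitors <- c(monitors, "delta0")
    if (spec$phi_by_population) monitors <- c(monitors, "lphig", "sphig")
    rjags::coda.samples(jm, monitors, n.iter = iterations - warmup,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressMessages(run()) else run()

  draws <- do.call(rbind, lapply(samples, as.matrix))
  rhat <- gelman_rubin(samples)
  fit <- structure(list(
    samples = samples, draws = draws, spec = spec, data = data,
    chains = chains, iterations = iterations, warmup = warmup, seed = seed,
    rhat = rhat, converged = isTRUE(attr(rhat, "converged")),
    log_lik = NULL), class = "zoib_fit")
  if (compute_log_lik) fit$log_lik <- pointwise_log_lik(fit)
  fit
}

# draws x observations matrix of ZOIB log-densities, vectorized over draws.
pointwise_log_lik <- function(fit) {
  d <- fit$data; M <- fit$draws; spec <- fit$spec
  P <- length(spec$covariates); Pa <- length(spec$random_slopes)
  ann_idx <- match(spec$random_slopes, spec$covariates)
  S <- nrow(M); N <- length(d$y)
  ll <- matrix(NA_real_, S, N)
  col <- function(nm) M[, nm, drop = TRUE]
  for (j in seq_len(N)) {
    kj <- d$k[j]; gj <- d$g[j]; xj <- d$X[j, ]
    eta <- col(sprintf("beta0[%d]", kj)) + col(sprintf("b0[%d,%d]", kj, gj))
    zet <- col(sprintf("gamma0[%d]", kj)) + col(sprintf("u0[%d,%d]", kj, gj))
    if (P > 0) {
      eta <- eta + M[, sprintf("beta1[%d,%d]", kj, seq_len(P)), drop = FALSE] %*% xj
      zet <- zet + M[, sprintf("gamma1[%d,%d]", kj, seq_len(P)), drop = FALSE] %*% xj
    }
    if (Pa > 0) {
      xa <- xj[ann_idx]
      eta <- eta + M[, sprintf("b1[%d,%d,%d]", kj, gj, seq_len(Pa)), drop = FALSE] %*% xa
      zet <- zet + M[, sprintf("u1[%d,%d,%d]", kj, gj, seq_len(Pa)), drop = FALSE] %*% xa
    }
    if (spec$include_eps) eta <- eta + col(sprintf("eps[%d]", j))
    lphi <- col(sprintf("logphi[%d]", kj))
    if (spec$phi_by_population) lphi <- lphi + col(sprintf("lphig[%d,%d]", kj, gj))
    phi <- exp(pmin(lphi, 500))
    # clamp: extreme pre-convergence draws can push mu to the boundary,
    # where the beta shapes degenerate to 0
    mu <- pmin(pmax(plogis(as.vector(eta)), 1e-12), 1 - 1e-12)
    pz <- pmin(pmax(plogis(as.vector(zet)), 1e-15), 1 - 1e-15)
    if (d$y[j] == 0) {
      ll[, j] <- log(pz)
    } else {
      lq <- if (spec$include_one_inflation)
        plogis(col(sprintf("delta0[%d]", kj))) else 0
      if (d$y[j] == 1) {
        ll[, j] <- log1p(-pz) + log(lq)
      } else {
        ll[, j] <- log1p(-pz) + log1p(-lq) +
          dbeta(d$y[j], mu * phi, (1 - mu) * phi, log = TRUE)
      }
    }
  }
  ll
}

#' Posterior medians and credible intervals in published-table layout
#'
#' One row per (sub-model, response, parameter): posterior median and the
#' 2.5 and 97.5 percent quantiles. Sub-model `mu` holds the mean-model
#' fixed effects, `p` the zero-model fixed effects, `phi` the
#' log-dispersion intercepts.
#'
#' @param fit a `zoib_fit`.
#' @return data.frame with columns `submodel`, `response`, `parameter`,
#'   `median`, `q2.5`, `q97.5`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "zoib_fit"))
  M <- fit$draws
  covs <- fit$spec$covariates
  P <- length(covs)
  resp <- c("donor", "recipient")
  row <- function(submodel, r, param, nm) {
    qs <- quantile(M[, nm], c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(submodel = submodel, response = resp[r], parameter = param,
               median = qs[1], q2.5 = qs[2], q97.5 = qs[3],
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (r in 1:2) {
    out <- c(out, list(row("mu", r, "intercept", sprintf("beta0[%d]", r))))
    if (P > 0) out <- c(out, lapply(seq_len(P), function(c.)
      row("mu", r, covs[c.], sprintf("beta1[%d,%d]", r, c.))))
  }
  for (r in 1:2) {
    out <- c(out, list(row("p", r, "intercept", sprintf("gamma0[%d]", r))))
    if (P > 0) out <- c(out, lapply(seq_len(P), function(c.)
      row("p", r, covs[c.], sprintf("gamma1[%d,%d]", r, c.))))
  }
  for (r in 1:2)
    out <- c(out, list(row("phi", r, "log_phi", sprintf("logphi[%d]", r))))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.zoib_fit <- function(x, ...) {
  cat(sprintf("ZOIB hierarchical fit: %d observations, %d populations, %d covariate(s)\n",
              length(x$data$y), length(x$data$populations),
              length(x$spec$covariates)))
  cat(sprintf("chains: %d, iterations: %d (warmup %d), seed %s\n",
              x$chains, x$iterations, x$warmup, format(x$seed)))
  cat(sprintf("max split R-hat: %.4f (%s)\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged at the 1.01 threshold" else "NOT converged"))
  invisible(x)
}
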