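test_that("mean/dispersion parameterization maps to beta shapes", {
  sh <- beta_from_mean_dispersion(0.5, 2)
  expect_equal(c(sh$alpha1, sh$alpha2), c(1, 1))
  sh <- beta_from_mean_dispersion(0.1, 10)
  expect_equal(c(sh$alpha1, sh$alpha2), c(1, 9))
  # verify the mean of Beta(1, 9) by quadrature
  m <- integrate(function(x) x * dbeta(x, 1, 9), 0, 1)$value
  expect_equal(m, 0.1, tolerance = 1e-8)
  # identity alpha1 + alpha2 = phi over random parameters
  set.seed(1)
  for (i in 1:25) {
    mu <- runif(1, 0.01, 0.99); phi <- runif(1, 0.1, 50)
    sh <- beta_from_mean_dispersion(mu, phi)
    expect_equal(sh$alpha1 + sh$alpha2, phi)
  }
  expect_error(beta_from_mean_dispersion(0, 2), "mu")
  expect_error(beta_from_mean_dispersion(1, 2), "mu")
  expect_error(beta_from_mean_dispersion(0.5, 0), "phi")
})

test_that("the piecewise log-density branches are correct", {
  expect_equal(zoib_logpdf(0, p = 0.3, alpha1 = 1, alpha2 = 1), log(0.3))
  expect_equal(zoib_logpdf(0.5, p = 0, q = 0, alpha1 = 1, alpha2 = 1), 0)
  expect_equal(zoib_logpdf(1, p = 0.2, q = 0.1, alpha1 = 2, alpha2 = 2),
               log(0.8) + log(0.1))
  # q = 0: a one has density zero
  expect_identical(zoib_logpdf(1, p = 0.2, q = 0, alpha1 = 2, alpha2 = 2), -Inf)
  expect_error(zoib_logpdf(1.2, p = 0.1, alpha1 = 1, alpha2 = 1), "y must lie")
  expect_error(zoib_logpdf(-0.1, p = 0.1, alpha1 = 1, alpha2 = 1), "y must lie")
})

test_that("total probability mass is one for randomized parameters", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.9); q <- sample(c(0, runif(1, 0, 0.3)), 1)
    mu <- runif(1, 0.05, 0.95); phi <- runif(1, 0.2, 80)
    sh <- beta_from_mean_dispersion(mu, phi)
    cont <- integrate(function(x) exp(zoib_logpdf(x, p, q, sh$alpha1, sh$alpha2)),
                      0, 1, rel.tol = 1e-10)$value
    mass <- p + (1 - p) * q + cont
    expect_equal(mass, 1, tolerance = 1e-8)
  }
})

test_that("conditional variance follows mu(1-mu)/(1+phi)", {
  set.seed(11)
  mu <- 0.3; phi <- 12
  sh <- beta_from_mean_dispersion(mu, phi)
  x <- rbeta(2e5, sh$alpha1, sh$alpha2)
  theo <- mu * (1 - mu) / (1 + phi)
  mc_se <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(var(x) - theo), 4 * mc_se)
})

test_that("link functions compose into the linear predictors", {
  p0 <- zoib_params(covariates = character(0), n_populations = 2)
  lp <- linked_predictors(numeric(0), p0, "donor", 1)
  expect_equal(lp, list(mu = 0.5, phi = 1, p = 0.5))
  # slope moving logit(mu) to logit(0.9)
  p1 <- zoib_params(covariates = "flow", n_populations = 2,
                    beta1 = matrix(qlogis(0.9), 2, 1))
  lp <- linked_predictors(1, p1, "donor", 1)
  expect_equal(lp$mu, 0.9)
  # a population intercept shifts logit(mu) exactly
  set.seed(2)
  b0 <- matrix(rnorm(4), 2, 2)
  p2 <- zoib_params(covariates = "flow", n_populations = 2,
                    beta0 = c(-1, -2), beta1 = matrix(0.5, 2, 1), b0 = b0)
  x <- 0.7
  lp <- linked_predictors(x, p2, 2, 2)
  expect_equal(qlogis(lp$mu), -2 + 0.5 * x + b0[2, 2], tolerance = 1e-12)
})

test_that("pipeline log-likelihood matches the brute-force oracle", {
  spec <- zoib_spec(c("area", "escapement", "confluence_temp"),
                    random_slopes = c("escapement", "confluence_temp"))
  sim <- simulate_rates(sim_config(n_populations = 6, n_years = 9, spec = spec,
                                   seed = 5))
  expect_gte(length(sim$data$y), 100)
  got <- zoib_loglik(sim$data, sim$params)
  want <- oracle_loglik(sim$data, sim$params)
  expect_equal(got$pointwise, want$pointwise, tolerance = 1e-8)
  expect_equal(got$total, want$total, tolerance = 1e-8)
  # single zero observation contributes exactly log(p)
  j <- which(sim$data$y == 0)[1]
  lp <- linked_predictors(sim$data$X[j, ], sim$params, sim$data$k[j], sim$data$g[j])
  expect_equal(got$pointwise[j], log(lp$p))
})

test_that("likelihood increases as mu approaches the empirical mean", {
  # positive-only one-covariate toy data at mu = 0.3
  set.seed(3)
  sh <- beta_from_mean_dispersion(0.3, 25)
  y <- rbeta(150, sh$alpha1, sh$alpha2)
  dat <- structure(list(y = y, k = rep(1L, 150), g = rep(1L, 150),
                        X = matrix(0, 150, 0)), class = "zoib_data")
  ll_at <- function(mu) {
    p <- zoib_params(n_populations = 1, beta0 = c(qlogis(mu), 0),
                     gamma0 = c(-20, -20), log_phi = c(log(25), 0))
    zoib_loglik(dat, p)$total
  }
  grid <- c(0.1, 0.2, 0.3, 0.45, 0.6)
  lls <- vapply(grid, ll_at, numeric(1))
  expect_equal(which.max(lls), 3L)
  expect_true(all(diff(lls[1:3]) > 0) && all(diff(lls[3:5]) < 0))
})
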