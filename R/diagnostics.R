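#' Split-chain Gelman-Rubin potential scale reduction
#'
#' Each chain is split in half and the potential scale reduction factor
#' R-hat = sqrt(((n-1)/n * W + B/n) / W) is computed per parameter from the
#' between-half (B) and within-half (W) variances. Splitting makes the
#' statistic sensitive to trends within chains, not only to disagreement
#' between them. Convergence is declared when every parameter's statistic
#' is below 1.01.
#'
#' @param x a `zoib_fit`, a `coda::mcmc.list`, or a list of iterations x
#'   parameters matrices (one per chain).
#' @return named numeric vector of R-hat values (NA for parameters with no
#'   within-chain variance), with attribute `converged` (all < 1.01).
#' @export
gelman_rubin <- function(x) {
  chains <- if (inherits(x, "zoib_fit")) lapply(x$samples, as.matrix)
  else if (coda::is.mcmc.list(x)) lapply(x, as.matrix)
  else if (is.list(x)) lapply(x, as.matrix)
  else stop("x must be a zoib_fit, mcmc.list, or list of chain matrices", call. = FALSE)
  if (length(chains) < 2)
    stop("at least 2 chains are required for the Gelman-Rubin statistic", call. = FALSE)
  n <- nrow(chains[[1]])
  if (n < 4) stop("chains too short to split", call. = FALSE)
  nh <- floor(n / 2)
  halves <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(nh), , drop = FALSE],
         ch[seq.int(n - nh + 1, n), , drop = FALSE])), recursive = FALSE)
  m <- length(halves)
  means <- vapply(halves, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(halves, function(h) apply(h, 2, var), numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  W <- rowMeans(vars)
  B <- nh * apply(means, 1, var)
  rhat <- sqrt(((nh - 1) / nh * W + B / nh) / W)
  rhat[W == 0] <- NA_real_
  names(rhat) <- colnames(chains[[1]])
  attr(rhat, "converged") <- all(rhat < 1.01, na.rm = TRUE)
  rhat
}
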