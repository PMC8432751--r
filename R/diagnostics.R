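# MCMC convergence diagnostics: split-chain potential scale reduction
# factor (R-hat), autocorrelation-based effective sample size, and lag-k
# autocorrelation summaries.

# split each chain in half along iterations: (iter x chains) -> matrix with
# twice the chains and half the iterations
split_chains <- function(m) {
  n <- nrow(m)
  half <- n %/% 2L
  cbind(m[seq_len(half), , drop = FALSE],
        m[(n - half + 1L):n, , drop = FALSE])
}

# split-chain R-hat for one parameter (iterations x chains matrix)
rhat_param <- function(m) {
  m <- split_chains(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) return(NA_real_)
  mu <- colMeans(m)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(mu)
  var_plus <- (n - 1) / n * W + B / n
  if (W == 0) return(1)
  sqrt(var_plus / W)
}

# effective sample size for one parameter via chain-averaged
# autocorrelations with Geyer's initial monotone positive sequence
ess_param <- function(m) {
  m <- split_chains(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) return(NA_real_)
  mu <- colMeans(m)
  W <- mean(apply(m, 2, stats::var))
  var_plus <- (n - 1) / n * W + n * stats::var(mu) / n
  if (var_plus == 0) return(NA_real_)
  max_lag <- n - 1L
  acov <- sapply(seq_len(k), function(j) {
    a <- stats::acf(m[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)                 # lag 0 .. max_lag
  rho <- c(1, 1 - (W - mean_acov[-1]) / var_plus)  # lags 0, 1, ...
  # Geyer pair sums (rho0+rho1, rho2+rho3, ...): stop before the first
  # non-positive pair, then enforce monotone decay
  t_max <- length(rho) - length(rho) %% 2L
  Pk <- rho[seq(1, t_max, by = 2)] + rho[seq(2, t_max, by = 2)]
  first_neg <- which(Pk <= 0)
  if (length(first_neg)) Pk <- Pk[seq_len(max(first_neg[1] - 1L, 1L))]
  Pk <- cummin(Pk)
  tau <- max(-1 + 2 * sum(Pk), 1 / log10(n * k))  # guard against tau < 1
  min(n * k / tau, n * k)
}

#' Convergence diagnostics for posterior draws
#'
#' Computes, per parameter, the split-chain potential scale reduction
#' factor (Gelman--Rubin R-hat), the autocorrelation-based effective sample
#' size, and the lag-1/lag-10 autocorrelations of the pooled chains, and
#' checks them against the thresholds R-hat < 1.01 and ESS > 1,000.  Values
#' of R-hat close to 1.0 are suggestive of convergence.
#'
#' @param x a `posterior_fit` or an iterations x chains x parameters array.
#' @param rhat_max,ess_min pass/fail thresholds.
#' @return a `mcmc_diagnostics` data frame with one row per parameter
#'   (`rhat`, `ess`, `acf_lag1`, `acf_lag10`, `pass`), with attributes
#'   `n_divergent` (0: the random-walk sampler defines no divergences),
#'   `single_chain` and `all_pass`.
#' @export
diagnose <- function(x, rhat_max = 1.01, ess_min = 1000) {
  arr <- if (inherits(x, "posterior_fit")) x$draws_array else x
  stopifnot(length(dim(arr)) == 3L)
  params <- dimnames(arr)[[3]]
  if (is.null(params)) params <- paste0("param", seq_len(dim(arr)[3]))
  single <- dim(arr)[2] == 1L
  if (single) {
    message("single chain: R-hat computed by the split-chain method")
  }
  out <- do.call(rbind, lapply(seq_len(dim(arr)[3]), function(j) {
    m <- arr[, , j, drop = FALSE][, , 1]
    if (is.null(dim(m))) m <- matrix(m, ncol = dim(arr)[2])
    pooled <- as.vector(m)
    ac <- stats::acf(pooled, lag.max = 10, plot = FALSE)$acf[, 1, 1]
    data.frame(parameter = params[j],
               rhat = rhat_param(m),
               ess = ess_param(m),
               acf_lag1 = ac[2],
               acf_lag10 = ac[11],
               stringsAsFactors = FALSE)
  }))
  out$pass <- out$rhat < rhat_max & out$ess > ess_min
  rownames(out) <- NULL
  structure(out, class = c("mcmc_diagnostics", "data.frame"),
            n_divergent = 0L, single_chain = single,
            all_pass = all(out$pass))
}
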