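# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO).  The importance ratios for observation i are 1/p(y_i | theta)
# across posterior draws; their upper tail is stabilized by fitting a
# generalized Pareto distribution (GPD) and replacing the tail weights with
# the fitted quantiles.  The GPD shape estimate k-hat diagnoses how
# reliable each observation's weights are (k-hat < 0.7: good).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Zhang & Stephens (2009) posterior-mean estimator for the GPD shape k and
# scale sigma, fitted to exceedances x > 0.  Parameterized through
# b = -k/sigma with profile likelihood l(b) = n [log(-b/k(b)) - 1 - k(b)],
# k(b) = mean(log(1 - b x)).  A weak prior nudges k-hat toward 1/2
# (stabilizes small tails).
gpd_fit <- function(x, wip = TRUE) {
  x <- sort.int(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * xstar)
  k_of_b <- vapply(b, function(bj) mean(log1p(-bj * x)), numeric(1))
  # b near 0 makes k -> 0; guard the log
  l <- n * (log(-b / k_of_b) - k_of_b - 1)
  l[!is.finite(l)] <- -Inf
  w <- exp(l - logsumexp(l))
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma <- -k_hat / b_hat
  if (wip) k_hat <- (k_hat * n + 5) / (n + 10)
  list(k = k_hat, sigma = sigma)
}

# GPD quantile with survival (1 + k x / sigma)^(-1/k)
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# smooth one vector of log importance ratios; returns the smoothed log
# weights (unnormalized) and the tail-shape estimate
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5L) return(list(log_weights = log_ratios, k = NA_real_))
  ord <- order(log_ratios)
  tail_idx <- ord[(S - tail_len + 1L):S]
  cutoff <- log_ratios[ord[S - tail_len]]
  exc <- exp(log_ratios[tail_idx]) - exp(cutoff)
  if (all(exc <= 0) || stats::sd(exc) == 0) {
    return(list(log_weights = log_ratios, k = -Inf))
  }
  fit <- gpd_fit(exc[exc > 0])
  qq <- gpd_quantile((seq_len(tail_len) - 0.5) / tail_len, fit$k, fit$sigma)
  smoothed <- log(exp(cutoff) + qq)
  smoothed <- pmin(smoothed, max(log_ratios))   # never exceed the raw max
  lw <- log_ratios
  lw[tail_idx[order(exc)]] <- smoothed
  list(log_weights = lw, k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' @param fit a `posterior_fit` with a pointwise log-likelihood matrix, or
#'   the draws-by-observations matrix itself.
#' @return a `psis_loo` list: `elpd_loo`, `se`, `pointwise` (per-observation
#'   elpd), `pareto_k` (per-observation tail-shape estimates), `n`,
#'   `n_draws`.
#' @export
psis_loo <- function(fit) {
  ll <- if (inherits(fit, "posterior_fit")) fit$loglik else fit
  if (is.null(ll)) {
    stop("fit carries no pointwise log-likelihood (refit with ",
         "pointwise_loglik = TRUE)", call. = FALSE)
  }
  S <- nrow(ll); n <- ncol(ll)
  pointwise <- numeric(n); k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$log_weights - logsumexp(sm$log_weights)
    pointwise[i] <- logsumexp(lw + ll[, i])
    k[i] <- sm$k
  }
  structure(list(elpd_loo = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = k,
                 n = n, n_draws = S),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo = %.2f (SE %.2f), n = %d, draws = %d\n",
              x$elpd_loo, x$se, x$n, x$n_draws))
  bad <- sum(x$pareto_k > 0.7, na.rm = TRUE)
  cat(sprintf("  Pareto k > 0.7 for %d of %d observations\n", bad, x$n))
  invisible(x)
}

#' Compare transition models by PSIS-LOO
#'
#' Ranks candidate fits of the same data by expected log predictive density
#' (higher is better).  Models with any Pareto k-hat above `k_threshold`
#' are flagged as having unreliable importance weights.
#'
#' @param fits named list of `posterior_fit` or `psis_loo` objects fitted to
#'   identical data rows.
#' @param k_threshold reliability threshold for Pareto k (default 0.7).
#' @return a `loo_comparison` data frame ordered best-first: `model`,
#'   `elpd_loo`, `se`, `elpd_diff` and `se_diff` (relative to the best
#'   model), `max_pareto_k`, `reliable`.
#' @export
loo_compare <- function(fits, k_threshold = 0.7) {
  loos <- lapply(fits, function(f) {
    if (inherits(f, "psis_loo")) f else psis_loo(f)
  })
  ns <- vapply(loos, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) {
    stop("comparison error: models were fitted on different numbers of ",
         "observations", call. = FALSE)
  }
  nm <- names(loos)
  if (is.null(nm)) nm <- paste0("model", seq_along(loos))
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  best <- which.max(elpd)
  out <- data.frame(
    model = nm,
    elpd_loo = elpd,
    se = vapply(loos, `[[`, numeric(1), "se"),
    elpd_diff = elpd - elpd[best],
    se_diff = vapply(seq_along(loos), function(j) {
      if (j == best) return(0)
      d <- loos[[j]]$pointwise - loos[[best]]$pointwise
      sqrt(length(d) * stats::var(d))
    }, numeric(1)),
    max_pareto_k = vapply(loos, function(l) {
      suppressWarnings(max(l$pareto_k, na.rm = TRUE))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$reliable <- is.finite(out$max_pareto_k) &
    out$max_pareto_k < k_threshold | out$max_pareto_k == -Inf
  out <- out[order(-out$elpd_loo), ]
  rownames(out) <- NULL
  structure(out, class = c("loo_comparison", "data.frame"))
}
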