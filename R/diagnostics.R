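# Split-chain potential scale reduction and effective sample size,
# following the standard split-Rhat / initial-monotone-sequence estimators.

#' MCMC convergence diagnostics
#'
#' \code{rhat_split} computes the split-chain potential scale reduction
#' factor; \code{ess_basic} the multi-chain effective sample size using
#' per-chain autocorrelations combined with between-chain variance and
#' Geyer's initial monotone positive sequence truncation.
#'
#' @param x numeric matrix of posterior draws, iterations x chains.
#' @return a single number.
#' @export
rhat_split <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  s2 <- apply(sp, 2, var)
  W <- mean(s2)
  B <- nn * var(mu)
  if (W < 1e-12) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' @rdname rhat_split
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  ch_var <- apply(x, 2, var)
  W <- mean(ch_var)
  var_plus <- (n - 1) / n * W + (if (m > 1) var(colMeans(x)) else 0)
  if (var_plus < 1e-12) return(n * m)
  max_lag <- min(n - 2, 1000)
  # mean autocovariance across chains
  acov <- rowMeans(vapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = max_lag, plot = FALSE, type = "covariance",
             demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1)))
  rho <- c(1, 1 - (W - acov[-1]) / var_plus)
  # Geyer: sum lag pairs (rho_0+rho_1), (rho_2+rho_3), ... while positive,
  # enforcing monotone decrease, then tau = -1 + 2 * sum(pairs)
  np <- floor(length(rho) / 2)
  pair <- rho[2 * seq_len(np) - 1] + rho[2 * seq_len(np)]
  k <- which(pair <= 0)
  if (length(k) > 0) pair <- pair[seq_len(k[1] - 1)]
  if (length(pair) > 1) pair <- cummin(pair)
  tau <- -1 + 2 * sum(pair)
  max(n * m / max(tau, 1e-6), 1)
}
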