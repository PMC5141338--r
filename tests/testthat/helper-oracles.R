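# Independent oracles used across the suite.

# Dense-grid (trapezoidal) marginal log-likelihood of the pairwise
# random-intercept model; independent of the quadrature code path.
grid_pair_loglik <- function(y1, y2, beta0, beta1, sigma,
                             n_grid = 2001, width = 8) {
  half <- width * max(sigma, 0.5)
  u <- seq(-half, half, length.out = n_grid)
  du <- u[2] - u[1]
  eta <- c(beta0, beta0 + beta1)
  cnt <- tabulate(1L + 2L * y1 + y2, nbins = 4L)
  pats <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  ll <- vapply(pats, function(y) {
    s1 <- if (y[1] == 1L) 1 else -1
    s2 <- if (y[2] == 1L) 1 else -1
    f <- stats::dnorm(u, sd = sigma) *
      stats::plogis(s1 * (eta[1] + u)) * stats::plogis(s2 * (eta[2] + u))
    log(sum((f[-1] + f[-n_grid]) / 2) * du)
  }, numeric(1))
  sum(cnt * ll)
}

# Maximum-likelihood fit of the same model using only the grid loglik.
grid_pair_fit <- function(y1, y2) {
  n <- length(y1)
  clamp <- function(p) pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)
  start <- c(stats::qlogis(clamp(mean(y1))),
             stats::qlogis(clamp(mean(y2))) - stats::qlogis(clamp(mean(y1))),
             log(0.5))
  opt <- stats::optim(start, function(th) {
    -grid_pair_loglik(y1, y2, th[1], th[2], exp(th[3]), n_grid = 801)
  }, method = "L-BFGS-B", lower = c(-15, -30, log(1e-3)),
  upper = c(15, 30, log(10)), control = list(factr = 1e6))
  list(beta0 = opt$par[1], beta1 = opt$par[2], sigma = exp(opt$par[3]),
       loglik = -opt$value)
}

# Brute-force Cox partial log-likelihood (no ties assumed).
brute_cox_pll <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + sum(x[i, ] * beta) -
      log(sum(exp(as.matrix(x[risk, , drop = FALSE]) %*% beta)))
  }
  ll
}

# write a small wide response CSV and return its path
write_wide_fixture <- function(mat, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "responses.csv")
  df <- data.frame(subject_id = paste0("s", seq_len(nrow(mat))), mat)
  colnames(df) <- c("subject_id", paste0("q", seq_len(ncol(mat))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
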