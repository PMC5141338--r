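# Overall-attrition comparison between groups: discrete dropout times,
# product-limit attrition curves, log-rank test, and Cox proportional
# hazards with completers censored after the final item.
#
# "Survival" is survey participation: the event is dropout, the discrete
# event time is the dropout point (first item after the last answered
# one), and subjects who completed the survey are censored after the
# final question. Item-indexed times make ties massive, so the Efron
# approximation is the default in the Cox fit.

#' Build discrete dropout survival data from a response matrix
#'
#' @param rm a [response_matrix].
#' @param covariates optional covariate data frame merged by subject id.
#' @return Data frame of class `dropout_survival` with `subject_id`,
#'   `time` (dropout point for events, `n_items` for censored
#'   completers), `event` (1 = dropped out, 0 = completer) and any
#'   covariate columns. Attribute `n_items` records the horizon.
#' @export
build_survival_data <- function(rm, covariates = NULL) {
  stopifnot(inherits(rm, "response_matrix"))
  cs <- classify_cells(rm)
  event <- as.integer(!cs$completer)
  time <- ifelse(cs$completer, rm$n_items, cs$dropout_point)
  df <- data.frame(subject_id = rm$subject_ids, time = as.numeric(time),
                   event = event, row.names = NULL)
  if (!is.null(covariates)) {
    covariates <- align_covariates(covariates, rm)
    df <- cbind(df, covariates[setdiff(colnames(covariates), "subject_id")])
  }
  structure(df, n_items = rm$n_items,
            class = c("dropout_survival", "data.frame"))
}

# Product-limit (Kaplan-Meier) participation curve for one group.
.km_curve <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  n_at_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - d / n_at_risk)
  data.frame(time = c(0, ut), n_risk = c(length(time), n_at_risk),
             n_event = c(0, d), surv = c(1, surv))
}

#' Log-rank comparison of dropout patterns between groups
#'
#' Standard log-rank test on the discrete dropout times, with tied
#' events pooled at each time point. Also returns the per-group
#' product-limit participation curves for plotting.
#'
#' @param sd a `dropout_survival` data frame.
#' @param group name of the grouping column (>= 2 nonempty groups).
#' @return Object of class `logrank_result`: `statistic`, `df`,
#'   `p_value`, per-group `observed`/`expected` event counts, and
#'   `curves` (named list of step-function coordinate tables).
#' @export
logrank_test <- function(sd, group) {
  stopifnot(inherits(sd, "dropout_survival") || is.data.frame(sd))
  if (!group %in% colnames(sd)) config_error("unknown group column '%s'", group)
  g <- factor(sd[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2L) config_error("log-rank needs at least 2 nonempty groups")
  time <- sd$time; event <- sd$event
  G <- nlevels(g)
  ut <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(G), levels(g))
  V <- matrix(0, G, G, dimnames = list(levels(g), levels(g)))
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ng <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    dg <- vapply(levels(g), function(l) sum(event == 1 & time == t & g == l),
                 numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      V <- V + d * (n - d) / (n - 1) * (diag(ng / n, G) - tcrossprod(ng / n))
    }
  }
  idx <- seq_len(G - 1L)
  oe <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(oe) %*% solve(Vi, oe)),
                   error = function(e) {
                     drop(t(oe) %*% MASS_ginv(Vi) %*% oe)
                   })
  stat <- max(stat, 0)
  curves <- lapply(stats::setNames(levels(g), levels(g)), function(l) {
    .km_curve(time[g == l], event[g == l])
  })
  structure(list(statistic = stat, df = G - 1L,
                 p_value = stats::pchisq(stat, G - 1L, lower.tail = FALSE),
                 observed = O, expected = E, var = V, curves = curves,
                 group = group),
            class = "logrank_result")
}

# small Moore-Penrose fallback (avoids importing MASS for one edge case)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test on dropout times by '%s'\n", x$group))
  print(data.frame(group = names(x$observed), observed = as.numeric(x$observed),
                   expected = round(as.numeric(x$expected), 2)), row.names = FALSE)
  cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# ---- Cox proportional hazards (partial likelihood, Efron/Breslow ties) ----

.cox_design <- function(sd, covariates, interactions = NULL) {
  terms <- covariates
  if (!is.null(interactions)) {
    terms <- c(terms, vapply(interactions, function(pr) paste(pr, collapse = ":"), ""))
  }
  missing <- setdiff(covariates, colnames(sd))
  if (length(missing) > 0L) config_error("unknown covariate(s): %s",
                                         paste(missing, collapse = ", "))
  fml <- stats::reformulate(terms)
  mf <- stats::model.frame(fml, data = as.data.frame(sd))
  X <- stats::model.matrix(fml, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    data_error("collinear (rank-deficient) covariate columns: %s",
               paste(bad, collapse = ", "))
  }
  X
}

# Partial log-likelihood, gradient and information at beta.
# tt_col: optional index of a column whose value at event time t is
# X[, tt_col] * log(t) (used for the proportional-hazards check).
.cox_pll <- function(beta, time, event, X, ties = "efron", tt_base = NULL) {
  p <- ncol(X)
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  ut <- sort(unique(time[event == 1]))
  for (t in ut) {
    Xt <- X
    if (!is.null(tt_base)) Xt[, p] <- tt_base * log(t)
    risk <- which(time >= t)
    Dset <- which(event == 1 & time == t)
    d <- length(Dset)
    eta <- drop(Xt[risk, , drop = FALSE] %*% beta)
    w <- exp(eta)
    WR <- sum(w)
    S1R <- drop(crossprod(Xt[risk, , drop = FALSE], w))
    S2R <- crossprod(Xt[risk, , drop = FALSE] * w, Xt[risk, , drop = FALSE])
    etaD <- drop(Xt[Dset, , drop = FALSE] %*% beta)
    wD <- exp(etaD)
    WD <- sum(wD)
    S1D <- drop(crossprod(Xt[Dset, , drop = FALSE], wD))
    S2D <- crossprod(Xt[Dset, , drop = FALSE] * wD, Xt[Dset, , drop = FALSE])
    ll <- ll + sum(etaD)
    for (l in seq_len(d) - 1L) {
      a <- if (ties == "efron") l / d else 0
      denom <- WR - a * WD
      s1 <- S1R - a * S1D
      s2 <- S2R - a * S2D
      xbar <- s1 / denom
      ll <- ll - log(denom)
      grad <- grad - xbar
      info <- info + s2 / denom - tcrossprod(xbar)
    }
    grad <- grad + colSums(Xt[Dset, , drop = FALSE])
  }
  list(ll = ll, grad = grad, info = info)
}

#' Cox proportional hazards regression on discrete dropout times
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with the Efron
#' correction for tied event times (default; item-indexed dropout times
#' produce massive ties; Breslow is available). Standard errors come
#' from the observed information. A proportional-hazards check is
#' reported per covariate as the Wald p-value of a
#' `covariate x log(time)` interaction added one at a time; a small
#' p-value indicates a time-varying effect.
#'
#' @param sd a `dropout_survival` data frame.
#' @param covariates character vector of covariate column names.
#' @param interactions optional list of character pairs, each added as an
#'   interaction term.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `cox_fit`: `coefficients`, `se`, `z`,
#'   `p_value`, `hazard_ratio`, `var`, `loglik` (at 0 and at the
#'   estimate), `score_test` (at beta = 0), `ph_check`, `ties`,
#'   `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(sd, covariates, interactions = NULL,
                    ties = c("efron", "breslow"), max_iter = 30, tol = 1e-9) {
  ties <- match.arg(ties)
  if (length(covariates) < 1L) config_error("need at least one covariate")
  X <- .cox_design(sd, covariates, interactions)
  time <- sd$time; event <- sd$event
  if (sum(event) < ncol(X) + 1L) data_error("too few events (%d) for %d parameter(s)",
                                            sum(event), ncol(X))
  fit <- .cox_newton(time, event, X, ties, max_iter, tol)
  # score test at beta = 0 (equals the log-rank statistic for a single
  # binary covariate without ties)
  at0 <- .cox_pll(numeric(ncol(X)), time, event, X, ties)
  score_stat <- drop(t(at0$grad) %*% solve(at0$info, at0$grad))
  ph <- vapply(colnames(X), function(cn) {
    j <- match(cn, colnames(X))
    Xe <- cbind(X, tt = 0)
    f <- tryCatch(.cox_newton(time, event, Xe, ties, max_iter, tol,
                              tt_base = X[, j]),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NA_real_)
    k <- ncol(Xe)
    2 * stats::pnorm(-abs(f$beta[k] / sqrt(f$var[k, k])))
  }, numeric(1))
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 se = stats::setNames(sqrt(diag(fit$var)), colnames(X)),
                 z = fit$beta / sqrt(diag(fit$var)),
                 p_value = 2 * stats::pnorm(-abs(fit$beta / sqrt(diag(fit$var)))),
                 hazard_ratio = exp(fit$beta),
                 var = fit$var, loglik = c(null = at0$ll, fitted = fit$ll),
                 score_test = list(statistic = score_stat, df = ncol(X),
                                   p_value = stats::pchisq(score_stat, ncol(X),
                                                           lower.tail = FALSE)),
                 ph_check = ph, ties = ties, converged = fit$converged,
                 iterations = fit$iter, n = nrow(X), n_events = sum(event)),
            class = "cox_fit")
}

.cox_newton <- function(time, event, X, ties, max_iter = 30, tol = 1e-9,
                        tt_base = NULL) {
  p <- ncol(X)
  beta <- numeric(p)
  cur <- .cox_pll(beta, time, event, X, ties, tt_base)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    step <- tryCatch(solve(cur$info, cur$grad),
                     error = function(e) numeric_error("singular information matrix"))
    halv <- 0
    repeat {
      cand <- beta + step
      nxt <- .cox_pll(cand, time, event, X, ties, tt_base)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      step <- step / 2
      halv <- halv + 1
      if (halv > 20) break
    }
    change <- abs(nxt$ll - cur$ll)
    beta <- cand
    cur <- nxt
    if (change < tol * (abs(cur$ll) + 1)) { converged <- TRUE; break }
  }
  list(beta = beta, ll = cur$ll, var = .safe_solve(cur$info),
       converged = converged, iter = iter)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards on dropout times (%s ties), %d subjects, %d events\n",
              x$ties, x$n, x$n_events))
  print(data.frame(coef = round(x$coefficients, 4), HR = round(x$hazard_ratio, 4),
                   se = round(x$se, 4), z = round(x$z, 3),
                   p = signif(x$p_value, 3),
                   ph_check_p = signif(x$ph_check, 3)))
  if (!x$converged) cat("  WARNING: Newton-Raphson did not converge\n")
  invisible(x)
}

#' Screen candidate covariates, then fit an adjusted model with interaction
#'
#' Reproduces the screening-then-adjustment workflow: each candidate
#' covariate is tested one at a time against time to dropout (bivariate
#' Cox Wald test); those significant at `alpha` are then entered with
#' the exposure and an exposure-by-covariate interaction into a
#' multivariate model. A significant interaction is labeled effect
#' modification; a significant covariate main effect marks a confounding
#' candidate. Labels only, not causal claims.
#'
#' @param sd a `dropout_survival` data frame.
#' @param exposure the covariate of primary interest.
#' @param candidates character vector of candidate covariates to screen.
#' @param alpha screening / significance gate (default 0.05).
#' @param ties passed to [cox_fit()].
#' @return List of class `screen_then_adjust`: `screen` (data frame of
#'   bivariate p-values), `selected`, `adjusted` (the multivariate
#'   `cox_fit`, or the unadjusted exposure fit when nothing screens in),
#'   `interpretation` (character labels per term).
#' @export
screen_then_adjust <- function(sd, exposure, candidates, alpha = 0.05,
                               ties = "efron") {
  screen_p <- vapply(candidates, function(cv) {
    f <- tryCatch(cox_fit(sd, cv, ties = ties), error = function(e) NULL)
    if (is.null(f)) NA_real_ else min(f$p_value)
  }, numeric(1))
  selected <- candidates[!is.na(screen_p) & screen_p < alpha]
  if (length(selected) == 0L) {
    adj <- cox_fit(sd, exposure, ties = ties)
    inter <- character(0)
  } else {
    adj <- cox_fit(sd, c(exposure, selected),
                   interactions = lapply(selected, function(s) c(exposure, s)),
                   ties = ties)
    inter <- names(adj$p_value)[grepl(":", names(adj$p_value)) &
                                  adj$p_value < alpha]
  }
  main <- setdiff(names(adj$p_value)[adj$p_value < alpha],
                  c(inter, grep(":", names(adj$p_value), value = TRUE)))
  interp <- c(
    if (length(inter) > 0) stats::setNames(rep("effect modification", length(inter)), inter),
    stats::setNames(rep("significant main effect (confounding candidate)",
                        length(main)), main))
  structure(list(screen = data.frame(candidate = candidates, p_value = screen_p),
                 selected = selected, adjusted = adj, alpha = alpha,
                 interpretation = interp),
            class = "screen_then_adjust")
}

#' Export survival data or KM curves as CSV
#' @param x a `dropout_survival` data frame or a `logrank_result`.
#' @param path output CSV path.
#' @export
write_survival_csv <- function(x, path) {
  if (inherits(x, "logrank_result")) {
    df <- do.call(rbind, lapply(names(x$curves), function(g) {
      cbind(group = g, x$curves[[g]])
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
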