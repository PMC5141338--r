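# Discrete dropout survival: data construction, log-rank, Cox.

surv_df <- function(time, event, ...) {
  df <- data.frame(time = time, event = event, ...)
  class(df) <- c("dropout_survival", "data.frame")
  df
}

test_that("survival data encodes dropout times and completer censoring", {
  mat <- rbind(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),   # completer
               c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0),   # drops after item 4
               c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))   # immediate dropout
  rm <- response_matrix(mat)
  sd <- build_survival_data(rm)
  expect_equal(sd$time, c(12, 5, 2))
  expect_equal(sd$event, c(0L, 1L, 1L))
  # event = 0 iff censored at the horizon
  expect_true(all((sd$event == 0) == (sd$time == 12 &
                                        classify_cells(rm)$completer)))
  expect_true(all(sd$time >= 2 & sd$time <= 12))
  # conservation: events = starters - completers
  expect_equal(sum(sd$event), rm$n_subjects - sum(classify_cells(rm)$completer))
})

test_that("identical groups give a zero log-rank statistic", {
  sd <- surv_df(rep(c(2, 3, 5, 7), 2), rep(c(1, 1, 1, 0), 2),
                g = rep(c("A", "B"), each = 4))
  lr <- logrank_test(sd, "g")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-8)
})

test_that("toy log-rank matches the hand-worked observed-minus-expected table", {
  # group A times (2,3,4) all events, group B (4,5,6) all events:
  # O_A = 3, E_A = 0.5 + 0.4 + 0.5 = 1.4, V = 0.25 + 0.24 + 0.25 = 0.74
  sd <- surv_df(c(2, 3, 4, 4, 5, 6), rep(1L, 6), g = rep(c("A", "B"), each = 3))
  lr <- logrank_test(sd, "g")
  expect_equal(unname(lr$observed["A"]), 3)
  expect_equal(unname(lr$expected["A"]), 1.4)
  expect_equal(lr$statistic, (3 - 1.4)^2 / 0.74, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # label swap leaves the statistic unchanged
  sd$g <- ifelse(sd$g == "A", "B", "A")
  expect_equal(logrank_test(sd, "g")$statistic, lr$statistic)
})

test_that("log-rank and Cox match the survival package on random datasets", {
  skip_if_not_installed("survival")
  set.seed(14)
  for (r in 1:20) {
    n <- 250
    sd <- surv_df(sample(2:9, n, TRUE), rbinom(n, 1, 0.75),
                  g = sample(c("a", "b", if (r %% 2) "c"), n, TRUE),
                  x = rnorm(n), z = rbinom(n, 1, 0.4))
    lr <- logrank_test(sd, "g")
    sref <- survival::survdiff(survival::Surv(time, event) ~ g, data = sd)
    expect_equal(lr$statistic, sref$chisq, tolerance = 1e-4)
    cf <- cox_fit(sd, c("x", "z"))
    cref <- survival::coxph(survival::Surv(time, event) ~ x + z, data = sd,
                            ties = "efron")
    expect_equal(unname(cf$coefficients), unname(stats::coef(cref)),
                 tolerance = 1e-4)
    expect_equal(unname(cf$se), unname(sqrt(diag(stats::vcov(cref)))),
                 tolerance = 1e-4)
    cfb <- cox_fit(sd, c("x", "z"), ties = "breslow")
    crefb <- survival::coxph(survival::Surv(time, event) ~ x + z, data = sd,
                             ties = "breslow")
    expect_equal(unname(cfb$coefficients), unname(stats::coef(crefb)),
                 tolerance = 1e-4)
  }
})

test_that("log-rank has power at hazard ratio 1.5 and holds size at 1", {
  run_once <- function(lhr, seed) {
    cfg <- simulation_config(c(g1 = 600L, g2 = 600L), 10L, hazard = 0.08,
                             frailty_sd = 0, group_log_hr = c(g1 = lhr, g2 = 0),
                             seed = seed)
    sim <- simulate_survey(cfg)
    sd <- build_survival_data(sim$responses, sim$covariates)
    logrank_test(sd, "group")$p_value < 0.05
  }
  alt <- mean(vapply(1:60, function(r) run_once(log(1.5), 3000 + r), logical(1)))
  nul <- mean(vapply(1:60, function(r) run_once(0, 6000 + r), logical(1)))
  expect_gt(alt, 0.8)
  expect_lt(nul, 0.15)
})

test_that("Cox recovers a known hazard ratio and nulls a noise covariate", {
  cfg <- simulation_config(2000L, 10L, hazard = 0.07, frailty_sd = 0,
                           covariates = list(
                             list(name = "exposed", levels = c("no", "yes"),
                                  probs = c(0.5, 0.5), log_hr = c(0, log(2))),
                             list(name = "noise", mean = 0, sd = 1, log_hr = 0)),
                           seed = 101L)
  sim <- simulate_survey(cfg)
  sd <- build_survival_data(sim$responses, sim$covariates)
  cf <- cox_fit(sd, c("exposed", "noise"))
  # discrete-time logit hazard shift of log(2) is approximately a
  # proportional-hazards log HR of log(2) at small baseline hazard
  expect_lt(abs(cf$coefficients["exposedyes"] - log(2)),
            3 * cf$se["exposedyes"] + 0.05)
  expect_lt(abs(cf$coefficients["noise"]), 3 * cf$se["noise"])
  expect_true(cf$converged)
})

test_that("without ties Efron and Breslow coincide with a brute-force optimum", {
  sd <- surv_df(c(2, 3, 5, 8), c(1, 1, 1, 0), x = c(1, 0, 1, 0))
  fe <- cox_fit(sd, "x")
  fb <- cox_fit(sd, "x", ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-8)
  x <- matrix(sd$x, ncol = 1)
  brute <- stats::optimize(function(b) -brute_cox_pll(b, sd$time, sd$event, x),
                           c(-10, 10), tol = 1e-10)
  expect_equal(unname(fe$coefficients), brute$minimum, tolerance = 1e-5)
  expect_equal(fe$loglik[["fitted"]], -brute$objective, tolerance = 1e-8)
})

test_that("Cox score test at zero equals the log-rank statistic without ties", {
  set.seed(8)
  time <- sample(2:200, 30)  # distinct times, no ties
  sd <- surv_df(time, rbinom(30, 1, 0.8), b = rbinom(30, 1, 0.5))
  if (length(unique(sd$b)) < 2) sd$b[1:2] <- c(0, 1)
  cf <- cox_fit(sd, "b")
  lr <- logrank_test(transform(sd, g = b), "g")
  expect_equal(cf$score_test$statistic, lr$statistic, tolerance = 1e-6)
})

test_that("coefficients rescale exactly under affine covariate transforms", {
  set.seed(44)
  sd <- surv_df(sample(2:8, 400, TRUE), rbinom(400, 1, 0.7), x = rnorm(400))
  f1 <- cox_fit(sd, "x")
  sd$x <- 10 * sd$x + 3
  f2 <- cox_fit(sd, "x")
  expect_equal(unname(f1$coefficients), 10 * unname(f2$coefficients),
               tolerance = 1e-6)
  expect_equal(unname(f1$se), 10 * unname(f2$se), tolerance = 1e-6)
})

test_that("rank-deficient designs and single groups raise classed errors", {
  sd <- surv_df(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 0),
                x = c(1, 2, 3, 4, 5, 6))
  sd$x2 <- 2 * sd$x
  expect_error(cox_fit(sd, c("x", "x2")), class = "attrition_data_error")
  expect_error(logrank_test(transform(sd, g = "one"), "g"),
               class = "attrition_config_error")
  expect_error(logrank_test(sd, "missing"), class = "attrition_config_error")
  expect_error(cox_fit(sd[1:3, ], c("x", "x2")), class = "attrition_data_error")
})

test_that("proportional-hazards check reports a p-value per covariate", {
  cfg <- simulation_config(800L, 8L, hazard = 0.1, frailty_sd = 0,
                           covariates = list(
                             list(name = "g", levels = c("a", "b"),
                                  probs = c(0.5, 0.5), log_hr = c(0, 0.5))),
                           seed = 71L)
  sim <- simulate_survey(cfg)
  sd <- build_survival_data(sim$responses, sim$covariates)
  cf <- cox_fit(sd, "g")
  expect_true(is.finite(cf$ph_check["gb"]))
  expect_true(cf$ph_check["gb"] >= 0 && cf$ph_check["gb"] <= 1)
})

test_that("screen-then-adjust reproduces the screening workflow", {
  cfg <- simulation_config(1500L, 10L, hazard = 0.08, frailty_sd = 0,
                           covariates = list(
                             list(name = "gender", levels = c("F", "M"),
                                  probs = c(0.5, 0.5), log_hr = c(0.35, 0)),
                             list(name = "phase", levels = c("p1", "p2"),
                                  probs = c(0.5, 0.5), log_hr = c(0, 0.4)),
                             list(name = "noise", mean = 0, sd = 1, log_hr = 0)),
                           seed = 300L)
  sim <- simulate_survey(cfg)
  sd <- build_survival_data(sim$responses, sim$covariates)
  res <- screen_then_adjust(sd, exposure = "gender",
                            candidates = c("phase", "noise"))
  expect_true("phase" %in% res$selected)
  expect_false("noise" %in% res$selected)
  expect_true(any(grepl("gender", names(res$adjusted$coefficients))))
  expect_true(any(grepl(":", names(res$adjusted$coefficients))))
})

test_that("survival CSV exports include step-function coordinates", {
  dir <- withr::local_tempdir()
  sd <- surv_df(c(2, 3, 4, 4, 5, 6), rep(1L, 6), g = rep(c("A", "B"), each = 3))
  lr <- logrank_test(sd, "g")
  p <- file.path(dir, "km.csv")
  write_survival_csv(lr, p)
  back <- utils::read.csv(p)
  expect_true(all(c("group", "time", "surv") %in% colnames(back)))
  # product-limit values for group A: 1, 2/3, 1/3, 0
  expect_equal(back$surv[back$group == "A"], c(1, 2/3, 1/3, 0),
               tolerance = 1e-10)
})
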