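# Pairwise random-intercept logistic model and delta-method transform.

test_that("delta method reproduces the hand-worked gradient and SE", {
  d <- delta_method_difference(0, 0, diag(2))
  expect_equal(d$diff, 0)
  expect_equal(d$gradient, c(0, -0.25))
  expect_equal(d$se, 0.25)
  expect_equal(d$ci, c(-1, 1) * stats::qnorm(0.975) * 0.25)
  # beta1 = 0 gives a zero difference exactly, for any intercept
  for (b0 in c(-3, -0.4, 0.7, 2)) {
    expect_identical(delta_method_difference(b0, 0, diag(2) * 0.3)$diff, 0)
  }
  expect_error(delta_method_difference(0, 0, matrix(c(1, 2, 2, 1), 2)),
               class = "attrition_numeric_error")
  expect_error(delta_method_difference(Inf, 0, diag(2)),
               class = "attrition_numeric_error")
})

test_that("logit-scale proportions transform to printed-precision differences", {
  # transform identities: p1 = plogis(b0), p2 = plogis(b0 + b1)
  p <- c(0.97, 0.76)
  b0 <- qlogis(p[1]); b1 <- qlogis(p[2]) - b0
  d <- delta_method_difference(b0, b1, diag(2) * 1e-6)
  expect_equal(round(d$diff, 2), 0.21)
  expect_equal(plogis(b0), p[1])
  expect_equal(plogis(b0 + b1), p[2])
})

test_that("quadrature log-likelihood matches dense-grid integration", {
  set.seed(10)
  for (r in 1:5) {
    n <- sample(50:200, 1)
    sp <- simulate_response_pair(n, runif(1, 0.3, 0.9), runif(1, 0.3, 0.9),
                                 sigma_u = runif(1, 0.2, 2), seed = 100 + r)
    th <- c(rnorm(1), rnorm(1), runif(1, 0.3, 2))
    llq <- pair_glmm_loglik(sp$y1, sp$y2, th[1], th[2], th[3])
    llg <- grid_pair_loglik(sp$y1, sp$y2, th[1], th[2], th[3])
    expect_lt(abs(llq - llg) / n, 1e-4)
  }
})

test_that("sigma fixed at 0 reduces to ordinary logistic estimates", {
  sp <- simulate_response_pair(400, 0.8, 0.6, sigma_u = 1, seed = 3)
  f <- fit_response_pair(sp$y1, sp$y2, sigma_fixed = 0)
  expect_equal(f$p1, mean(sp$y1), tolerance = 1e-8)
  expect_equal(f$p2, mean(sp$y2), tolerance = 1e-8)
  expect_identical(f$sigma_u, 0)
})

test_that("null pair with no frailty is recovered near the boundary", {
  sp <- simulate_response_pair(2000, 0.5, 0.5, sigma_u = 0, seed = 17)
  f <- fit_response_pair(sp$y1, sp$y2)
  expect_true(f$converged)
  # diff within 3 SE of 0
  expect_lt(abs(f$diff), 3 * f$se_diff)
  expect_lt(f$sigma_u, 0.3)  # true value 0; estimate near the boundary
})

test_that("parameters are recovered within 3 SE, matching a grid-integration oracle fit", {
  sp <- simulate_response_pair(5000, 0.9, 0.7, sigma_u = 1, seed = 42)
  f <- fit_response_pair(sp$y1, sp$y2)
  g <- grid_pair_fit(sp$y1, sp$y2)
  # quadrature and grid-oracle optima agree
  expect_equal(f$beta0, g$beta0, tolerance = 1e-3)
  expect_equal(f$beta1, g$beta1, tolerance = 1e-3)
  expect_equal(f$sigma_u, g$sigma, tolerance = 5e-3)
  # and recover the generating values within 3 SE
  se_b0 <- sqrt(f$cov_beta[1, 1]); se_b1 <- sqrt(f$cov_beta[2, 2])
  expect_lt(abs(f$beta0 - qlogis(0.9)), 3 * se_b0)
  expect_lt(abs(f$beta1 - (qlogis(0.7) - qlogis(0.9))), 3 * se_b1)
  expect_lt(abs(f$sigma_u - 1), 0.2)
})

test_that("an item answered by everyone triggers a separation warning, not a failure", {
  set.seed(5)
  y1 <- rep(1L, 800)
  y2 <- rbinom(800, 1, 0.97)
  f <- fit_response_pair(y1, y2)
  expect_true(f$separation_warning)
  expect_equal(f$p1, 1, tolerance = 1e-4)
  # unstable wide interval is reported as-is (not clipped to [-1, 1])
  expect_true(is.finite(f$se_diff) && f$se_diff > 0)
  expect_gt(f$p_value, 0.05)
})

test_that("firth penalty pulls a separated estimate into the interior", {
  y1 <- rep(1L, 300)
  y2 <- rbinom(300, 1, 0.95)
  ml <- fit_response_pair(y1, y2)
  fi <- fit_response_pair(y1, y2, firth = TRUE)
  expect_lt(abs(fi$beta0), abs(ml$beta0))
})

test_that("results are invariant to subject reordering", {
  sp <- simulate_response_pair(500, 0.8, 0.6, sigma_u = 1, seed = 9)
  f1 <- fit_response_pair(sp$y1, sp$y2)
  perm <- sample(500)
  f2 <- fit_response_pair(sp$y1[perm], sp$y2[perm])
  expect_identical(f1$diff, f2$diff)
  expect_identical(f1$se_diff, f2$se_diff)
  expect_identical(f1$ci, f2$ci)
})

test_that("population-averaged proportions track the raw marginals", {
  sp <- simulate_response_pair(4000, 0.85, 0.65, sigma_u = 1.5, seed = 12)
  f <- fit_response_pair(sp$y1, sp$y2)
  m <- marginal_pair_proportions(f)
  expect_equal(unname(m["p1"]), mean(sp$y1), tolerance = 0.03)
  expect_equal(unname(m["p2"]), mean(sp$y2), tolerance = 0.03)
  # conditional (u = 0) proportions are more extreme than marginal ones
  expect_gt(f$p1, m["p1"])
})

test_that("scan flags no pair on an attrition-free survey", {
  rm <- response_matrix(matrix(1L, 60, 3))
  sc <- sequential_attrition_scan(rm)
  expect_equal(nrow(sc$table), 2L)
  expect_false(any(sc$table$significant))
  expect_true(all(abs(sc$table$diff) < 1e-6))
})

test_that("scan flags the engineered cliff pair as the dominant attrition point", {
  sim <- simulate_survey(sim_preset("cliff", seed = 31))
  sc <- sequential_attrition_scan(sim$responses)
  expect_equal(nrow(sc$table), 5L)
  expect_true(sc$table$significant[2])
  expect_equal(which.min(sc$table$p_value), 2L)
})

test_that("scan survives a failing pair and validates its inputs", {
  rm <- response_matrix(rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1)))
  expect_error(sequential_attrition_scan(rm, alpha = 2),
               class = "attrition_config_error")
  expect_error(fit_pairwise_glmm(rm, 2, 2), class = "attrition_config_error")
  expect_message(fit_pairwise_glmm(rm, 1, 3), "non-sequential")
})

test_that("multiplicity adjustment is off by default but available", {
  sim <- simulate_survey(sim_preset("cliff", seed = 77))
  none <- sequential_attrition_scan(sim$responses)
  bonf <- sequential_attrition_scan(sim$responses, adjust = "bonferroni")
  expect_identical(none$table$p_value, none$table$p_adjusted)
  expect_true(all(bonf$table$p_adjusted >= bonf$table$p_value))
})

test_that("scan CSV mirrors the results-table layout", {
  dir <- withr::local_tempdir()
  sim <- simulate_survey(simulation_config(200L, 4L, hazard = 0.2,
                                           frailty_sd = 1, seed = 2L))
  sc <- sequential_attrition_scan(sim$responses)
  p <- file.path(dir, "scan.csv")
  write_scan_csv(sc, p)
  back <- utils::read.csv(p)
  expect_true(all(c("pair", "p1", "p2", "diff", "se", "ci_low", "ci_high",
                    "p_value") %in% colnames(back)))
  expect_equal(nrow(back), 3L)
})
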