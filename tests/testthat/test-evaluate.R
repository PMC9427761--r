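test_that("AUC equals concordant-pair counting and behaves at the extremes", {
  scores <- c(0.1, 0.3, 0.35, 0.6, 0.7, 0.9)
  labels <- c(0, 0, 1, 0, 1, 1)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, brute_auc(scores, labels))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  perf <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perf$auc, 1)

  # ties get half credit
  tied <- roc_auc(c(1, 1, 2), c(0, 1, 1))
  expect_equal(tied$auc, brute_auc(c(1, 1, 2), c(0, 1, 1)))

  set.seed(51)
  s <- rnorm(10000)
  l <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.02)

  expect_error(roc_auc(1:5, rep(1, 5)), class = "validation_error")
})

test_that("AUC antisymmetry: flipping the score flips the AUC", {
  set.seed(52)
  s <- rnorm(200)
  l <- rbinom(200, 1, 0.4)
  expect_equal(roc_auc(s, l)$auc + roc_auc(-s, l)$auc, 1)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # times 1, 2+, 3, 4+, 5: S(3) = (4/5)(2/3) = 8/15
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  s3 <- km$surv[km$time == 3]
  expect_equal(s3, (4 / 5) * (2 / 3))
  s5 <- km$surv[km$time == 5]
  expect_equal(s5, 0)

  # without censoring the estimator reduces to 1 - ECDF at event times
  set.seed(53)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  expect_equal(km2$surv, 1 - ecdf(t)(km2$time))
})

test_that("log-rank test and Cox score test agree for one binary covariate", {
  set.seed(54)
  g <- rep(0:1, each = 30)
  t <- rexp(60, rate = ifelse(g == 1, 1.8, 1)) + 0.01 * seq_len(60) # no ties
  e <- rbinom(60, 1, 0.8)
  lr <- logrank_test(t, e, g)
  cox <- survival::coxph(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, unname(summary(cox)$sctest["test"]),
               tolerance = 1e-6)
  expect_error(logrank_test(t, rep(0, 60), g), class = "validation_error")
})

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  # 8 subjects, distinct times, single binary covariate
  t8 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e8 <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x8 <- c(1, 1, 0, 1, 0, 1, 0, 0)
  df <- data.frame(time = t8, event = e8, x = x8)
  fit <- cox_fit(df, "time", "event", "x", entry_p = 1)
  beta_hat <- log(fit$multivariate$hr[1])
  beta_brute <- stats::optimize(function(b)
    brute_cox_loglik(b, x8, t8, e8), c(-5, 5), maximum = TRUE)$maximum
  expect_equal(beta_hat, beta_brute, tolerance = 1e-4)
})

test_that("Cox estimates are invariant to duplicating every subject", {
  set.seed(55)
  n <- 60
  df <- data.frame(time = rexp(n) + seq_len(n) * 1e-4,
                   event = rbinom(n, 1, 0.7),
                   x = rnorm(n))
  f1 <- cox_fit(df, "time", "event", "x", entry_p = 1)
  f2 <- cox_fit(rbind(df, df), "time", "event", "x", entry_p = 1)
  # identical up to the iterative fitter's stopping tolerance
  expect_equal(f1$multivariate$hr, f2$multivariate$hr, tolerance = 1e-3)
})

test_that("univariate screening feeds the multivariate model", {
  set.seed(56)
  n <- 150
  x1 <- rnorm(n)
  x2 <- rnorm(n)  # pure noise
  t <- rexp(n, exp(0.9 * x1)) + seq_len(n) * 1e-5
  df <- data.frame(time = t, event = rep(1, n), x1 = x1, x2 = x2)
  fit <- cox_fit(df, "time", "event", c("x1", "x2"))
  expect_true("x1" %in% fit$entered)
  expect_equal(nrow(fit$univariate), 2)
  expect_true(fit$c_index > 0.5)
})

test_that("C-index equals brute-force pair enumeration; extremes behave", {
  set.seed(57)
  n <- 40
  t <- rexp(n) + seq_len(n) * 1e-5
  e <- rbinom(n, 1, 0.7)
  lp <- rnorm(n)
  ci <- c_index(lp, t, e, n_boot = 50, seed = 1)
  expect_equal(ci$c_index, brute_c_index(lp, t, e), tolerance = 1e-12)
  expect_true(ci$ci_low <= ci$c_index && ci$c_index <= ci$ci_high)

  perfect <- c_index(-t, t, rep(1, n), n_boot = 10, seed = 1)
  expect_equal(perfect$c_index, 1)

  set.seed(58)
  big <- c_index(rnorm(2000), rexp(2000), rep(1, 2000), n_boot = 10, seed = 1)
  expect_lt(abs(big$c_index - 0.5), 0.05)
})

test_that("Cox linear predictor is at least as concordant as single covariates", {
  set.seed(59)
  wins <- vapply(1:20, function(r) {
    n <- 150
    x1 <- rnorm(n); x2 <- rnorm(n)
    t <- rexp(n, exp(0.7 * x1 + 0.5 * x2)) + seq_len(n) * 1e-6
    df <- data.frame(time = t, event = rep(1, n), x1 = x1, x2 = x2)
    fit <- cox_fit(df, "time", "event", c("x1", "x2"), entry_p = 1)
    lp <- predict(fit$model)
    cm <- c_index(lp, t, df$event, n_boot = 2, seed = 1)$c_index
    c1 <- c_index(x1, t, df$event, n_boot = 2, seed = 1)$c_index
    c2 <- c_index(x2, t, df$event, n_boot = 2, seed = 1)$c_index
    cm >= max(c1, c2)
  }, logical(1))
  expect_gt(mean(wins), 0.8)
})

test_that("nomogram scoring: reference zero, extreme 100, linear in RS", {
  set.seed(60)
  n <- 200
  rs <- rnorm(n)
  stage <- factor(sample(c("I", "II", "III"), n, replace = TRUE))
  t <- rexp(n, exp(0.8 * rs + 0.4 * (stage == "III"))) + seq_len(n) * 1e-6
  df <- data.frame(time = t, event = rep(1, n), rs = rs, stage = stage)
  fit <- cox_fit(df, "time", "event", c("rs", "stage"), entry_p = 1)

  ref <- data.frame(rs = min(rs) * sign(coef(fit$model)["rs"] > 0) +
                      max(rs) * sign(coef(fit$model)["rs"] < 0),
                    stage = factor("I", levels = levels(stage)))
  # reference = covariate values minimizing each contribution
  rs_ref <- if (coef(fit$model)["rs"] > 0) min(rs) else max(rs)
  ref <- data.frame(rs = rs_ref, stage = factor("I", levels = levels(stage)))
  ns_ref <- nomogram_score(fit, ref)
  expect_equal(ns_ref$points, 0, tolerance = 1e-8)

  rs_max <- if (coef(fit$model)["rs"] > 0) max(rs) else min(rs)
  extreme <- data.frame(rs = rs_max, stage = factor("I",
                                                    levels = levels(stage)))
  # rs has by far the widest effect range here, so it carries the 100 points
  ns_ext <- nomogram_score(fit, extreme)
  expect_equal(ns_ext$points, 100, tolerance = 1e-6)

  two <- data.frame(rs = c(0, 1), stage = factor(c("II", "II"),
                                                 levels = levels(stage)))
  ns2 <- nomogram_score(fit, two)
  expect_equal(diff(ns2$lp), unname(coef(fit$model)["rs"]))
  expect_gt(stats::cor(ns2$points, ns2$lp), 0.999)

  expect_error(nomogram_score(fit, data.frame(rs = 1)),
               class = "schema_error")
})

test_that("response tables report OR / disease-control / PD rates", {
  resp <- c(rep("PD", 9), rep("CR", 3), rep("PR", 11), rep("SD", 2),
            rep("PD", 14), rep("PR", 2), rep("SD", 5))
  grp <- c(rep("RS-Low", 23), rep("RS-High", 23))
  rs <- c(rnorm(23, -0.4, 0.2), rnorm(23, 0.3, 0.2))
  out <- response_table(resp, grp, rs)
  low <- out$rates[out$rates$group == "RS-Low", ]
  # 14 objective responses out of 23
  expect_equal(low$objective_response, 100 * 14 / 23, tolerance = 1e-9)
  expect_equal(round(low$objective_response, 1), 60.9)
  expect_true(!is.null(out$chisq$p.value))

  all_pd <- response_table(rep("PD", 10), rep(c("RS-Low", "RS-High"), 5),
                           rnorm(10))
  expect_true(all(all_pd$rates$objective_response == 0))

  set.seed(61)
  same <- rnorm(20, 0, 1)
  out2 <- response_table(rep(c("PD", "SD"), each = 20), rep("RS-Low", 40),
                         c(same, same))
  tt <- out2$rs_tests[out2$rs_tests$group1 == "PD" &
                        out2$rs_tests$group2 == "SD", ]
  expect_gt(tt$p, 0.99)

  expect_error(response_table(c("CR", NA), c("a", "b"), c(1, 2)),
               class = "validation_error")
})
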