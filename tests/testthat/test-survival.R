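test_that("product-limit estimate matches hand computation", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km@surv, c(2/3, 1/3, 0))
  # tie rule: events precede censorings at the same time
  km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(survivalAt(km2, 1)$prob, 2/3)
  expect_equal(survivalAt(km2, 3)$prob, 0)
  # all censored: S identically 1
  km3 <- kmEstimate(c(5, 8), c(0, 0))
  expect_equal(km3@surv, c(1, 1))
  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM equals the empirical survival function without censoring", {
  withr::with_seed(41, {
    for (i in 1:10) {
      t <- round(rexp(sample(5:60, 1), 0.05), 2) + 0.01
      km <- kmEstimate(t, rep(1, length(t)))
      for (h in c(0, quantile(t, c(0.2, 0.5, 0.9)), max(t) + 1))
        expect_equal(survivalAt(km, h)$prob, mean(t > h))
    }
  })
})

test_that("KM and Greenwood SE agree with the survival package", {
  skip_if_not_installed("survival")
  withr::with_seed(43, {
    t <- rexp(80, 0.02)
    e <- rbinom(80, 1, 0.7)
    km <- kmEstimate(t, e)
    fit <- survival::survfit(survival::Surv(t, e) ~ 1)
    expect_equal(km@time, fit$time)
    expect_equal(km@surv, fit$surv, tolerance = 1e-12)
    expect_equal(km@nRisk, fit$n.risk)
    expect_equal(km@nEvent, fit$n.event)
    ok <- fit$surv > 0  # survfit reports NaN SE where S reaches 0
    expect_equal(km@se[ok], (fit$std.err * fit$surv)[ok],
                 tolerance = 1e-8)
  })
})

test_that("survival lookup is a right-continuous step function", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(survivalAt(km, 0)$prob, 1)
  expect_equal(survivalAt(km, 2.5)$prob, 1/3)
  expect_equal(survivalAt(km, 2)$prob, 1/3)  # right-continuity at a jump
  out <- survivalAt(km, 10)
  expect_true(out$extrapolated)
  expect_equal(out$prob, 0)
})

test_that("five-year survival of an exponential cohort with 60-month median is one half", {
  coh <- simSurvivalCohort(97, n = 2000L, hazardRatio = 1,
                           censorFraction = 0)
  km <- kmEstimate(coh$cohort$time, coh$cohort$event)
  expect_lt(abs(survivalAt(km, 60)$prob - 0.5), 0.03)
})

test_that("log-rank is symmetric, null on identical groups, and matches survdiff", {
  t <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  g <- rep(c("A", "B"), each = 5)
  # identical groups: statistic 0, p 1
  same <- logrankTest(c(t, t), c(e, e), rep(c("A", "B"), each = 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # label swap leaves the statistic unchanged
  lr <- logrankTest(t, e, g)
  lr2 <- logrankTest(t, e, rev(g))
  expect_equal(lr$statistic,
               logrankTest(t, e, ifelse(g == "A", "B", "A"))$statistic)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-12)
  expect_equal(lr$p.value, 1 - pchisq(sd$chisq, 1), tolerance = 1e-12)
  withr::with_seed(47, {
    for (i in 1:5) {
      n <- sample(20:60, 1)
      tt <- rexp(n, 0.05)
      ee <- rbinom(n, 1, 0.8)
      gg <- sample(c("A", "B"), n, replace = TRUE)
      if (length(unique(gg)) < 2 || sum(ee) == 0) next
      mine <- logrankTest(tt, ee, gg)
      ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
      expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
    }
  })
})

test_that("chi-square p agrees with the exhaustive permutation oracle on small sets", {
  fixtures <- list(
    list(t = c(1, 2, 3, 4, 5, 6, 7, 8), e = rep(1, 8),
         g = rep(c("A", "B"), 4)),
    list(t = c(2, 4, 6, 8, 1, 3, 5, 7), e = c(1, 1, 0, 1, 1, 0, 1, 1),
         g = rep(c("A", "B"), each = 4)),
    list(t = c(1, 1, 2, 3, 5, 8, 13, 21, 4, 6),
         e = c(1, 0, 1, 1, 1, 0, 1, 1, 1, 1),
         g = rep(c("A", "B"), each = 5)))
  for (f in fixtures) {
    p_chisq <- logrankTest(f$t, f$e, f$g)$p.value
    p_perm <- perm_logrank_p(f$t, f$e, f$g)
    expect_lt(abs(p_chisq - p_perm), 0.25)  # coarse agreement at n = 8-10
    # the seeded permutation option approximates the exhaustive value
    p_mc <- logrankTest(f$t, f$e, f$g, nPermutations = 2000,
                        seed = 7)$p.permutation
    expect_lt(abs(p_mc - p_perm), 0.05)
  }
})

test_that("mean split dichotomises at the arithmetic mean", {
  rec <- data.frame(time = c(10, 20, 30), event = c(1, 1, 1),
                    covariate = c(0.1, 0.2, 0.6))
  cut <- splitByMean(rec)
  expect_equal(cutoffThreshold(cut), 0.3)
  expect_equal(cut@nLow, 2L)
  expect_equal(cut@nHigh, 1L)
  expect_error(splitByMean(data.frame(time = 1:3, event = c(1, 1, 1),
                                      covariate = rep(0.5, 3))),
               "degenerate")
})

test_that("mean split separates the modes of a bimodal methylation cohort", {
  coh <- simSurvivalCohort(53, n = 400L, cutoff = 0.4)
  cut <- splitByMean(coh$cohort)
  splitHigh <- coh$cohort$covariate >= cutoffThreshold(cut)
  # the mean falls between the two Beta modes, so the mean split
  # recovers the latent mixture component for nearly all subjects
  expect_gt(mean(splitHigh == coh$truth$mode_high), 0.95)
})

test_that("best-cutoff scan recovers a planted step at 0.30", {
  coh <- simSurvivalCohort(1, n = 500L, cutoff = 0.30, hazardRatio = 3)
  cut <- bestCutoffScan(coh$cohort)
  expect_lt(abs(cutoffThreshold(cut) - 0.30), 0.05)
  expect_equal(cut@method, "best_cutoff")
  expect_gt(cut@nTested, 10L)
})

test_that("best-cutoff scan handles two-point covariates and degenerate input", {
  rec <- data.frame(time = c(rexp(10, 0.1), rexp(10, 0.4)),
                    event = 1,
                    covariate = rep(c(0, 1), each = 10))
  cut <- suppressWarnings(bestCutoffScan(rec))
  expect_equal(cutoffThreshold(cut), 1)  # the only split: <1 vs >=1
  expect_error(suppressWarnings(
    bestCutoffScan(data.frame(time = 1:10, event = 1, covariate = 0.3))),
    "degenerate")
})

test_that("minimum-p selection on null cohorts inflates the false-positive rate", {
  hits <- withr::with_seed(59, {
    vapply(1:60, function(i) {
      coh <- simSurvivalCohort(sample.int(1e6, 1), n = 60L,
                               hazardRatio = 1, censorFraction = 0.2)
      cutoffP(bestCutoffScan(coh$cohort)) < 0.05
    }, logical(1))
  })
  # far above the nominal 5%: this is the selection bias the
  # unadjusted-p warning refers to
  expect_gt(mean(hits), 0.15)
})

test_that("low-methylation groups outlive high groups under a deleterious HR", {
  wins <- vapply(1:10, function(i) {
    coh <- simSurvivalCohort(100 + i, n = 500L, cutoff = 0.30,
                             hazardRatio = 2)
    cv <- kmByGroup(coh$cohort, 0.30)
    survivalAt(cv$low, 60)$prob > survivalAt(cv$high, 60)$prob
  }, logical(1))
  expect_true(all(wins))
})
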