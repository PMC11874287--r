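test_that("Kaplan-Meier estimate matches the hand-computed product-limit table", {
  # 6 records with censoring: events at 1, 3, 4, 4; censored at 2 and 5
  d <- data.frame(time = c(1, 2, 3, 4, 4, 5),
                  event = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  km <- km_curve(d)
  oracle <- km_oracle(d$time, d$event)
  expect_equal(km$time[km$n_event > 0], oracle$time)
  expect_equal(km$surv[km$n_event > 0], oracle$surv, tolerance = 1e-12)
  # S(1)=5/6, S(3)=5/8, S(4)=5/24
  expect_equal(oracle$surv, c(5 / 6, 5 / 8, 5 / 24), tolerance = 1e-12)
  expect_equal(km$median, 4)

  # n=2 with events at 1 and 2
  km2 <- km_curve(data.frame(time = c(1, 2), event = TRUE))
  expect_equal(km2$survfun(1.5), 0.5)
  expect_equal(km2$survfun(2.5), 0)
  expect_equal(km2$median, 1)

  # no events: flat at 1, median never reached
  km3 <- km_curve(data.frame(time = c(3, 9), event = FALSE))
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median))

  expect_error(km_curve(data.frame(time = c(1, -2), event = TRUE)),
               "positive")
})

test_that("KM curves start at 1, never increase, and are right-continuous", {
  set.seed(121)
  for (i in 1:10) {
    d <- data.frame(time = rexp(30, 0.2) + 0.01,
                    event = runif(30) < 0.7)
    km <- km_curve(d)
    expect_equal(km$survfun(0), 1)
    expect_true(all(diff(km$surv) <= 1e-12))
    for (t in km$time)  # right-continuity at jumps
      expect_equal(km$survfun(t), km$surv[km$time == t])
  }
})

test_that("log-rank statistic equals the O-E / V oracle", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                            FALSE),
                  group = rep(c("a", "b"), each = 4))
  lr <- logrank_test(d)
  expect_equal(lr$statistic, logrank_oracle(d$time, d$event, d$group),
               tolerance = 1e-9)

  set.seed(131)
  for (i in 1:10) {
    d <- data.frame(time = round(rexp(40, 0.3) + 0.1, 1),
                    event = runif(40) < 0.8,
                    group = sample(c("a", "b"), 40, TRUE))
    if (sum(d$event) == 0 || length(unique(d$group)) < 2) next
    expect_equal(logrank_test(d)$statistic,
                 logrank_oracle(d$time, d$event, d$group),
                 tolerance = 1e-9)
  }

  # identical groups: statistic 0, p ~ 1
  dup <- data.frame(time = rep(c(1, 2, 3), 2), event = TRUE,
                    group = rep(c("a", "b"), each = 3))
  lr0 <- logrank_test(dup)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-9)

  # no events anywhere: defined as statistic 0, p = 1
  none <- data.frame(time = 1:4, event = FALSE,
                     group = rep(c("a", "b"), 2))
  expect_equal(logrank_test(none)$statistic, 0)
  expect_equal(logrank_test(none)$p_value, 1)
})

test_that("trend test is symmetric under order reversal and needs 3 groups", {
  set.seed(141)
  g <- list(a = data.frame(time = rexp(20, log(2) / 4) + 0.01,
                           event = runif(20) < 0.8),
            b = data.frame(time = rexp(20, log(2) / 6) + 0.01,
                           event = runif(20) < 0.8),
            c = data.frame(time = rexp(20, log(2) / 9) + 0.01,
                           event = runif(20) < 0.8))
  fwd <- logrank_trend(g)
  rev <- logrank_trend(g[3:1])
  expect_equal(fwd$statistic, rev$statistic, tolerance = 1e-9)
  expect_identical(fwd$direction, -rev$direction)

  # three identical groups: statistic 0
  same <- data.frame(time = c(1, 2, 3), event = TRUE)
  expect_equal(logrank_trend(list(a = same, b = same, c = same))$statistic,
               0, tolerance = 1e-12)

  expect_error(logrank_trend(g[1:2]), "logrank_test")
})

test_that("trend test beats the plain log-rank on ordered hazards", {
  # clearly ordered alternative (medians doubling group to group): the
  # 1-df trend statistic concentrates its power along the ordering while
  # the 2-df log-rank spreads it over every contrast
  set.seed(151)
  wins <- 0
  n_rep <- 300
  meds <- c(3, 6, 12)
  for (r in 1:n_rep) {
    d <- do.call(rbind, lapply(seq_along(meds), function(i) {
      data.frame(time = rexp(40, log(2) / meds[i]) + 1e-6,
                 event = runif(40) < 0.8,
                 group = factor(c("depleted", "compartmentalised",
                                  "enriched")[i],
                                levels = c("depleted", "compartmentalised",
                                           "enriched")))
    }))
    if (logrank_trend(d)$p_value < logrank_test(d)$p_value)
      wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("marker dichotomisation follows the median and fixed-cutoff rules", {
  v <- setNames(c(1, 2, 3, 4), paste0("P", 1:4))
  dm <- dichotomise_marker(v, "median")
  expect_identical(dm$group, c("low", "low", "high", "high"))

  fx <- dichotomise_marker(setNames(c(150, 250), c("P1", "P2")), "fixed",
                           threshold = 200)
  expect_identical(fx$group, c("low", "high"))

  # exactly at a fixed threshold: low, flagged
  at <- dichotomise_marker(setNames(c(200, 250), c("P1", "P2")), "fixed",
                           threshold = 200)
  expect_identical(at$group[1], "low")
  expect_true(at$flagged[1])

  expect_error(dichotomise_marker(setNames(c(2, 2, 2), paste0("P", 1:3)),
                                  "median"), "degenerate")
})

test_that("horizon ROC handles exclusion, perfect and tied markers", {
  rec <- data.frame(patient_id = paste0("P", 1:4),
                    time = c(2, 3, 10, 12), event = TRUE)
  # markers increasing with PFS: perfect separation at 8 months
  r <- roc_auc_pfs(setNames(c(1, 2, 3, 4), rec$patient_id), rec,
                   horizon = 8)
  expect_equal(r$auc, 1.0)
  # interleaved outcome pattern: rank-sum AUC 0.75
  r2 <- roc_auc_pfs(setNames(c(1, 2, 3, 4), rec$patient_id),
                    data.frame(patient_id = paste0("P", 1:4),
                               time = c(2, 10, 3, 12), event = TRUE),
                    horizon = 8)
  expect_equal(r2$auc, 0.75)

  # censored before the horizon: excluded and counted
  rec3 <- data.frame(patient_id = paste0("P", 1:6),
                     time = c(2, 3, 5, 10, 12, 11),
                     event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  r3 <- roc_auc_pfs(setNames(c(1, 2, 3, 4, 5, 6), rec3$patient_id), rec3,
                    horizon = 8)
  expect_equal(r3$n_excluded, 1L)
  expect_equal(r3$n_reached + r3$n_progressed, 5L)

  # a marker independent of outcome hovers near AUC 0.5
  set.seed(161)
  n <- 400
  recn <- data.frame(patient_id = paste0("P", 1:n),
                     time = rexp(n, log(2) / 8) + 1e-6, event = TRUE)
  rn <- roc_auc_pfs(setNames(runif(n), recn$patient_id), recn, horizon = 8)
  expect_lt(abs(rn$auc - 0.5), 0.08)

  expect_error(roc_auc_pfs(setNames(c(1, 2), c("P1", "P2")),
                           data.frame(patient_id = c("P1", "P2"),
                                      time = c(2, 10), event = TRUE),
                           horizon = 8),
               "AUC undefined")
})

test_that("the Bonferroni helper scales p values by the family size", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.02, n = 3), 0.06)
})
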