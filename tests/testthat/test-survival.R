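test_that("the product-limit estimate handles the textbook cases", {
  allc <- kaplan_meier(tibble::tibble(time = c(1, 2, 3), status = 0))
  expect_equal(nrow(allc$curve), 0)  # no events: S stays 1 everywhere
  expect_equal(km_at(allc, c(0.5, 5)), c(1, 1))
  # no censoring reduces to the empirical survival function
  d <- tibble::tibble(time = c(1, 2, 3, 4), status = 1)
  km <- kaplan_meier(d)
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  # events at 1 and 3, censoring at 2: hand product-limit computation
  km2 <- kaplan_meier(tibble::tibble(time = c(1, 2, 3), status = c(1, 0, 1)))
  expect_equal(km2$curve$surv, c(2 / 3, 0))
  expect_error(kaplan_meier(tibble::tibble(time = -1, status = 1)),
               "negative")
})

test_that("Kaplan-Meier and Greenwood SE agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(14)
  d <- tibble::tibble(time = round(rexp(120), 2) + 0.01,
                      status = rbinom(120, 1, 0.6),
                      group = rep(c("a", "b"), 60))
  km <- kaplan_meier(d, group = "group")
  for (g in c("a", "b")) {
    sf <- survival::survfit(survival::Surv(time, status) ~ 1,
                            data = d[d$group == g, ])
    i <- sf$n.event > 0
    cv <- km$curve[km$curve$group == g, ]
    expect_equal(cv$surv, sf$surv[i], tolerance = 1e-12)
    se_ref <- (sf$std.err * sf$surv)[i]
    ok <- is.finite(se_ref)  # survfit reports NaN once S reaches 0
    expect_equal(cv$se[ok], se_ref[ok], tolerance = 1e-12)
  }
})

test_that("the log-rank test matches the single-time hand formula and survdiff", {
  # one event in group a at t = 1 with one subject at risk per group
  d1 <- tibble::tibble(time = c(1, 2), status = c(1, 0), group = c("a", "b"))
  lr1 <- logrank_test(d1)
  expect_equal(lr1$statistic, 1.0)
  expect_equal(unname(lr1$table$observed[1] - lr1$table$expected[1]), 0.5)
  # identical groups give statistic 0, p = 1
  d2 <- tibble::tibble(time = rep(c(1, 2, 3), 2),
                       status = rep(c(1, 0, 1), 2),
                       group = rep(c("a", "b"), each = 3))
  lr2 <- logrank_test(d2)
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)
  skip_if_not_installed("survival")
  set.seed(15)
  for (i in 1:10) {
    d <- tibble::tibble(time = round(rexp(60), 2) + 0.01,
                        status = rbinom(60, 1, 0.7),
                        group = sample(c("a", "b"), 60, replace = TRUE))
    sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = d)
    expect_equal(logrank_test(d)$statistic, sd$chisq, tolerance = 1e-10)
  }
})

test_that("cumulative incidence follows the hand computation and conservation", {
  # two subjects: relapse at 1, competing death at 2
  d <- tibble::tibble(time = c(1, 2),
                      event_type = c("relapse", "death_in_remission"))
  cif <- cumulative_incidence(d, "relapse")
  expect_equal(cif_at(cif, c(0.5, 1, 5)), c(0, 0.5, 0.5))
  cif_d <- cumulative_incidence(d, "death_in_remission")
  expect_equal(cif_at(cif_d, 2), 0.5)
  # conservation: survival plus all cause-specific CIFs equals 1
  set.seed(16)
  d2 <- tibble::tibble(
    time = round(rexp(150), 2) + 0.01,
    event_type = sample(c("censored", "relapse", "competing"), 150, TRUE))
  km <- kaplan_meier(tibble::tibble(
    time = d2$time, status = as.integer(d2$event_type != "censored")))
  c1 <- cumulative_incidence(d2, "relapse")
  c2 <- cumulative_incidence(d2, "competing")
  et <- sort(unique(d2$time[d2$event_type != "censored"]))
  total <- km_at(km, et) + cif_at(c1, et) + cif_at(c2, et)
  expect_equal(total, rep(1, length(et)), tolerance = 1e-10)
  # CIFs are monotone and SE is 0 before the first event
  expect_true(all(diff(c1$curve$cif) >= -1e-12))
  expect_equal(cif_at(c1, 0.001, what = "se"), 0)
  expect_error(cumulative_incidence(d2, "bogus"), "unknown")
})

test_that("without competing events the CIF equals one minus Kaplan-Meier", {
  set.seed(17)
  d <- tibble::tibble(time = round(rexp(80), 2) + 0.01,
                      event_type = ifelse(rbinom(80, 1, 0.6) == 1,
                                          "relapse", "censored"))
  cif <- cumulative_incidence(d, "relapse")
  km <- kaplan_meier(tibble::tibble(
    time = d$time, status = as.integer(d$event_type == "relapse")))
  expect_equal(cif$curve$cif, 1 - km$curve$surv, tolerance = 1e-12)
})

test_that("CIF standard errors track the cmprsk delta-method estimator", {
  skip_if_not_installed("cmprsk")
  set.seed(18)
  d <- tibble::tibble(
    time = round(rexp(400, 0.1), 2) + 0.01,
    event_type = sample(c("censored", "relapse", "competing"), 400, TRUE,
                        prob = c(0.4, 0.35, 0.25)))
  cif <- cumulative_incidence(d, "relapse")
  cm <- cmprsk::cuminc(d$time, d$event_type, cencode = "censored")
  tp <- cmprsk::timepoints(cm, cif$curve$time)
  expect_equal(cif$curve$cif, unname(tp$est["1 relapse", ]),
               tolerance = 1e-12)
  ratio <- cif$curve$se / sqrt(tp$var["1 relapse", ])
  keep <- is.finite(ratio) & cif$curve$n_risk > 20
  expect_true(all(abs(ratio[keep] - 1) < 0.1))
})

test_that("Gray's test reduces to the log-rank test without competing events", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    d <- tibble::tibble(
      time = round(rexp(n), 2) + 0.01,
      event_type = ifelse(rbinom(n, 1, 0.7) == 1, "relapse", "censored"),
      group = sample(c("a", "b"), n, replace = TRUE))
    if (length(unique(d$group)) < 2 || sum(d$event_type == "relapse") == 0) next
    g <- gray_test(d, "relapse")
    lr <- logrank_test(dplyr::mutate(
      d, status = as.integer(event_type == "relapse")))
    expect_equal(g$p, lr$p, tolerance = 1e-6)
  }
})

test_that("Gray's test is label-symmetric and near the exhaustive permutation law", {
  set.seed(20)
  d <- tibble::tibble(
    time = round(rexp(12), 1) + 0.1,
    event_type = sample(c("censored", "relapse", "competing"), 12, TRUE,
                        prob = c(0.2, 0.5, 0.3)),
    group = rep(c("a", "b"), 6))
  g1 <- gray_test(d, "relapse")
  swapped <- dplyr::mutate(d, group = ifelse(group == "a", "b", "a"))
  g2 <- gray_test(swapped, "relapse")
  expect_equal(g1$statistic, g2$statistic, tolerance = 1e-12)
  # exhaustive label permutation as the small-sample reference law
  gp <- gray_test(d, "relapse", p_method = "permutation")
  expect_equal(gp$n_perm, choose(12, 6))
  # independent oracle: recompute the permutation p with an explicit loop
  idx <- utils::combn(12, 6)
  stats <- apply(idx, 2, function(ii) {
    dd <- d; dd$group <- ifelse(seq_len(12) %in% ii, "a", "b")
    gray_test(dd, "relapse")$statistic
  })
  expect_equal(gp$p, mean(stats >= g1$statistic - 1e-12))
  # the asymptotic p should be within Monte-Carlo distance of the exact law
  expect_lt(abs(g1$p - gp$p), 0.12)
  expect_error(gray_test(dplyr::mutate(d, event_type = "censored"), "relapse"),
               "no events")
})

test_that("Gray's statistic is close to the cmprsk implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(22)
  rel_err <- vapply(1:10, function(i) {
    d <- tibble::tibble(
      time = round(rexp(150), 2) + 0.01,
      event_type = sample(c("censored", "relapse", "competing"), 150, TRUE,
                          prob = c(0.3, 0.4, 0.3)),
      group = sample(c("a", "b"), 150, replace = TRUE))
    g <- gray_test(d, "relapse")
    cm <- cmprsk::cuminc(d$time, d$event_type, d$group, cencode = "censored")
    abs(g$statistic - cm$Tests["relapse", "stat"]) /
      max(1, cm$Tests["relapse", "stat"])
  }, numeric(1))
  # same score, slightly different variance estimator: close, not identical
  expect_lt(stats::median(rel_err), 0.15)
})

test_that("endpoint derivation maps events per the trial definitions", {
  cl <- tibble::tibble(
    patient_id = sprintf("P%d", 1:5),
    followup_years = c(1, 2, 3, 4, 5),
    event = c("none", "relapse_progression", "death_in_remission",
              "second_malignancy", "death_other"))
  efs <- derive_endpoint(cl, "efs")
  expect_equal(efs$status, c(0L, 1L, 1L, 1L, 1L))
  os <- derive_endpoint(cl, "os")
  expect_equal(os$status, c(0L, 0L, 1L, 0L, 1L))
  rel <- derive_endpoint(cl, "relapse")
  expect_equal(rel$event_type,
               c("censored", "relapse_progression", "competing",
                 "competing", "competing"))
  expect_error(derive_endpoint(dplyr::mutate(cl, event = "exploded"), "efs"),
               "unknown")
})
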