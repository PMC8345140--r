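# Density estimation, concordance, time-dependent ROC, KM and log-rank

test_that("cell density follows the closed-form area conversion", {
  lab <- matrix(0L, 50, 50)
  expect_equal(cell_density(lab, 0.25)$density, 0)
  # 100 cells over a 1-mm-diameter core: density = 100 / (pi * 0.5^2)
  lab2 <- matrix(0L, 2000, 2000)
  centres <- expand.grid(r = seq(50, 1950, length.out = 10),
                         c = seq(50, 1950, length.out = 10))
  for (i in seq_len(100))
    lab2[centres$r[i] + 0:1, centres$c[i] + 0:1] <- i
  mpp <- 1000 * sqrt(pi * 0.25) / 2000  # so that 2000^2 px = pi*0.5^2 mm2
  d <- cell_density(lab2, mpp)
  expect_equal(d$n_cells, 100)
  expect_equal(d$area_mm2, pi * 0.25, tolerance = 1e-12)
  expect_equal(d$density, 100 / (pi * 0.25), tolerance = 1e-12)
  expect_equal(d$density, 127.32395, tolerance = 1e-6)
  # doubling the pixel size at fixed pixel count divides density by 4
  expect_equal(cell_density(lab2, 2 * mpp)$density, d$density / 4)
  # analysed mask restricts the area
  half <- matrix(0, 2000, 2000); half[, 1:1000] <- 1
  expect_equal(cell_density(lab2, mpp, analysed_mask = half)$area_mm2,
               d$area_mm2 / 2)
})

test_that("density concordance is the Pearson coefficient with guards", {
  x <- c(10, 40, 70, 100, 220)
  expect_equal(density_concordance(x, x), 1)
  expect_equal(density_concordance(x, -2 * x), -1)
  expect_equal(density_concordance(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(density_concordance(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(density_concordance(1:2, 1:2), "at least 3")
})

test_that("Kaplan-Meier estimator matches hand product-limit results", {
  # all censored: flat at 1
  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # three events: 2/3, 1/3, 0
  km3 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km3$surv, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(km3$time, c(0, 1, 2, 3))
  # single event among n at risk drops survival by (n-1)/n
  km5 <- km_curve(c(2, 5, 5, 5, 5), c(1, 0, 0, 0, 0))
  expect_equal(km5$surv[2], 4 / 5)
  # censoring-aware case against the hand oracle
  time <- c(1, 1.5, 2, 2, 3, 4, 4.5, 6)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  km <- km_curve(time, event)
  hand <- oracle_km(time, event)
  expect_equal(km$surv[match(hand$time, km$time)], hand$surv)
  # survival curves never increase and start at 1
  expect_equal(km$surv[1], 1)
  expect_true(all(diff(km$surv) <= 0))
})

test_that("log-rank statistic matches the observed-minus-expected form", {
  # identical groups: chi2 = 0, p = 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(t0, e0, t0, e0)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  # 6 + 6 worked fixture with distinct event times
  t1 <- c(1.1, 2.3, 3.4, 4.2, 5.1, 6.3); e1 <- c(1, 1, 0, 1, 1, 0)
  t2 <- c(0.8, 1.7, 2.8, 3.9, 4.6, 5.8); e2 <- c(1, 1, 1, 1, 0, 1)
  lr <- logrank_test(t1, e1, t2, e2)
  hand <- oracle_logrank_chisq(c(t1, t2), c(e1, e2),
                               rep(1:2, each = 6))
  expect_equal(lr$chisq, hand, tolerance = 1e-9)
  expect_equal(lr$p, pchisq(hand, 1, lower.tail = FALSE))
  # administrative censoring at the horizon changes the data entering the test
  lr5 <- logrank_test(t1, e1, t2, e2, horizon = 5)
  hand5 <- oracle_logrank_chisq(pmin(c(t1, t2), 5),
                                ifelse(c(t1, t2) > 5, 0, c(e1, e2)),
                                rep(1:2, each = 6))
  expect_equal(lr5$chisq, hand5, tolerance = 1e-9)
  expect_error(logrank_test(numeric(0), numeric(0), t2, e2), "non-empty")
})

test_that("time-dependent ROC separates a fully informative marker", {
  # densities perfectly ordering 5-year status, no censoring
  n <- 40
  marker <- seq_len(n)
  time <- ifelse(marker > 20, 2, 8)       # high marker -> early event
  event <- rep(1, n)
  ro <- td_roc_cutoff(marker, time, event, horizon = 5)
  expect_equal(ro$auc, 1)
  expect_equal(unname(ro$cutoff), 21)
  expect_true(all(ro$group[marker >= 21] == 1))
  expect_true(all(ro$group[marker < 21] == 2))
  expect_error(td_roc_cutoff(marker, rep(10, n), rep(0, n), 5), "events")
})

test_that("time-dependent ROC AUC is near 0.5 for an uninformative marker", {
  aucs <- vapply(1:20, function(s) {
    co <- generate_cohort(synth_cohort_config(n_patients = 500,
                                              log_hr_per_density = 0,
                                              seed = 1000 + s))
    td_roc_cutoff(co$density, co$time_years, co$event, horizon = 5)$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("stratification flags a strong density effect", {
  co <- generate_cohort(synth_cohort_config(n_patients = 200,
                                            log_hr_per_density = 0.01,
                                            seed = 77))
  st <- stratify_survival(co, horizon = 5)
  # dichotomization is a partition
  expect_equal(sort(unique(st$group)), 1:2)
  expect_equal(sum(st$n), nrow(co))
  # the high-density group must carry the higher 5-year event rate
  ev5 <- function(g) mean(co$event[st$group == g] == 1 &
                            co$time_years[st$group == g] <= 5)
  expect_gt(ev5(1), ev5(2))
  expect_lt(st$logrank$p, 0.05)
  expect_s3_class(st, "nq_strat")
  expect_output(print(st), "log-rank")
})
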