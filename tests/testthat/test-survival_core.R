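test_that("product-limit estimator matches hand-computed values", {
  # all events, no censoring: empirical survival
  cv <- km_estimate(data.frame(time_months = 1:4, event = 1))
  expect_equal(cv$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  cv <- km_estimate(data.frame(time_months = c(5, 10), event = 0))
  expect_true(all(cv$surv == 1))
  # hand product-limit: (2,1),(3,0),(4,1),(5,1) -> S(4) = 3/4 * 1/2
  cv <- km_estimate(data.frame(time_months = c(2, 3, 4, 5),
                               event = c(1, 0, 1, 1)))
  expect_equal(css_at(cv, 2), 0.75)
  expect_equal(css_at(cv, 4), 0.375)
  expect_equal(css_at(cv, 5), 0)
})

test_that("KM equals empirical survival without censoring and ignores record order", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(3:40, 1)
    tm <- ceiling(rexp(n, 0.1) * 10) / 10
    rec <- data.frame(time_months = tm, event = 1)
    cv <- km_estimate(rec)
    emp <- vapply(cv$time, function(tt) mean(tm > tt), numeric(1))
    expect_equal(cv$surv, emp, tolerance = 1e-12)
    shuf <- rec[sample(n), , drop = FALSE]
    expect_equal(km_estimate(shuf)$surv, cv$surv)
    expect_true(all(diff(cv$surv) <= 1e-12))
  }
})

test_that("cohort validation rejects degenerate inputs", {
  expect_error(km_estimate(data.frame(time_months = numeric(),
                                      event = integer())), "non-empty")
  expect_error(km_estimate(data.frame(time_months = -1, event = 1)),
               "non-negative")
  expect_error(km_estimate(data.frame(time_months = 1, event = 2)),
               "event")
})

test_that("css_at is a right-continuous step lookup with extrapolation flagged", {
  cv <- km_estimate(data.frame(time_months = c(2, 3, 4, 5),
                               event = c(1, 0, 1, 1)))
  expect_equal(css_at(cv, 0), 1.0)
  expect_equal(css_at(cv, 1.5), 1.0)   # before the first drop
  expect_equal(css_at(cv, 4.9), 0.375)
  expect_warning(v <- css_at(cv, 60), "extrapolated")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "extrapolated"))
  flat <- km_estimate(data.frame(time_months = rep(80, 5), event = 0))
  expect_equal(css_at(flat, 60), 1.0)
})

test_that("regrid is a faithful step interpolation", {
  cv <- km_estimate(data.frame(time_months = c(2, 3, 4, 5),
                               event = c(1, 0, 1, 1)))
  expect_equal(regrid(cv, cv$time)$surv, cv$surv)
  flat <- km_estimate(data.frame(time_months = 10, event = 0))
  expect_true(all(regrid(flat, c(3, 7, 30))$surv == 1))
  # consistency with css_at over random grids
  set.seed(11)
  for (r in 1:10) {
    g <- sort(sample(seq(0.5, 12, by = 0.5), 6))
    rg <- regrid(cv, g)
    for (i in seq_along(g)) {
      expect_equal(rg$surv[i], suppressWarnings(as.numeric(css_at(cv, g[i]))))
    }
  }
  expect_error(regrid(cv, c(3, 2)), "strictly increasing")
})

test_that("patient-level log-rank matches survival::survdiff and is symmetric", {
  set.seed(21)
  a <- data.frame(time_months = rexp(200, 0.1),
                  event = rbinom(200, 1, 0.8))
  b <- data.frame(time_months = rexp(200, 0.2),
                  event = rbinom(200, 1, 0.8))
  lr <- logrank_patient(a, b)
  d <- rbind(cbind(a, g = 0), cbind(b, g = 1))
  ref <- survival::survdiff(survival::Surv(time_months, event) ~ g,
                            data = d)
  expect_equal(lr$chi2, ref$chisq, tolerance = 1e-8)
  expect_equal(logrank_patient(b, a)$chi2, lr$chi2, tolerance = 1e-12)
  # identical groups: zero
  expect_equal(logrank_patient(a, a)$chi2, 0, tolerance = 1e-12)
  # extending a curve's grid past the last drop cannot change the distance
  g <- seq_len(ceiling(max(d$time_months)))
  ca <- regrid(km_estimate(a), g)
  cb <- regrid(km_estimate(b), g)
  g2 <- c(g, max(g) + 1:6)
  expect_equal(curve_chi2_distance(regrid(ca, g2), regrid(cb, g2))$chi2,
               curve_chi2_distance(ca, cb)$chi2, tolerance = 1e-12)
  expect_error(logrank_patient(data.frame(time_months = 1, event = 0),
                               data.frame(time_months = 2, event = 0)),
               "no events")
})

test_that("curve distance is zero on identical curves, symmetric and linear in N", {
  set.seed(31)
  rec <- data.frame(time_months = ceiling(rexp(300, 0.07)),
                    event = rbinom(300, 1, 0.9))
  rec2 <- data.frame(time_months = ceiling(rexp(300, 0.15)),
                     event = rbinom(300, 1, 0.9))
  g <- seq_len(80)
  ca <- regrid(km_estimate(rec), g)
  cb <- regrid(km_estimate(rec2), g)
  expect_equal(curve_chi2_distance(ca, ca)$chi2, 0)
  d_ab <- curve_chi2_distance(ca, cb)
  expect_equal(curve_chi2_distance(cb, ca)$chi2, d_ab$chi2,
               tolerance = 1e-12)
  expect_gt(d_ab$chi2, 0)
  expect_equal(curve_chi2_distance(ca, cb, n_per_group = 2000)$chi2,
               2 * curve_chi2_distance(ca, cb, n_per_group = 1000)$chi2,
               tolerance = 1e-12)
  expect_equal(curve_chi2_distance(ca, cb, n_per_group = 1000)$chi2,
               1000 * d_ab$chi2, tolerance = 1e-9)
})

test_that("curve distance converges to the patient-level statistic per capita", {
  for (n in c(100, 1000, 5000)) {
    set.seed(n)
    a <- data.frame(time_months = ceiling(rexp(n, 0.05)), event = 1)
    b <- data.frame(time_months = ceiling(rexp(n, 0.10)), event = 1)
    pl <- logrank_patient(a, b)
    g <- seq_len(max(a$time_months, b$time_months))
    ca <- regrid(km_estimate(a), g)
    cb <- regrid(km_estimate(b), g)
    cd <- curve_chi2_distance(ca, cb, n_per_group = n)
    expect_equal(cd$chi2, pl$chi2, tolerance = 0.02)
    exact <- curve_chi2_distance(ca, cb, n_per_group = n,
                                 finite_correction = TRUE)
    expect_equal(exact$chi2, pl$chi2, tolerance = 1e-10)
  }
})

test_that("curve distance rejects malformed inputs and prices chi2 into a p-value", {
  cv <- km_estimate(data.frame(time_months = 1:4, event = 1))
  short <- regrid(cv, 1:3)
  expect_error(curve_chi2_distance(cv, short), "incompatible grids")
  bad <- cv; bad$surv <- rev(bad$surv)
  expect_error(curve_chi2_distance(bad, bad), "non-increasing")
  # chi2 = 3.841 is the 5% point of chi-squared(1)
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  set.seed(5)
  a <- data.frame(time_months = ceiling(rexp(150, 0.05)), event = 1)
  b <- data.frame(time_months = ceiling(rexp(150, 0.15)), event = 1)
  g <- seq_len(max(a$time_months, b$time_months))
  res <- curve_chi2_distance(regrid(km_estimate(a), g),
                             regrid(km_estimate(b), g), n_per_group = 150)
  expect_equal(res$p,
               stats::pchisq(res$chi2, 1, lower.tail = FALSE))
})
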