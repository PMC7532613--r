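test_that("cohort summaries: identical uniform patients give the hand value, SD 0", {
  co <- uniform_cohort(list(ipsilateral_lung = 8.4))
  s <- summarize_cohort(co, model = "linear", age_exposure = 30)
  expect_equal(s$organ$mean_ear, 63)
  expect_equal(s$organ$sd, 0)
  expect_equal(s$organ$sem, 0)
  expect_equal(s$cumulative$mean, 63)
})

test_that("summaries require >= 2 patients and complete organ sets", {
  one <- cohort("solo", list(patient_plan("P01", list(
    ipsilateral_lung = uniform_dvh(8.4, organ = "ipsilateral_lung")
  ))))
  expect_error(summarize_cohort(one), class = "scrisk_input_error")

  p1 <- patient_plan("P01", list(ipsilateral_lung = uniform_dvh(8, organ = "ipsilateral_lung"),
                                 contralateral_lung = uniform_dvh(1, organ = "contralateral_lung")))
  p2 <- patient_plan("P02", list(ipsilateral_lung = uniform_dvh(9, organ = "ipsilateral_lung")))
  co <- cohort("gap", list(p1, p2))
  err <- tryCatch(summarize_cohort(co), error = function(e) conditionMessage(e))
  expect_match(err, "P02")
  expect_match(err, "contralateral_lung")
})

test_that("cumulative-EAR mean equals the sum of organ-EAR means (linearity)", {
  co <- generate_cohort(synthetic_cohort_config(2, "VMAT", "FB", seed = 21))
  for (m in c("linear", "linear_plateau")) {
    s <- summarize_cohort(co, model = m)
    expect_equal(s$cumulative$mean, sum(s$organ$mean_ear), tolerance = 1e-9)
    expect_equal(s$cumulative$sem, s$cumulative$sd / sqrt(s$n))
  }
})

test_that("relative factors reproduce published ratio-of-means arithmetic", {
  # cumulative means 230 (VMAT: 131+55+44) vs 65 (PT) -> 3.5 to one decimal
  expect_equal(round(relative_factor(rep(230, 5), rep(65, 5))$ratio_of_means, 1), 3.5)
  # linear-exponential means 110 (40+35+35) vs 21 -> 5.2
  expect_equal(round(relative_factor(rep(110, 5), rep(21, 5))$ratio_of_means, 1), 5.2)

  set.seed(41)
  a <- stats::runif(5, 200, 260); b <- stats::runif(5, 55, 75)
  rf <- relative_factor(a, b)
  expect_equal(rf$ratio_of_means, mean(a) / mean(b))
  expect_equal(rf$mean_ratio, mean(a / b))
  expect_equal(rf$sem_ratio, stats::sd(a / b) / sqrt(5))

  # identical cohorts: factor 1, degenerate p = 1
  rf <- relative_factor(b, b)
  expect_equal(rf$ratio_of_means, 1)
  expect_true(rf$degenerate)
  expect_equal(rf$p_value, 1)

  # swapping numerator and denominator inverts the factor, keeps p
  fwd <- relative_factor(a, b); rev <- relative_factor(b, a)
  expect_equal(rev$ratio_of_means, 1 / fwd$ratio_of_means)
  expect_equal(rev$p_value, fwd$p_value)

  expect_error(relative_factor(rep(0, 5), rep(0, 5)), class = "scrisk_input_error")
  expect_error(relative_factor(a, b[-1]), class = "scrisk_input_error")
})

test_that("relative factor is invariant under common dose rescaling (linear model)", {
  co_a <- uniform_cohort(list(ipsilateral_lung = 16.4), technique = "VMAT")
  co_b <- uniform_cohort(list(ipsilateral_lung = 8.4), label = "pt")
  scale_cohort <- function(x, k) {
    x$patients <- lapply(x$patients, function(p) {
      p$dvhs <- lapply(p$dvhs, function(d) { d$edges <- d$edges * k; d })
      p
    })
    x
  }
  f1 <- relative_factor(summarize_cohort(co_a), summarize_cohort(co_b))
  f2 <- relative_factor(summarize_cohort(scale_cohort(co_a, 2.5)),
                        summarize_cohort(scale_cohort(co_b, 2.5)))
  expect_equal(f1$ratio_of_means, f2$ratio_of_means, tolerance = 1e-12)
})

test_that("paired t matches the textbook statistic and flags degenerate cases", {
  set.seed(53)
  a <- stats::rnorm(5, 10); b <- stats::rnorm(5, 8)
  res <- paired_t_test(a, b)
  d <- a - b
  t_ref <- mean(d) / (stats::sd(d) / sqrt(5))
  p_ref <- 2 * stats::pt(-abs(t_ref), df = 4)
  expect_equal(res$statistic, t_ref, tolerance = 1e-10)
  expect_equal(res$p_value, p_ref, tolerance = 1e-10)
  expect_equal(res$df, 4)

  # a == b and constant nonzero shift both have zero-variance differences
  expect_true(paired_t_test(a, a)$degenerate)
  expect_equal(paired_t_test(a, a)$p_value, 1)
  shifted <- paired_t_test(a + 3, a)
  expect_true(shifted$degenerate)
  expect_equal(shifted$mean_difference, 3)

  expect_error(paired_t_test(a, b[-1]), class = "scrisk_input_error")
  expect_error(paired_t_test(1, 2), class = "scrisk_input_error")

  # invariant under adding the same constant to every value on both sides
  res2 <- paired_t_test(a + 100, b + 100)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
})

test_that("build_report assembles dose, EAR, comparison and delta tables", {
  a <- generate_cohort(synthetic_cohort_config(2, "VMAT", "FB", seed = 77))
  b <- generate_cohort(synthetic_cohort_config(2, "PT", "FB", seed = 77))
  rep <- build_report(list(a, b))
  expect_s3_class(rep, "risk_report")
  expect_equal(nrow(rep$doses), 6)
  expect_equal(nrow(rep$organ_ear), 2 * 3 * 2 * 3)   # cohorts x models x ages x organs
  expect_equal(nrow(rep$cumulative_ear), 2 * 3 * 2)
  cum <- rep$comparisons[rep$comparisons$scope == "cumulative", ]
  expect_equal(nrow(cum), 3 * 2)
  # proton is the denominator: photon/proton factors exceed 1
  expect_true(all(cum$factor_ratio_of_means > 1))
  expect_identical(unique(cum$cohort_b), "2-PT-FB")
  # delta-EAR table is per patient x organ x model
  expect_equal(nrow(rep$delta_ear), 2 * 5 * 3 * 3)
  br <- rep$delta_ear[rep$delta_ear$organ == "contralateral_breast" &
                        rep$delta_ear$cohort == "2-VMAT-FB", ]
  expect_equal(br$delta_ear / br$ear_30_70, rep(1 - 3.7 / 9.2, nrow(br)),
               tolerance = 1e-9)

  # single cohort: dose and EAR tables only
  solo <- build_report(a)
  expect_null(solo$comparisons)
  expect_equal(solo$n_tests, 0L)

  # zero contralateral-breast dose gives delta-EAR zero up to the
  # half-bin representative dose of the first bin (0.025 Gy)
  z <- uniform_cohort(list(ipsilateral_lung = 8.4, contralateral_breast = 0))
  rz <- build_report(z)
  zb <- rz$delta_ear[rz$delta_ear$organ == "contralateral_breast", ]
  expect_true(all(abs(zb$delta_ear) <= 0.025 * (9.2 - 3.7) + 1e-12))
})

test_that("report writing produces the CSV tables and a text rendering", {
  a <- generate_cohort(synthetic_cohort_config(1, "PT", "FB", seed = 5))
  b <- generate_cohort(synthetic_cohort_config(1, "3DCRT", "FB", seed = 5))
  rep <- build_report(list(b, a))
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  for (f in c("doses.csv", "organ_ear.csv", "cumulative_ear.csv",
              "comparisons.csv", "delta_ear.csv", "report.txt")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  back <- utils::read.csv(file.path(dir, "comparisons.csv"))
  expect_equal(nrow(back), nrow(rep$comparisons))
})
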