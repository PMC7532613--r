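test_that("uniform-dose OED reproduces the closed forms exactly", {
  for (D in c(0.5, 2, 10, 31.7, 60)) {
    u <- uniform_dvh(D)
    for (m in c("linear", "linear_exponential", "linear_plateau")) {
      expect_equal(oed(u, m), closed_form_oed(D, m), tolerance = 1e-12)
    }
  }
  # spot values evaluated by hand
  expect_equal(oed(uniform_dvh(10), "linear_exponential"), 10 * exp(-0.44),
               tolerance = 1e-12)
  expect_equal(oed(uniform_dvh(10), "linear_plateau"), (1 - exp(-1.39)) / 0.139,
               tolerance = 1e-12)
})

test_that("model names are normalised and unknown models rejected", {
  u <- uniform_dvh(10)
  expect_equal(oed(u, "lin-exp"), oed(u, "linear_exponential"))
  expect_equal(oed(u, "bell shape"), oed(u, "linear_exponential"))
  expect_equal(oed(u, "plateau"), oed(u, "linear_plateau"))
  expect_error(oed(u, "quadratic"), class = "scrisk_config_error")
  expect_error(risk_model_params("linear", alpha = -1), class = "scrisk_config_error")
})

test_that("OED orderings and bounds hold for random DVHs", {
  set.seed(17)
  for (rep in 1:50) {
    d <- random_diff_dvh(sample(10:200, 1), max_dose = stats::runif(1, 5, 80))
    lin <- oed(d, "linear")
    expect_identical(lin, mean_dose(d))
    expect_lt(oed(d, "linear_exponential"), lin)
    expect_lt(oed(d, "linear_plateau"), lin)
    expect_lt(oed(d, "linear_plateau"), 1 / 0.139)
  }
  # vanishing alpha recovers the linear model
  d <- random_diff_dvh(100)
  expect_equal(oed(d, risk_model_params("linear_exponential", alpha = 1e-9)),
               oed(d, "linear"), tolerance = 1e-6)
})

test_that("uniform linear-exponential OED is unimodal with its peak at 1/alpha", {
  grid <- seq(1, 60, by = 0.25)
  vals <- vapply(grid, function(D) oed(uniform_dvh(D), "linear_exponential"), 0)
  peak <- grid[which.max(vals)]
  expect_lt(abs(peak - 1 / 0.044), 0.25)
  expect_equal(sum(diff(sign(diff(vals))) != 0), 1L)  # one sign change: unimodal
})

test_that("DVH-binned OED matches the per-voxel brute-force sum", {
  set.seed(29)
  doses <- random_voxel_doses(10000)
  w <- 0.05
  d <- dvh_from_doses(doses, bin_width = w)
  # response slopes are at most 1, so half-bin dose error bounds the OED error
  for (m in c("linear", "linear_exponential", "linear_plateau")) {
    expect_lt(abs(oed(d, m) - voxel_oed(doses, m)), w / 2)
  }
})

test_that("EAR is the product of EAR0 and OED, with published spot values", {
  expect_equal(round(ear_from_oed(8.4, 7.5)), 63)
  expect_equal(round(ear_from_oed(5.9, 7.5)), 44)
  expect_identical(ear_from_oed(0, 7.5), 0)
  expect_error(ear_from_oed(-1, 7.5), class = "scrisk_config_error")
  expect_error(ear_from_oed(1, 0), class = "scrisk_config_error")

  # linearity in both factors
  set.seed(3)
  o <- stats::runif(5, 0, 20); k <- stats::runif(1, 0.1, 4)
  expect_equal(ear_from_oed(k * o, 7.5), k * ear_from_oed(o, 7.5))
  expect_equal(ear_from_oed(o, k * 7.5), k * ear_from_oed(o, 7.5))
})

test_that("baseline coefficient table carries the published values and CIs", {
  tab <- default_ear0_table()
  get <- function(cls, age) tab[tab$organ_class == cls & tab$age_exposure == age, ]
  expect_equal(get("lung", 30)$ear0, 7.5)
  expect_equal(unlist(get("lung", 30)[c("ci_low", "ci_high")], use.names = FALSE),
               c(5.1, 10.0))
  expect_equal(get("breast", 30)$ear0, 9.2)
  expect_equal(get("lung", 50)$ear0, 7.8)
  expect_equal(get("breast", 50)$ear0, 3.7)
  expect_true(all(tab$ci_low < tab$ear0 & tab$ear0 < tab$ci_high))

  # organ labels map to classes; laterality never changes the coefficient
  expect_equal(ear0_coefficient("contralateral_breast", 30)$ear0, 9.2)
  expect_equal(ear0_coefficient("ipsilateral_lung", 50)$ear0,
               ear0_coefficient("contralateral_lung", 50)$ear0)
  # the default table is defined at attained age 70 only
  expect_error(ear0_coefficient("lung", 30, age_attained = 60),
               class = "scrisk_config_error")
})

test_that("cumulative EAR sums distinct organs", {
  expect_equal(cumulative_ear(c(63, 2, 0)), 65)
  expect_equal(cumulative_ear(c(44, 1, 0)), 45)
  expect_equal(cumulative_ear(numeric(0)), 0)

  p <- patient_plan("P01", list(
    ipsilateral_lung = uniform_dvh(8.4, organ = "ipsilateral_lung"),
    contralateral_lung = uniform_dvh(0.3, organ = "contralateral_lung")
  ))
  est <- compute_risk(p, models = "linear", age_exposure = 30)
  expect_equal(cumulative_ear(est), 7.5 * (8.4 + 0.3))
  dup <- rbind(est, est[1, ])
  expect_error(cumulative_ear(dup), class = "scrisk_input_error")
})

test_that("age-at-exposure difference follows the coefficient ratio", {
  # fixed OED: relative breast reduction 1 - 3.7/9.2, about 60%
  o <- 4.7
  d <- delta_ear(ear_from_oed(o, 9.2), ear_from_oed(o, 3.7))
  expect_equal(d / ear_from_oed(o, 9.2), 1 - 3.7 / 9.2, tolerance = 1e-12)
  expect_equal(1 - 3.7 / 9.2, 0.598, tolerance = 1e-3)
  # lungs: small negative difference (7.5 vs 7.8)
  dl <- delta_ear(ear_from_oed(8.4, 7.5), ear_from_oed(8.4, 7.8))
  expect_lt(dl, 0)
  expect_lt(abs(dl), 0.05 * ear_from_oed(8.4, 7.5))
  expect_identical(delta_ear(0, 0), 0)

  # data-frame form pairs the two exposure ages per patient/organ/model
  p <- patient_plan("P01", list(
    contralateral_breast = uniform_dvh(4.7, organ = "contralateral_breast")
  ))
  est <- compute_risk(p, models = c("linear", "linear_plateau"))
  de <- delta_ear(est)
  expect_equal(nrow(de), 2L)
  expect_equal(de$delta_ear, de$ear_30_70 - de$ear_50_70)
  expect_error(delta_ear(est[est$age_exposure == 30, ]),
               class = "scrisk_input_error")
})

test_that("compute_risk emits one row per patient-organ-model-age with CI bounds", {
  co <- uniform_cohort(list(ipsilateral_lung = 8.4, contralateral_lung = 0.3,
                            contralateral_breast = 0.09))
  est <- compute_risk(co)
  expect_equal(nrow(est), 5 * 3 * 3 * 2)
  expect_true(all(est$ear >= 0))
  expect_equal(est$ear_ci_low, est$oed * ifelse(
    est$organ_class == "lung",
    ifelse(est$age_exposure == 30, 5.1, 4.6),
    ifelse(est$age_exposure == 30, 6.8, 2.1)
  ))
  expect_true(all(est$ear_ci_low <= est$ear & est$ear <= est$ear_ci_high))
})

test_that("risk configuration files override defaults and are validated", {
  cfg <- read_risk_config(NULL)
  expect_equal(cfg$alpha, 0.044)
  expect_equal(cfg$delta, 0.139)
  expect_equal(cfg$models,
               c("linear", "linear_exponential", "linear_plateau"),
               ignore_attr = TRUE)

  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "models: [bell-shape, linear]",
    "alpha: 0.05",
    "dispersion: sem",
    "ear0:",
    "  - organ_class: lung",
    "    age_exposure: 30",
    "    value: 8.0",
    "    ci_low: 5.0",
    "    ci_high: 11.0"
  ), p)
  cfg <- read_risk_config(p)
  expect_equal(cfg$models, c("linear_exponential", "linear"), ignore_attr = TRUE)
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$dispersion, "sem")
  expect_equal(ear0_coefficient("lung", 30, table = cfg$ear0_table)$ear0, 8.0)
  # untouched entries keep their defaults
  expect_equal(ear0_coefficient("breast", 50, table = cfg$ear0_table)$ear0, 3.7)

  writeLines(c("alpha: -2"), p)
  expect_error(read_risk_config(p), class = "scrisk_config_error")
})
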