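# Synthetic DVH cohort generator.
#
# No per-patient clinical DVHs are published for the study conditions the
# package reproduces, so cohorts are emulated with a two-component
# mixture per organ:
#
#   * a target-adjacent high-dose component: a beta distribution scaled
#     to [0, D_presc], carrying volume fraction f_h;
#   * a low-dose out-of-field "bath": an exponential distribution
#     truncated at D_presc, carrying 1 - f_h.
#
# Photon plans (3D-CRT, VMAT) have a substantial bath in contralateral
# organs; proton pencil-beam-scanning plans have a near-zero one. Only
# organ mean doses are published, so the component shapes are free
# parameters and f_h is solved per patient so that the *discretised*
# mixture mean equals the drawn patient mean exactly.
#
# Inter-patient spread: each patient's organ mean dose is lognormal
# around the profile mean with the profile's CV, sampled by Latin
# hypercube (one normal quantile stratum per patient, uniform jitter
# within the stratum). Stratification makes cohort means converge at
# O(1/n) while keeping a realistic spread at n = 5. The stratum draw for
# patient i and organ o depends only on (seed, i, o) - not on the
# technique - so two cohorts generated with the same master seed are
# paired: patient i represents the same anatomy under both techniques,
# as in a planning study where each patient is planned twice.

#' Organ dose profile for the synthetic generator
#'
#' @param organ Organ label (e.g. `"ipsilateral_lung"`).
#' @param mu Cohort mean organ dose in Gy.
#' @param cv Inter-patient coefficient of variation of the mean dose
#'   (dimensionless, >= 0).
#' @param high_shape Beta shape parameters `c(shape1, shape2)` of the
#'   high-dose component over `[0, d_presc]`, or a single dose value for
#'   a degenerate point mass at that dose.
#' @param bath_mean Mean in Gy of the exponential low-dose bath
#'   component (0 collapses the bath to the first dose bin).
#' @param d_presc Prescription dose in Gy (upper dose limit).
#' @return An object of class `"organ_dose_profile"`.
#' @export
organ_dose_profile <- function(organ, mu, cv, high_shape = c(3, 1.5),
                               bath_mean = 0.5, d_presc = 50) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    abort_config("organ_dose_profile(): 'mu' must be a non-negative number")
  }
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0) {
    abort_config("organ_dose_profile(): 'cv' must be non-negative")
  }
  if (!is.numeric(high_shape) || !length(high_shape) %in% c(1L, 2L) ||
      any(!is.finite(high_shape)) || any(high_shape <= 0)) {
    abort_config("organ_dose_profile(): 'high_shape' must be beta shapes or a point dose")
  }
  if (!is.numeric(bath_mean) || length(bath_mean) != 1L || !is.finite(bath_mean) ||
      bath_mean < 0) {
    abort_config("organ_dose_profile(): 'bath_mean' must be non-negative")
  }
  if (!is.numeric(d_presc) || length(d_presc) != 1L || d_presc <= 0) {
    abort_config("organ_dose_profile(): 'd_presc' must be positive")
  }
  structure(
    list(organ = as.character(organ), mu = mu, cv = cv,
         high_shape = high_shape, bath_mean = bath_mean, d_presc = d_presc),
    class = "organ_dose_profile"
  )
}

# discretised bin masses of the scaled-beta high-dose component
discretize_high <- function(high_shape, d_presc, edges) {
  n <- length(edges) - 1L
  if (length(high_shape) == 1L) {
    # degenerate: point mass at the stated dose
    idx <- findInterval(high_shape, edges, rightmost.closed = TRUE, all.inside = TRUE)
    mass <- numeric(n); mass[idx] <- 1
    return(mass)
  }
  p <- stats::pbeta(edges / d_presc, high_shape[1L], high_shape[2L])
  diff(p) / (p[n + 1L] - p[1L])
}

# discretised bin masses of the truncated-exponential bath
discretize_bath <- function(bath_mean, d_presc, edges) {
  n <- length(edges) - 1L
  if (bath_mean <= 0) {
    mass <- numeric(n); mass[1L] <- 1
    return(mass)
  }
  r <- 1 / bath_mean
  p <- stats::pexp(edges, rate = r)
  diff(p) / stats::pexp(d_presc, rate = r)
}

# deterministic mixture construction for a given realised patient mean.
# Solves f_h from the discretised component means; when the target mean
# falls below the bath mean the bath rate is re-solved instead (pure
# bath), and means outside the representable range [w/2, m_high] are
# clamped to it.
build_mixture_dvh <- function(profile, mu_p, bin_width) {
  d_presc <- profile$d_presc
  n <- max(1L, round(d_presc / bin_width))
  edges <- seq(0, d_presc, length.out = n + 1L)
  centers <- (edges[-1L] + edges[-(n + 1L)]) / 2
  high <- discretize_high(profile$high_shape, d_presc, edges)
  bath <- discretize_bath(profile$bath_mean, d_presc, edges)
  m_high <- sum(high * centers)
  m_bath <- sum(bath * centers)
  if (profile$mu > m_high) {
    abort_config(sprintf(
      "profile '%s': mean dose %.3g Gy exceeds the high-dose component mean %.3g Gy; calibration infeasible",
      profile$organ, profile$mu, m_high
    ))
  }
  mu_p <- min(max(mu_p, centers[1L]), m_high)
  if (mu_p >= m_bath) {
    f_h <- (mu_p - m_bath) / (m_high - m_bath)
    values <- f_h * high + (1 - f_h) * bath
  } else if (mu_p <= centers[1L] + 1e-12) {
    values <- numeric(n); values[1L] <- 1
  } else {
    # pure bath: solve the exponential rate so the discretised mean hits mu_p
    obj <- function(log_rate) {
      b <- discretize_bath(1 / exp(log_rate), d_presc, edges)
      sum(b * centers) - mu_p
    }
    root <- stats::uniroot(obj, lower = log(1e-6), upper = log(1e6),
                           tol = 1e-13)$root
    values <- discretize_bath(1 / exp(root), d_presc, edges)
  }
  list(edges = edges, values = values)
}

# deterministic substream seed from master seed, patient index and organ
# label; technique-independent so equal-seed cohorts are paired
derive_seed <- function(seed, patient_index, organ) {
  h <- sum(utf8ToInt(organ)) %% 32768
  as.integer((as.numeric(seed) %% 2147483647 + patient_index * 1664525 +
                h * 22695477) %% 2147483647)
}

#' Generate one patient's organ DVH from a dose profile
#'
#' Draws the patient's mean organ dose lognormally around the profile
#' mean (`sdlog^2 = log(1 + cv^2)`, median-adjusted so the expectation
#' equals `mu`), then builds the binned two-component mixture whose
#' discretised mean equals the drawn value. With `stratum` and
#' `n_strata` the normal quantile is Latin-hypercube stratified, which
#' is how [generate_cohort()] calls it.
#'
#' @param profile An [organ_dose_profile].
#' @param seed Integer seed for the patient/organ substream.
#' @param stratum,n_strata Optional stratified-sampling position: the
#'   normal quantile is drawn uniformly within stratum `stratum` of
#'   `n_strata`. Default (both `NULL`) is an unstratified draw.
#' @param bin_width Dose bin width in Gy (default 0.05, giving
#'   discretisation errors well below other uncertainties at
#'   prescription-level doses).
#' @param patient Patient label stored in the DVH.
#' @param rbe_weighted Flag copied to the DVH (set for proton plans).
#' @return A differential [dvh] that passes [validate_dvh()].
#' @export
generate_patient_dvh <- function(profile, seed = NULL, stratum = NULL,
                                 n_strata = NULL, bin_width = 0.05,
                                 patient = NA_character_, rbe_weighted = FALSE) {
  if (!inherits(profile, "organ_dose_profile")) {
    abort_config("generate_patient_dvh(): 'profile' must be an organ_dose_profile")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  z <- if (!is.null(stratum)) {
    if (is.null(n_strata) || stratum < 1L || stratum > n_strata) {
      abort_config("generate_patient_dvh(): need 1 <= stratum <= n_strata")
    }
    stats::qnorm((stratum - 1L + stats::runif(1)) / n_strata)
  } else {
    stats::rnorm(1)
  }
  # winsorise at the 0.1%/99.9% normal quantiles: inter-patient spread in a
  # planning cohort is bounded, and an unbounded lognormal tail would let a
  # single extreme patient dominate cohort means at high CV
  z <- min(max(z, stats::qnorm(0.001)), stats::qnorm(0.999))
  sdlog <- sqrt(log(1 + profile$cv^2))
  mu_p <- profile$mu * exp(sdlog * z - sdlog^2 / 2)
  mix <- build_mixture_dvh(profile, mu_p, bin_width)
  out <- dvh(mix$edges, mix$values, form = "differential",
             organ = profile$organ, patient = patient,
             rbe_weighted = rbe_weighted)
  assert_valid_dvh(out, what = "generated DVH")
  out
}

# published cohort mean organ doses (Gy) and their standard errors
# (n = 5) per group/technique/setup; order: ipsilateral lung,
# contralateral lung, contralateral breast
.study_doses <- list(
  "1.PT.FB"     = list(mu = c(5.9, 0.08, 0.08), sem = c(2.1, 0.10, 0.03)),
  "1.3DCRT.FB"  = list(mu = c(11.5, 0.6, 0.9),  sem = c(1.1, 0.1, 0.1)),
  "2.PT.FB"     = list(mu = c(8.4, 0.3, 0.09),  sem = c(0.3, 0.1, 0.02)),
  "2.VMAT.FB"   = list(mu = c(16.4, 7.3, 4.7),  sem = c(1.6, 0.4, 0.3)),
  "2.PT.DIBH"   = list(mu = c(7.4, 0.15, 0.07), sem = c(0.8, 0.02, 0.01)),
  "2.VMAT.DIBH" = list(mu = c(14.6, 6.2, 4.8),  sem = c(0.9, 0.3, 0.3))
)

.study_organs <- c("ipsilateral_lung", "contralateral_lung", "contralateral_breast")

#' Default organ dose profiles for a study arm
#'
#' Profiles whose organ means equal the published cohort means for the
#' requested group/technique/setup combination and whose inter-patient
#' CVs are derived from the published standard errors (`CV = SEM *
#' sqrt(5) / mean`). The supported design is: Group 1 planned with PT or
#' tangential 3D-CRT in free breathing; Group 2 planned with PT or VMAT
#' in free breathing or breath hold. Breath-hold profiles reuse the
#' free-breathing component shapes with the breath-hold means.
#'
#' Shape choices emulate the published cumulative-DVH morphology: the
#' ipsilateral lung has a broad target-adjacent high-dose component;
#' photon contralateral organs sit in an extended low-/intermediate-dose
#' bath; proton contralateral organs receive a near-zero scatter bath
#' only.
#'
#' @param group Study group, 1 or 2.
#' @param technique `"PT"`, `"3DCRT"` or `"VMAT"`.
#' @param setup `"FB"` or `"DIBH"`.
#' @param d_presc Prescription dose in Gy (default 50).
#' @return Named list of [organ_dose_profile] objects for the
#'   ipsilateral lung, contralateral lung and contralateral breast.
#' @export
#' @examples
#' p <- default_profiles(2, "VMAT", "FB")
#' p$contralateral_lung$mu  # 7.3 Gy
default_profiles <- function(group, technique, setup = "FB", d_presc = 50) {
  key <- sprintf("%s.%s.%s", group, technique, setup)
  entry <- .study_doses[[key]]
  if (is.null(entry)) {
    abort_config(sprintf(
      "no such study arm: group %s, technique %s, setup %s (supported: %s)",
      group, technique, setup, paste(names(.study_doses), collapse = ", ")
    ))
  }
  photon <- technique %in% c("3DCRT", "VMAT")
  n <- 5  # published cohort size behind the SEMs
  profiles <- list()
  for (k in seq_along(.study_organs)) {
    organ <- .study_organs[k]
    mu <- entry$mu[k]
    cv <- entry$sem[k] * sqrt(n) / mu
    if (organ == "ipsilateral_lung") {
      high_shape <- c(3, 1.5)                     # mean 2/3 * D_presc
      bath_mean <- if (photon) 2.0 else 0.5
    } else {
      high_shape <- c(1.5, 6)                     # mean 0.2 * D_presc
      bath_mean <- if (photon) {
        if (organ == "contralateral_lung") 2.0 else 1.5
      } else {
        0.8 * mu                                  # scatter-only, near-zero
      }
    }
    profiles[[organ]] <- organ_dose_profile(
      organ = organ, mu = mu, cv = cv, high_shape = high_shape,
      bath_mean = bath_mean, d_presc = d_presc
    )
  }
  profiles
}

#' Synthetic cohort configuration
#'
#' @param group,technique,setup Study arm (see [default_profiles()]).
#' @param n_patients Number of patients (>= 2; the study size is 5).
#' @param d_presc Prescription dose in Gy (default 50, delivered in
#'   2 Gy fractions in the emulated study).
#' @param bin_width DVH bin width in Gy (default 0.05).
#' @param seed Master random seed; recorded in the cohort and required
#'   for reproducibility.
#' @param label Cohort label (default `"<group>-<technique>-<setup>"`).
#' @param profiles Optional list of [organ_dose_profile] overrides;
#'   default is [default_profiles()] for the arm.
#' @return A list of class `"synthetic_cohort_config"`.
#' @export
synthetic_cohort_config <- function(group, technique, setup = "FB",
                                    n_patients = 5, d_presc = 50,
                                    bin_width = 0.05, seed = 1,
                                    label = NULL, profiles = NULL) {
  if (!is.numeric(n_patients) || n_patients < 2) {
    abort_config("synthetic_cohort_config(): 'n_patients' must be >= 2")
  }
  if (is.null(profiles)) {
    profiles <- default_profiles(group, technique, setup, d_presc = d_presc)
  }
  if (!all(vapply(profiles, inherits, TRUE, what = "organ_dose_profile"))) {
    abort_config("synthetic_cohort_config(): 'profiles' must be organ_dose_profile objects")
  }
  if (is.null(label)) label <- sprintf("%s-%s-%s", group, technique, setup)
  structure(
    list(group = group, technique = technique, setup = setup,
         n_patients = as.integer(n_patients), d_presc = d_presc,
         bin_width = bin_width, seed = as.integer(seed),
         label = label, profiles = profiles),
    class = "synthetic_cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Generates `n_patients` patients, each with one DVH per configured
#' organ, deterministically from the master seed: the draw for patient
#' *i* and organ *o* depends only on `(seed, i, o)`, so cohorts of
#' different techniques generated with the same seed are paired
#' patient-by-patient (the same anatomy planned twice). Pass `out_dir`
#' to also write the DVH files and manifest; outputs are byte-identical
#' across runs with the same configuration.
#'
#' @param config A [synthetic_cohort_config].
#' @param out_dir Optional output directory for DVH CSV files and
#'   `manifest.csv`.
#' @return A [cohort]; the configuration (including the seed) is
#'   attached as attribute `"config"`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  if (!inherits(config, "synthetic_cohort_config")) {
    abort_config("generate_cohort(): 'config' must be a synthetic_cohort_config")
  }
  rbe <- identical(config$technique, "PT")
  patients <- lapply(seq_len(config$n_patients), function(i) {
    pid <- sprintf("%s_P%02d", gsub("[^A-Za-z0-9]+", "", config$label), i)
    dvhs <- lapply(config$profiles, function(profile) {
      generate_patient_dvh(
        profile,
        seed = derive_seed(config$seed, i, profile$organ),
        stratum = i, n_strata = config$n_patients,
        bin_width = config$bin_width, patient = pid, rbe_weighted = rbe
      )
    })
    patient_plan(patient_id = pid, dvhs = dvhs)
  })
  out <- cohort(label = config$label, patients = patients,
                group = config$group, technique = config$technique,
                setup = config$setup)
  attr(out, "config") <- config
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Recover mixture parameters from a generated DVH
#'
#' Least-squares fit of the high-dose volume fraction `f_h` and the bath
#' mean to the binned volume fractions of a DVH, holding the high-dose
#' beta shape fixed. Intended as a self-consistency check of the
#' generator: on a high-resolution DVH generated from known parameters
#' the fit recovers them closely.
#'
#' @param x A differential [dvh] from the mixture family.
#' @param high_shape Beta shape parameters of the high-dose component.
#' @param d_presc Prescription dose in Gy.
#' @return A list with elements `f_h` and `bath_mean`.
#' @export
estimate_mixture_params <- function(x, high_shape = c(3, 1.5), d_presc = 50) {
  d <- as_differential(x)
  assert_valid_dvh(d)
  edges <- d$edges
  high <- discretize_high(high_shape, d_presc, edges)
  obj <- function(par) {
    f_h <- stats::plogis(par[1L])
    bath <- discretize_bath(exp(par[2L]), d_presc, edges)
    sum((f_h * high + (1 - f_h) * bath - d$values)^2)
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(f_h = stats::plogis(fit$par[1L]), bath_mean = exp(fit$par[2L]))
}
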