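# Cohort containers and cohort-level statistics.

#' A patient's set of organ DVHs
#'
#' @param patient_id Unique patient label.
#' @param dvhs Named list of [dvh] objects, names being organ labels. If
#'   unnamed, organ labels are taken from each DVH's `organ` field.
#' @return An object of class `"patient_plan"`.
#' @export
patient_plan <- function(patient_id, dvhs) {
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id)) {
    abort_input("patient_plan(): 'patient_id' must be a non-empty string")
  }
  if (!is.list(dvhs) || length(dvhs) == 0L ||
      !all(vapply(dvhs, inherits, TRUE, what = "dvh"))) {
    abort_input("patient_plan(): 'dvhs' must be a non-empty list of dvh objects")
  }
  if (is.null(names(dvhs)) || any(!nzchar(names(dvhs)))) {
    nm <- vapply(dvhs, function(d) d$organ, "")
    if (anyNA(nm) || any(!nzchar(nm))) {
      abort_input("patient_plan(): organs must be named (list names or dvh$organ)")
    }
    names(dvhs) <- nm
  }
  if (anyDuplicated(names(dvhs))) {
    abort_input(sprintf("patient_plan(): duplicate organ '%s' for patient %s",
                        names(dvhs)[duplicated(names(dvhs))][1L], patient_id))
  }
  structure(list(patient_id = patient_id, dvhs = dvhs), class = "patient_plan")
}

#' A cohort of patient plans
#'
#' @param label Cohort label, e.g. `"2-PT-FB"`.
#' @param patients List of [patient_plan] objects with unique ids.
#' @param group Study group (1: supraclavicular nodes only; 2:
#'   supraclavicular plus internal mammary nodes).
#' @param technique Treatment technique (`"PT"`, `"3DCRT"`, `"VMAT"`).
#' @param setup Breathing setup (`"FB"` free breathing, `"DIBH"` deep
#'   inspiration breath hold).
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(label, patients, group = NA, technique = NA_character_,
                   setup = NA_character_) {
  if (!is.list(patients) || length(patients) == 0L ||
      !all(vapply(patients, inherits, TRUE, what = "patient_plan"))) {
    abort_input("cohort(): 'patients' must be a non-empty list of patient_plan objects")
  }
  ids <- vapply(patients, function(p) p$patient_id, "")
  if (anyDuplicated(ids)) {
    abort_input(sprintf("cohort(): duplicate patient id '%s'", ids[duplicated(ids)][1L]))
  }
  structure(
    list(label = as.character(label), patients = patients, group = group,
         technique = as.character(technique), setup = as.character(setup)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  organs <- unique(unlist(lapply(x$patients, function(p) names(p$dvhs))))
  cat(sprintf("<cohort> %s: %d patients, organs: %s\n",
              x$label, length(x$patients), paste(organs, collapse = ", ")))
  invisible(x)
}

# patients x organs matrix of EAR for one model and exposure age; errors
# name the first patient/organ with a missing DVH
ear_matrix <- function(x, model, age_exposure, ear0_table, alpha, delta) {
  organs <- unique(unlist(lapply(x$patients, function(p) names(p$dvhs))))
  pars <- risk_model_params(model, alpha = alpha, delta = delta)
  mat <- matrix(NA_real_, nrow = length(x$patients), ncol = length(organs),
                dimnames = list(vapply(x$patients, function(p) p$patient_id, ""),
                                organs))
  for (p in x$patients) {
    for (organ in organs) {
      d <- p$dvhs[[organ]]
      if (is.null(d)) {
        abort_input(sprintf("cohort %s: patient %s has no DVH for organ '%s'",
                            x$label, p$patient_id, organ))
      }
      coefs <- ear0_coefficient(organ, age_exposure = age_exposure,
                                table = ear0_table)
      mat[p$patient_id, organ] <- ear_from_oed(oed(d, pars), coefs$ear0)
    }
  }
  mat
}

#' Cohort summary statistics for one model and exposure age
#'
#' Per-organ mean EAR over patients with SD and SEM (`SEM = SD /
#' sqrt(n)`), plus the cumulative EAR computed per patient (sum over
#' organs) and then averaged; by linearity this equals the sum of the
#' organ means.
#'
#' @param x A [cohort] with at least 2 patients (dispersion is undefined
#'   otherwise) in which every patient has a DVH for every organ.
#' @param model Dose-response model name.
#' @param age_exposure Exposure age (default 30).
#' @param ear0_table Baseline coefficient table.
#' @param alpha,delta Dose-response parameters.
#' @return An object of class `"cohort_summary"`: a list with `organ`
#'   (data frame of per-organ mean/sd/sem), `cumulative` (mean/sd/sem),
#'   `per_patient` (data frame of per-patient organ and cumulative EARs),
#'   `model`, `age_exposure`, `n`, `label`.
#' @export
summarize_cohort <- function(x, model = "linear", age_exposure = 30,
                             ear0_table = default_ear0_table(),
                             alpha = 0.044, delta = 0.139) {
  if (!inherits(x, "cohort")) abort_input("summarize_cohort(): not a 'cohort' object")
  n <- length(x$patients)
  if (n < 2L) {
    abort_input(sprintf(
      "cohort %s has %d patient(s); at least 2 are required for dispersion statistics",
      x$label, n
    ))
  }
  model <- normalize_model(model)
  mat <- ear_matrix(x, model, age_exposure, ear0_table, alpha, delta)
  cum <- rowSums(mat)
  organ_stats <- data.frame(
    organ = colnames(mat),
    mean_ear = colMeans(mat),
    sd = apply(mat, 2L, stats::sd),
    sem = apply(mat, 2L, stats::sd) / sqrt(n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(
      organ = organ_stats,
      cumulative = list(mean = mean(cum), sd = stats::sd(cum),
                        sem = stats::sd(cum) / sqrt(n)),
      per_patient = data.frame(patient_id = rownames(mat), mat,
                               cumulative = cum, row.names = NULL,
                               check.names = FALSE, stringsAsFactors = FALSE),
      model = model, age_exposure = age_exposure, n = n, label = x$label
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s, model %s, exposure age %d, n = %d\n",
              x$label, x$model, as.integer(x$age_exposure), x$n))
  tab <- x$organ
  tab$mean_ear <- round(tab$mean_ear)
  tab$sd <- round(tab$sd, 1)
  tab$sem <- round(tab$sem, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("cumulative EAR: %d (SD %.1f, SEM %.1f) cases per 10,000 person-years\n",
              round(x$cumulative$mean), x$cumulative$sd, x$cumulative$sem))
  invisible(x)
}

#' Two-tailed paired Student t test
#'
#' Thin wrapper around [stats::t.test()] that handles the degenerate
#' case of zero-variance paired differences (common with identical or
#' perfectly shifted synthetic cohorts) by returning `p = 1` with a
#' `degenerate` flag instead of failing.
#'
#' @param a,b Paired numeric vectors (same patients, same order), length
#'   at least 2.
#' @return A list of class `"paired_t_result"`: `statistic`, `df`,
#'   `p_value`, `significant` (at 0.05), `degenerate`, `mean_difference`,
#'   `n`.
#' @export
paired_t_test <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    abort_input("paired_t_test(): inputs must be numeric")
  }
  if (length(a) != length(b)) {
    abort_input("paired_t_test(): inputs must be paired (equal length)")
  }
  n <- length(a)
  if (n < 2L) abort_input("paired_t_test(): at least 2 pairs are required")
  d <- a - b
  if (stats::sd(d) == 0) {
    res <- list(statistic = NA_real_, df = n - 1L, p_value = 1,
                significant = FALSE, degenerate = TRUE,
                mean_difference = mean(d), n = n)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, significant = tt$p.value < 0.05,
                degenerate = FALSE, mean_difference = mean(d), n = n)
  }
  structure(res, class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("paired t test: degenerate (zero-variance differences), p = 1, n = %d\n",
                x$n))
  } else {
    cat(sprintf("paired t test: t = %.3f, df = %d, p = %.4g%s, n = %d\n",
                x$statistic, x$df, x$p_value,
                if (x$significant) " (significant at 0.05)" else "", x$n))
  }
  invisible(x)
}

#' Relative risk factor between two cohorts
#'
#' Compares paired per-patient cumulative (or per-organ) EARs of two
#' cohorts. Two factor conventions are computed: the ratio of cohort
#' means, which is the headline value, and the mean of per-patient
#' ratios with its SEM. A two-tailed paired t test accompanies them.
#'
#' @param a,b Either [cohort_summary] objects (their per-patient
#'   cumulative EARs are used) or paired numeric vectors of per-patient
#'   EARs. `a` is the numerator.
#' @return A list of class `"scr_comparison"`: `ratio_of_means`,
#'   `mean_ratio`, `sem_ratio`, `p_value`, `significant`, `degenerate`,
#'   `n`.
#' @export
#' @examples
#' vmat <- c(228, 232, 225, 235, 230)
#' pt <- c(64, 66, 63, 67, 65)
#' relative_factor(vmat, pt)$ratio_of_means  # about 3.5
relative_factor <- function(a, b) {
  as_vec <- function(x, side) {
    if (inherits(x, "cohort_summary")) return(x$per_patient$cumulative)
    if (is.numeric(x)) return(x)
    abort_input(sprintf(
      "relative_factor(): '%s' must be a cohort_summary or numeric vector", side
    ))
  }
  va <- as_vec(a, "a")
  vb <- as_vec(b, "b")
  if (length(va) != length(vb)) {
    abort_input("relative_factor(): cohorts must be paired (equal patient counts)")
  }
  if (mean(vb) == 0) {
    abort_input("relative_factor(): denominator cohort mean EAR is 0; ratio undefined")
  }
  ratios <- va / vb
  tt <- paired_t_test(va, vb)
  structure(
    list(
      ratio_of_means = mean(va) / mean(vb),
      mean_ratio = mean(ratios),
      sem_ratio = if (all(is.finite(ratios))) stats::sd(ratios) / sqrt(length(ratios))
                  else NA_real_,
      p_value = tt$p_value,
      significant = tt$significant,
      degenerate = tt$degenerate,
      n = length(va)
    ),
    class = "scr_comparison"
  )
}

#' @export
print.scr_comparison <- function(x, ...) {
  cat(sprintf(
    "relative EAR factor: %.2f (ratio of means); %.2f +/- %.2f (mean of per-patient ratios, SEM); p = %.4g%s\n",
    x$ratio_of_means, x$mean_ratio, x$sem_ratio, x$p_value,
    if (x$degenerate) " [degenerate t]" else ""
  ))
  invisible(x)
}
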