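# Report assembly: mean-dose table, per-organ and cumulative EAR tables,
# cross-technique comparisons and the age-at-exposure difference table.

#' Build a full risk report over one or more cohorts
#'
#' Assembles (a) a mean organ dose table, (b) per-organ EAR tables for
#' every requested model and exposure age, (c) cumulative EAR with
#' cross-technique relative factors and paired t tests, and (d) the
#' per-patient age-at-exposure EAR difference (exposure at 30 minus
#' exposure at 50). Cohorts sharing group and setup but differing in
#' technique are compared pairwise, with the proton cohort (when
#' present) as the denominator; with a single cohort only the dose and
#' EAR tables are produced. The linear model is computed alongside the
#' others but should be read as a reference: it is expected to
#' overestimate risk at organ doses above a few Gy.
#'
#' No multiple-testing correction is applied; the number of tests
#' performed is recorded in the `n_tests` element.
#'
#' @param cohorts A [cohort] or list of cohorts.
#' @param config Risk configuration list from [read_risk_config()] /
#'   [default_risk_config()].
#' @return An object of class `"risk_report"`: list of data frames
#'   `doses`, `organ_ear`, `cumulative_ear`, `comparisons`, `delta_ear`,
#'   plus `dispersion` and `n_tests`.
#' @export
build_report <- function(cohorts, config = default_risk_config()) {
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  if (!is.list(cohorts) || length(cohorts) == 0L ||
      !all(vapply(cohorts, inherits, TRUE, what = "cohort"))) {
    abort_input("build_report(): 'cohorts' must be a cohort or list of cohorts")
  }
  labels <- vapply(cohorts, function(x) x$label, "")
  if (anyDuplicated(labels)) abort_input("build_report(): cohort labels must be unique")
  names(cohorts) <- labels

  dose_rows <- list()
  for (x in cohorts) {
    organs <- unique(unlist(lapply(x$patients, function(p) names(p$dvhs))))
    for (organ in organs) {
      md <- vapply(x$patients, function(p) {
        d <- p$dvhs[[organ]]
        if (is.null(d)) abort_input(sprintf(
          "cohort %s: patient %s has no DVH for organ '%s'", x$label, p$patient_id, organ
        ))
        mean_dose(d)
      }, 0)
      dose_rows[[length(dose_rows) + 1L]] <- data.frame(
        cohort = x$label, organ = organ, mean_dose_gy = mean(md),
        sd = stats::sd(md), sem = stats::sd(md) / sqrt(length(md)),
        n = length(md), stringsAsFactors = FALSE
      )
    }
  }

  organ_rows <- list()
  cum_rows <- list()
  summaries <- list()
  for (x in cohorts) {
    for (model in config$models) {
      for (age in config$age_exposure) {
        s <- summarize_cohort(x, model = model, age_exposure = age,
                              ear0_table = config$ear0_table,
                              alpha = config$alpha, delta = config$delta)
        summaries[[paste(x$label, model, age, sep = "|")]] <- s
        o <- s$organ
        o$cohort <- x$label; o$model <- model; o$age_exposure <- age
        organ_rows[[length(organ_rows) + 1L]] <-
          o[, c("cohort", "model", "age_exposure", "organ", "mean_ear", "sd", "sem")]
        cum_rows[[length(cum_rows) + 1L]] <- data.frame(
          cohort = x$label, model = model, age_exposure = age,
          mean_ear = s$cumulative$mean, sd = s$cumulative$sd,
          sem = s$cumulative$sem, n = s$n, stringsAsFactors = FALSE
        )
      }
    }
  }

  # pair cohorts sharing group and setup but differing in technique;
  # proton is the denominator when one side of the pair is PT
  comp_rows <- list()
  n_tests <- 0L
  if (length(cohorts) > 1L) {
    for (i in seq_along(cohorts)) {
      for (j in seq_along(cohorts)) {
        if (i >= j) next
        a <- cohorts[[i]]; b <- cohorts[[j]]
        if (!identical(a$group, b$group) || !identical(a$setup, b$setup) ||
            identical(a$technique, b$technique)) next
        if (identical(a$technique, "PT") && !identical(b$technique, "PT")) {
          tmp <- a; a <- b; b <- tmp
        }
        for (model in config$models) {
          for (age in config$age_exposure) {
            sa <- summaries[[paste(a$label, model, age, sep = "|")]]
            sb <- summaries[[paste(b$label, model, age, sep = "|")]]
            rf <- relative_factor(sa, sb)
            n_tests <- n_tests + 1L
            comp_rows[[length(comp_rows) + 1L]] <- data.frame(
              cohort_a = a$label, cohort_b = b$label, model = model,
              age_exposure = age, scope = "cumulative",
              factor_ratio_of_means = rf$ratio_of_means,
              factor_mean_ratio = rf$mean_ratio, factor_sem = rf$sem_ratio,
              p_value = rf$p_value, significant = rf$significant,
              degenerate = rf$degenerate, stringsAsFactors = FALSE
            )
            for (organ in sa$organ$organ) {
              ea <- sa$per_patient[[organ]]
              eb <- sb$per_patient[[organ]]
              if (is.null(eb)) next
              tt <- paired_t_test(ea, eb)
              n_tests <- n_tests + 1L
              comp_rows[[length(comp_rows) + 1L]] <- data.frame(
                cohort_a = a$label, cohort_b = b$label, model = model,
                age_exposure = age, scope = organ,
                factor_ratio_of_means = if (mean(eb) > 0) mean(ea) / mean(eb) else NA_real_,
                factor_mean_ratio = NA_real_, factor_sem = NA_real_,
                p_value = tt$p_value, significant = tt$significant,
                degenerate = tt$degenerate, stringsAsFactors = FALSE
              )
            }
          }
        }
      }
    }
  }

  delta_rows <- list()
  if (all(c(30, 50) %in% config$age_exposure)) {
    for (x in cohorts) {
      est <- compute_risk(x, models = config$models, age_exposure = c(30, 50),
                          age_attained = config$age_attained,
                          ear0_table = config$ear0_table,
                          alpha = config$alpha, delta = config$delta)
      de <- delta_ear(est)
      de$cohort <- x$label
      delta_rows[[length(delta_rows) + 1L]] <-
        de[, c("cohort", "patient_id", "organ", "model",
               "ear_30_70", "ear_50_70", "delta_ear")]
    }
  }

  structure(
    list(
      doses = do.call(rbind, dose_rows),
      organ_ear = do.call(rbind, organ_rows),
      cumulative_ear = do.call(rbind, cum_rows),
      comparisons = if (length(comp_rows) > 0L) do.call(rbind, comp_rows) else NULL,
      delta_ear = if (length(delta_rows) > 0L) do.call(rbind, delta_rows) else NULL,
      dispersion = config$dispersion,
      n_tests = n_tests
    ),
    class = "risk_report"
  )
}

#' Write a risk report to CSV files plus a text rendering
#'
#' One CSV per table (`doses.csv`, `organ_ear.csv`, `cumulative_ear.csv`,
#' `comparisons.csv`, `delta_ear.csv`, as available) at full numeric
#' precision, plus `report.txt` with the rounded human-readable
#' rendering.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "risk_report")) {
    abort_input("write_report(): not a 'risk_report' object")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (name in c("doses", "organ_ear", "cumulative_ear", "comparisons", "delta_ear")) {
    tab <- report[[name]]
    if (is.null(tab)) next
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    written <- c(written, path)
  }
  txt <- file.path(dir, "report.txt")
  writeLines(utils::capture.output(print(report)), txt)
  invisible(c(written, txt))
}

#' @export
print.risk_report <- function(x, ...) {
  disp <- if (identical(x$dispersion, "sem")) "sem" else "sd"
  cat("== Mean organ dose (Gy; mean +/- SEM) ==\n")
  d <- x$doses
  d$summary <- sprintf("%.2f +/- %.2f", d$mean_dose_gy, d$sem)
  print(d[, c("cohort", "organ", "summary")], row.names = FALSE)
  cat(sprintf("\n== Organ EAR (cases per 10,000 person-years; mean +/- %s) ==\n",
              toupper(disp)))
  o <- x$organ_ear
  o$summary <- sprintf("%d +/- %d", round(o$mean_ear), round(o[[disp]]))
  print(o[, c("cohort", "model", "age_exposure", "organ", "summary")],
        row.names = FALSE)
  cat(sprintf("\n== Cumulative EAR (mean +/- %s) ==\n", toupper(disp)))
  cu <- x$cumulative_ear
  cu$summary <- sprintf("%d +/- %d", round(cu$mean_ear), round(cu[[disp]]))
  print(cu[, c("cohort", "model", "age_exposure", "summary")], row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\n== Technique comparisons (factor = a/b on cumulative EAR) ==\n")
    cm <- x$comparisons[x$comparisons$scope == "cumulative", , drop = FALSE]
    cm$factor <- sprintf("%.1f", cm$factor_ratio_of_means)
    cm$p <- signif(cm$p_value, 3)
    print(cm[, c("cohort_a", "cohort_b", "model", "age_exposure",
                 "factor", "p", "significant")], row.names = FALSE)
    cat(sprintf("(%d paired t tests performed; no multiplicity correction)\n",
                x$n_tests))
  }
  if (!is.null(x$delta_ear)) {
    agg <- stats::aggregate(delta_ear ~ cohort + organ + model,
                            data = x$delta_ear, FUN = mean)
    cat("\n== Mean age-at-exposure EAR difference (exposure 30 - exposure 50) ==\n")
    agg$delta_ear <- round(agg$delta_ear, 1)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
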