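# DVH CSV dialect and cohort manifest I/O.
#
# One file holds one organ of one plan:
#   # patient=<id>
#   # organ=<name>
#   # form=differential|cumulative
#   # dose_unit=Gy
#   dose_gy,volume_fraction
#   <edge>,<value>
#   ...
#
# Cumulative files have one row per bin edge. Differential files also
# have one row per edge: rows 1..n carry the volume fraction of the bin
# starting at that edge and the final row carries 0, marking the closing
# edge. Numbers are written with 17 significant digits so write/read
# round trips are bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a DVH to the package CSV dialect
#'
#' @param x A valid [dvh].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_dvh()]
#' @export
write_dvh <- function(x, path) {
  assert_valid_dvh(x)
  header <- c(
    sprintf("# patient=%s", if (is.na(x$patient)) "" else x$patient),
    sprintf("# organ=%s", if (is.na(x$organ)) "" else x$organ),
    sprintf("# form=%s", x$form),
    "# dose_unit=Gy",
    sprintf("# rbe_weighted=%s", if (isTRUE(x$rbe_weighted)) "true" else "false")
  )
  if (!is.na(x$total_volume)) {
    header <- c(header, sprintf("# total_volume_cm3=%s", fmt_num(x$total_volume)))
  }
  vals <- if (x$form == "differential") c(x$values, 0) else x$values
  lines <- c(
    header,
    "dose_gy,volume_fraction",
    paste(fmt_num(x$edges), fmt_num(vals), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a DVH from the package CSV dialect
#'
#' @param path File written by [write_dvh()] (or following the same
#'   layout).
#' @return A [dvh] object. The file is validated after parsing; invariant
#'   violations raise a `scrisk_validation_error`.
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("DVH file not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  form <- meta[["form"]]
  if (is.null(form) || !form %in% c("differential", "cumulative")) {
    abort_input(sprintf("%s: missing or invalid '# form=' header", path))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || trimws(body[1L]) != "dose_gy,volume_fraction") {
    abort_input(sprintf("%s: expected 'dose_gy,volume_fraction' column header", path))
  }
  parts <- strsplit(body[-1L], ",", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort_input(sprintf("%s: malformed data row", path))
  }
  edges <- as.numeric(vapply(parts, `[[`, "", 1L))
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(edges) || anyNA(vals)) {
    abort_input(sprintf("%s: non-numeric data row", path))
  }
  values <- if (form == "differential") vals[-length(vals)] else vals
  blank_na <- function(s) if (is.null(s) || !nzchar(s)) NA_character_ else s
  out <- dvh(
    edges, values, form = form,
    organ = blank_na(meta[["organ"]]),
    patient = blank_na(meta[["patient"]]),
    total_volume = if (is.null(meta[["total_volume_cm3"]])) NA_real_ else
      as.numeric(meta[["total_volume_cm3"]]),
    rbe_weighted = identical(meta[["rbe_weighted"]], "true")
  )
  assert_valid_dvh(out, what = sprintf("DVH in %s", path))
  out
}

#' Write a cohort's DVHs and manifest to a directory
#'
#' Writes one DVH file per patient-organ pair plus `manifest.csv` with
#' columns `patient_id,group,technique,setup,organ,dvh_file` (paths
#' relative to the manifest).
#'
#' @param x A [cohort].
#' @param dir Output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(x, dir) {
  if (!inherits(x, "cohort")) abort_input("write_cohort(): not a 'cohort' object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in x$patients) {
    for (organ in names(p$dvhs)) {
      fname <- sprintf("%s_%s.csv", p$patient_id, organ)
      write_dvh(p$dvhs[[organ]], file.path(dir, fname))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, group = x$group, technique = x$technique,
        setup = x$setup, organ = organ, dvh_file = fname,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a cohort from a manifest CSV
#'
#' @param manifest Path to a manifest with columns
#'   `patient_id,group,technique,setup,organ,dvh_file`; DVH paths are
#'   resolved relative to the manifest's directory.
#' @param label Optional cohort label; defaults to
#'   `"<group>-<technique>-<setup>"`.
#' @return A [cohort].
#' @export
load_cohort <- function(manifest, label = NULL) {
  if (!file.exists(manifest)) {
    abort_input(sprintf("manifest not found: %s", manifest))
  }
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "technique", "setup", "organ", "dvh_file")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    abort_input(sprintf(
      "manifest %s lacks column(s): %s", manifest,
      paste(missing_cols, collapse = ", ")
    ))
  }
  base <- dirname(manifest)
  ids <- unique(tab$patient_id)
  patients <- lapply(ids, function(id) {
    sub <- tab[tab$patient_id == id, , drop = FALSE]
    dvhs <- stats::setNames(lapply(seq_len(nrow(sub)), function(i) {
      f <- sub$dvh_file[i]
      path <- if (file.exists(f)) f else file.path(base, f)
      read_dvh(path)
    }), sub$organ)
    patient_plan(patient_id = id, dvhs = dvhs)
  })
  grp <- unique(tab$group)
  tech <- unique(tab$technique)
  setup <- unique(tab$setup)
  if (length(grp) != 1L || length(tech) != 1L || length(setup) != 1L) {
    abort_input(sprintf(
      "manifest %s mixes groups, techniques or setups; one cohort per manifest",
      manifest
    ))
  }
  if (is.null(label)) label <- sprintf("%s-%s-%s", grp, tech, setup)
  cohort(label = label, patients = patients, group = grp,
         technique = tech, setup = setup)
}
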