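# Dose-volume histogram data model.
#
# A DVH stores the distribution of absorbed dose over an organ volume,
# either as a differential histogram (volume fraction per dose bin) or as
# a cumulative one (volume fraction receiving at least each edge dose).
# Volumes are fractions of the organ volume; the absolute volume in cm^3
# is optional metadata only, since the organ-equivalent-dose sums use the
# volume-normalised form.

# volume-fraction normalisation tolerance for validation
.norm_tol <- 1e-9

#' Construct a dose-volume histogram
#'
#' @param edges Numeric vector of bin-edge doses in Gy, non-negative and
#'   strictly increasing, length `n + 1` for `n` bins.
#' @param values For `form = "differential"`, a length-`n` vector of
#'   per-bin volume fractions (summing to 1 for a whole-organ DVH). For
#'   `form = "cumulative"`, a length-`n + 1` vector giving the volume
#'   fraction receiving at least each edge dose (non-increasing, starting
#'   at 1).
#' @param form Either `"differential"` or `"cumulative"`.
#' @param organ,patient Optional identifying labels.
#' @param total_volume Optional absolute organ volume in cm^3 (metadata
#'   only; all computations use volume fractions).
#' @param rbe_weighted Logical flag recording that doses are RBE-weighted
#'   Gy(RBE), as for proton plans computed with a constant RBE of 1.1.
#'   Bookkeeping only: no conversion is ever applied.
#'
#' @details The constructor performs type coercion only; use
#'   [validate_dvh()] to obtain a full list of invariant violations.
#'   Computational functions reject invalid DVHs with a classed
#'   `scrisk_validation_error`.
#'
#' @return An object of class `"dvh"`.
#' @seealso [validate_dvh()], [as_differential()], [mean_dose()]
#' @export
#' @examples
#' d <- dvh(edges = c(0, 25, 50), values = c(0.5, 0.5), form = "differential")
#' mean_dose(d)
dvh <- function(edges, values, form = c("differential", "cumulative"),
                organ = NA_character_, patient = NA_character_,
                total_volume = NA_real_, rbe_weighted = FALSE) {
  form <- match.arg(form)
  if (!is.numeric(edges) || !is.numeric(values)) {
    abort_input("dvh(): 'edges' and 'values' must be numeric")
  }
  structure(
    list(
      edges = as.numeric(edges),
      values = as.numeric(values),
      form = form,
      organ = as.character(organ),
      patient = as.character(patient),
      total_volume = as.numeric(total_volume),
      rbe_weighted = isTRUE(rbe_weighted)
    ),
    class = "dvh"
  )
}

#' Check DVH invariants
#'
#' Returns a data frame of invariant violations rather than throwing, so
#' callers can decide how to react. An empty data frame means the DVH is
#' valid.
#'
#' Rules checked: edges non-negative and strictly increasing; value vector
#' length consistent with the form; differential values non-negative and
#' summing to 1 within `1e-9`; cumulative values in `[0, 1]`,
#' non-increasing, with first value 1 within `1e-9`.
#'
#' @param x A [dvh] object.
#' @return A data frame with columns `rule`, `index` (1-based position of
#'   the offending entry, `NA` for non-positional rules) and `message`;
#'   zero rows when all invariants hold.
#' @export
#' @examples
#' bad <- dvh(c(0, 25, 50), c(1.0, 0.4, 0.6), form = "cumulative")
#' validate_dvh(bad)
validate_dvh <- function(x) {
  if (!inherits(x, "dvh")) abort_input("validate_dvh(): not a 'dvh' object")
  v <- list()
  add <- function(rule, index, message) {
    v[[length(v) + 1L]] <<- data.frame(
      rule = rule, index = as.integer(index), message = message,
      stringsAsFactors = FALSE
    )
  }
  e <- x$edges
  val <- x$values
  if (length(e) < 2L) {
    add("edges", NA, "at least two bin edges are required")
  } else {
    bad <- which(!is.finite(e) | e < 0)
    for (i in bad) add("edge_nonnegative", i, sprintf("edge %d is negative or non-finite", i))
    nondec <- which(diff(e) <= 0)
    for (i in nondec) add("edge_increasing", i + 1L,
                          sprintf("edge %d does not exceed edge %d", i + 1L, i))
  }
  n_bins <- length(e) - 1L
  expected <- if (x$form == "differential") n_bins else n_bins + 1L
  if (length(val) != expected) {
    add("length", NA, sprintf(
      "%s DVH with %d bins requires %d values, got %d",
      x$form, n_bins, expected, length(val)
    ))
    return(do.call(rbind, v))
  }
  if (any(!is.finite(val))) {
    for (i in which(!is.finite(val))) add("finite_value", i, "non-finite value")
    return(do.call(rbind, v))
  }
  if (x$form == "differential") {
    for (i in which(val < 0)) add("negative_value", i, sprintf("bin %d has negative volume", i))
    s <- sum(val)
    if (abs(s - 1) > .norm_tol) {
      add("normalization", NA, sprintf("volume fractions sum to %.12g, expected 1", s))
    }
  } else {
    for (i in which(val < 0 | val > 1)) add("range", i, sprintf("value %d outside [0, 1]", i))
    for (i in which(diff(val) > 0)) add("monotonicity", i + 1L,
                                        sprintf("value %d exceeds value %d", i + 1L, i))
    if (abs(val[1L] - 1) > .norm_tol) {
      add("first_value", 1L, sprintf("first cumulative value is %.12g, expected 1", val[1L]))
    }
  }
  if (length(v) == 0L) {
    data.frame(rule = character(), index = integer(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

# stop with a validation error if the DVH breaks any invariant
assert_valid_dvh <- function(x, what = "DVH") {
  viol <- validate_dvh(x)
  if (nrow(viol) > 0L) {
    abort_validation(sprintf(
      "invalid %s (%s%s): %s", what,
      if (is.na(x$patient)) "" else paste0("patient ", x$patient, ", "),
      if (is.na(x$organ)) "unknown organ" else x$organ,
      paste(unique(viol$rule), collapse = ", ")
    ))
  }
  invisible(x)
}

# representative dose of each bin: the bin centre (unbiased for dose
# piecewise-uniform within bins)
bin_centers <- function(x) {
  (x$edges[-length(x$edges)] + x$edges[-1L]) / 2
}

bin_widths <- function(x) diff(x$edges)

#' Convert a DVH to differential form
#'
#' The differential value of bin *i* is the finite difference
#' `cumulative(edge_i) - cumulative(edge_{i+1})`; a differential input is
#' returned unchanged. The conversion pair with [as_cumulative()] is an
#' exact round trip.
#'
#' @param x A valid [dvh].
#' @return A differential [dvh] on the same edges.
#' @export
as_differential <- function(x) {
  if (!inherits(x, "dvh")) abort_input("as_differential(): not a 'dvh' object")
  if (x$form == "differential") return(x)
  assert_valid_dvh(x)
  out <- x
  out$form <- "differential"
  out$values <- -diff(x$values)
  out
}

#' Convert a DVH to cumulative form
#'
#' The cumulative value at edge *k* is the total volume fraction of bins
#' at or above that edge; the value at the final edge is 0. When the
#' differential DVH sums to 1 the first cumulative value is 1.
#'
#' @param x A valid [dvh].
#' @return A cumulative [dvh] on the same edges.
#' @export
as_cumulative <- function(x) {
  if (!inherits(x, "dvh")) abort_input("as_cumulative(): not a 'dvh' object")
  if (x$form == "cumulative") return(x)
  assert_valid_dvh(x)
  out <- x
  out$form <- "cumulative"
  out$values <- c(rev(cumsum(rev(x$values))), 0)
  out
}

#' Mean organ dose
#'
#' `sum(v_i * D_i)` over differential bins with `D_i` the bin centre;
#' cumulative input is converted internally. Equals the organ equivalent
#' dose under the linear dose-response model.
#'
#' @param x A valid [dvh].
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(x) {
  d <- as_differential(x)
  assert_valid_dvh(d)
  sum(d$values * bin_centers(d))
}

#' Rebin a DVH onto a uniform dose grid
#'
#' Each source bin's volume is treated as a point mass at the bin centre
#' and reassigned to the destination bin containing it, so total volume is
#' conserved exactly and the mean dose moves by at most half the new bin
#' width. Rebinning a uniform grid onto the same width is the identity.
#'
#' @param x A valid [dvh] (either form; output is differential).
#' @param new_bin_width Positive bin width in Gy of the destination grid,
#'   which starts at 0.
#' @return A differential [dvh] on the new grid.
#' @export
rebin_dvh <- function(x, new_bin_width) {
  if (!is.numeric(new_bin_width) || length(new_bin_width) != 1L ||
      !is.finite(new_bin_width) || new_bin_width <= 0) {
    abort_config("rebin_dvh(): 'new_bin_width' must be a positive number")
  }
  d <- as_differential(x)
  assert_valid_dvh(d)
  centers <- bin_centers(d)
  n_new <- max(1L, ceiling(max(d$edges) / new_bin_width))
  new_edges <- seq(0, by = new_bin_width, length.out = n_new + 1L)
  idx <- findInterval(centers, new_edges, rightmost.closed = TRUE, all.inside = TRUE)
  new_values <- numeric(n_new)
  acc <- tapply(d$values, factor(idx, levels = seq_len(n_new)), sum)
  new_values[!is.na(acc)] <- acc[!is.na(acc)]
  out <- d
  out$edges <- new_edges
  out$values <- new_values
  out
}

#' Build a differential DVH from a per-voxel dose list
#'
#' Bins explicit voxel doses on a uniform grid starting at 0. Useful both
#' for constructing DVHs from sampled dose distributions and as the
#' brute-force reference in histogram-accuracy checks.
#'
#' @param doses Numeric vector of non-negative voxel doses in Gy.
#' @param bin_width Bin width in Gy (default 0.05).
#' @inheritParams dvh
#' @return A differential [dvh]; each voxel carries volume `1/length(doses)`.
#' @export
dvh_from_doses <- function(doses, bin_width = 0.05,
                           organ = NA_character_, patient = NA_character_,
                           rbe_weighted = FALSE) {
  if (!is.numeric(doses) || length(doses) == 0L || any(!is.finite(doses)) ||
      any(doses < 0)) {
    abort_input("dvh_from_doses(): 'doses' must be non-negative finite numbers")
  }
  n_bins <- max(1L, ceiling(max(doses) / bin_width))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  idx <- findInterval(doses, edges, rightmost.closed = TRUE, all.inside = TRUE)
  values <- tabulate(idx, nbins = n_bins) / length(doses)
  dvh(edges, values, form = "differential", organ = organ, patient = patient,
      rbe_weighted = rbe_weighted)
}

#' Single-bin DVH for a uniformly irradiated organ
#'
#' Places all volume in one bin centred exactly on `dose`, so the mean
#' dose and all organ-equivalent-dose closed forms are reproduced without
#' discretisation error. Doses below half a bin width fall back to the
#' first grid bin `[0, bin_width]`.
#'
#' @param dose Uniform organ dose in Gy.
#' @param bin_width Bin width in Gy.
#' @inheritParams dvh
#' @return A differential [dvh] with a single bin.
#' @export
#' @examples
#' mean_dose(uniform_dvh(2))  # exactly 2 Gy
uniform_dvh <- function(dose, bin_width = 0.05,
                        organ = NA_character_, patient = NA_character_,
                        rbe_weighted = FALSE) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    abort_input("uniform_dvh(): 'dose' must be a single non-negative number")
  }
  edges <- if (dose >= bin_width / 2) {
    c(dose - bin_width / 2, dose + bin_width / 2)
  } else {
    c(0, bin_width)
  }
  dvh(edges, 1, form = "differential", organ = organ, patient = patient,
      rbe_weighted = rbe_weighted)
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf(
    "<dvh> %s DVH%s%s: %d bins, %g-%g Gy, mean %.3f Gy%s\n",
    x$form,
    if (is.na(x$organ)) "" else paste0(" of ", x$organ),
    if (is.na(x$patient)) "" else paste0(" (patient ", x$patient, ")"),
    length(x$edges) - 1L, min(x$edges), max(x$edges),
    tryCatch(mean_dose(x), error = function(e) NA_real_),
    if (isTRUE(x$rbe_weighted)) ", Gy(RBE)" else ""
  ))
  invisible(x)
}
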