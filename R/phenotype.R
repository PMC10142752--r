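#' Fit a high/low intensity cutoff for one marker
#'
#' The `valley` method fits a kernel-density estimate to log-intensities,
#' locates the two largest modes, and places the cutoff at the density
#' minimum between them — appropriate when distinct low- and high-expressing
#' populations are visible (as for Iba1). When the density is effectively
#' unimodal the method falls back, with a warning, to the `quantile` method.
#' `manual` records a user-chosen value, the pathway used for markers whose
#' cutoffs are set from scatter-plot structure by eye.
#'
#' Cells should be pooled across all cases before fitting, so that a single
#' cutoff applies to every group.
#'
#' @param intensities positive per-cell intensities for one marker.
#' @param method `"valley"`, `"quantile"` or `"manual"`.
#' @param manual_value cutoff for `method = "manual"`.
#' @param quantile_p upper-quantile probability for the `quantile` method
#'   (and the valley fallback); default 0.9.
#' @return A `moi_threshold`: list with `cutoff`, `provenance` (`"manual"`
#'   or `"fitted"`), `method`, and fitting `diagnostics` (mode locations and
#'   valley depth) when fitted.
#' @export
fit_threshold <- function(intensities,
                          method = c("valley", "quantile", "manual"),
                          manual_value = NULL, quantile_p = 0.9) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(manual_value)) {
      stop("manual_value required for method = 'manual'", call. = FALSE)
    }
    return(structure(list(cutoff = manual_value, provenance = "manual",
                          method = "manual", diagnostics = NULL),
                     class = "moi_threshold"))
  }
  x <- intensities[is.finite(intensities) & intensities > 0]
  if (length(x) < 100L) {
    stop("fitted threshold methods require >= 100 cells", call. = FALSE)
  }
  if (method == "quantile") {
    return(structure(list(cutoff = as.numeric(quantile(x, quantile_p)),
                          provenance = "fitted", method = "quantile",
                          diagnostics = list(quantile_p = quantile_p)),
                     class = "moi_threshold"))
  }
  lx <- log(x)
  if (stats::sd(lx) < 1e-12) {
    warning("valley method: degenerate (constant) intensities; ",
            "falling back to quantile cutoff")
    return(structure(list(cutoff = as.numeric(quantile(x, quantile_p)),
                          provenance = "fitted", method = "quantile_fallback",
                          diagnostics = NULL), class = "moi_threshold"))
  }
  d <- density(lx, n = 1024)
  y <- d$y
  # interior local maxima of the KDE, ignoring tail wiggles below 5% of
  # the dominant mode
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] >= 0.05 * max(y)]
  if (length(peaks) >= 2L) {
    top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
    lo <- min(top2); hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1L
  }
  # a shallow dip between "modes" is noise on a unimodal curve, not a
  # genuine low/high split
  if (length(peaks) < 2L || y[valley] > 0.9 * min(y[top2])) {
    warning("valley method: density is effectively unimodal; ",
            "falling back to quantile cutoff")
    return(structure(list(cutoff = as.numeric(quantile(x, quantile_p)),
                          provenance = "fitted", method = "quantile_fallback",
                          diagnostics = list(n_modes = length(peaks))),
                     class = "moi_threshold"))
  }
  structure(
    list(cutoff = exp(d$x[valley]), provenance = "fitted", method = "valley",
         diagnostics = list(
           mode_locations = exp(d$x[top2]),
           valley_depth = min(y[top2]) - y[valley])),
    class = "moi_threshold"
  )
}

#' @export
print.moi_threshold <- function(x, ...) {
  cat(sprintf("<moi_threshold> cutoff %.4g (%s, %s)\n",
              x$cutoff, x$method, x$provenance))
  invisible(x)
}

#' Fit cutoffs for several markers at once
#'
#' @param cells cell table with one intensity column per marker.
#' @param markers markers to fit.
#' @param method,manual_values see [fit_threshold()]; `manual_values` is a
#'   named vector used for `method = "manual"`.
#' @param quantile_p see [fit_threshold()].
#' @return A named list of `moi_threshold`s (a threshold set).
#' @export
fit_thresholds <- function(cells, markers = GLIAMUX_MARKERS,
                           method = "valley", manual_values = NULL,
                           quantile_p = 0.9) {
  out <- lapply(markers, function(m) {
    if (method == "manual") {
      fit_threshold(cells[[m]], "manual", manual_value = manual_values[[m]])
    } else {
      fit_threshold(cells[[m]], method, quantile_p = quantile_p)
    }
  })
  names(out) <- markers
  out
}

threshold_cutoffs <- function(thresholds) {
  vapply(thresholds, function(t) {
    if (inherits(t, "moi_threshold")) t$cutoff else as.numeric(t)
  }, numeric(1))
}

#' Gate cells high/low per marker
#'
#' Appends a logical `<marker>_high` column per marker: `TRUE` when the
#' cell's mean intensity is strictly above the cutoff (a cell exactly at
#' the cutoff is low). Idempotent; other columns are untouched.
#'
#' @param cells cell table.
#' @param thresholds named list of `moi_threshold`s or named numeric cutoffs.
#' @return `cells` with the flag columns appended.
#' @export
classify_moi <- function(cells, thresholds) {
  cut <- threshold_cutoffs(thresholds)
  missing_m <- setdiff(names(cut), names(cells))
  if (length(missing_m)) {
    stop(sprintf("input error: marker column(s) %s missing from cell table",
                 paste(missing_m, collapse = ", ")), call. = FALSE)
  }
  for (m in names(cut)) {
    cells[[paste0(m, "_high")]] <- cells[[m]] > cut[[m]]
  }
  cells
}

#' Percentage of MOI-high cells per case and region
#'
#' @param cells gated cell table (see [classify_moi()]).
#' @param markers markers to summarise.
#' @return Long data.frame: `case_id`, `group`, `region`, `marker`,
#'   `pct_high`, `n_cells`.
#' @export
percent_high <- function(cells, markers = GLIAMUX_MARKERS) {
  flags <- paste0(markers, "_high")
  missing_f <- setdiff(flags, names(cells))
  if (length(missing_f)) {
    stop("input error: run classify_moi() first (missing flag columns)",
         call. = FALSE)
  }
  key <- interaction(cells$case_id, cells$region, drop = TRUE)
  groups <- split(seq_len(nrow(cells)), key)
  rows <- lapply(groups, function(ix) {
    n <- length(ix)
    data.frame(case_id = cells$case_id[ix[1]],
               group = cells$group[ix[1]],
               region = cells$region[ix[1]],
               marker = markers,
               pct_high = vapply(flags, function(f) {
                 100 * mean(cells[[f]][ix])
               }, numeric(1)),
               n_cells = n, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
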