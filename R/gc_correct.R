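#' Fit a per-sample GC bias curve
#'
#' Locally weighted regression (robust `lowess`) of raw bin count on bin GC
#' fraction over the usable bins of one sample. The curve is evaluated by
#' linear interpolation between the smoother's knots, held flat outside the
#' observed GC range. `reference_level` is the median fitted value over the
#' usable bins; correction rescales each bin by
#' `reference_level / curve(gc)`, so a flat curve leaves counts unchanged.
#'
#' Bias is library-specific, so one curve is fitted per sample.
#'
#' @param counts Numeric vector of raw counts for one sample (length =
#'   bins), or a 1-row `bin_count_matrix`.
#' @param grid The matching GC-annotated `bin_grid`.
#' @param span `lowess` smoother span (default 0.3).
#' @return A list of class `gc_curve`: `predict(gc)` function, `span`,
#'   `reference_level`, `gc_range`, `n_bins`.
#' @export
fit_gc_curve <- function(counts, grid, span = 0.3) {
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == 1)
    counts <- counts[1, ]
  }
  stopifnot(length(counts) == nrow(grid))
  ok <- grid$usable & !is.na(grid$gc) & !is.na(counts)
  if (sum(ok) < 50)
    stop("GC curve needs >= 50 usable GC-annotated bins, got ", sum(ok),
         call. = FALSE)
  lo <- stats::lowess(grid$gc[ok], counts[ok], f = span)
  fn <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  ref <- stats::median(fn(grid$gc[ok]))
  if (ref <= 0) stop("degenerate GC curve: non-positive reference level",
                     call. = FALSE)
  structure(list(predict = fn, span = span, reference_level = ref,
                 gc_range = range(grid$gc[ok]), n_bins = sum(ok)),
            class = "gc_curve")
}

#' Apply a GC correction curve to one sample's counts
#'
#' `corrected = raw * reference_level / curve(gc)` for usable bins; unusable
#' or GC-missing bins become `NA`. Bins where the fitted curve is not
#' positive are masked (`NA`) with a warning. Corrected counts are
#' non-negative reals and are not re-rounded.
#'
#' @param counts Numeric vector (or 1-row matrix) of raw counts.
#' @param curve A `gc_curve` fitted on the same grid.
#' @param grid The `bin_grid`.
#' @return Numeric vector of corrected counts.
#' @export
apply_gc_correction <- function(counts, curve, grid) {
  if (is.matrix(counts)) counts <- counts[1, ]
  stopifnot(inherits(curve, "gc_curve"), length(counts) == nrow(grid))
  fitted <- rep(NA_real_, nrow(grid))
  ok <- grid$usable & !is.na(grid$gc)
  fitted[ok] <- curve$predict(grid$gc[ok])
  bad <- ok & fitted <= 0
  if (any(bad)) {
    warning(sum(bad), " bin(s) with non-positive fitted GC level masked")
    fitted[bad] <- NA_real_
  }
  out <- counts * curve$reference_level / fitted
  out[!ok] <- NA_real_
  out
}

#' GC-correct a whole count matrix
#'
#' Fits one curve per sample and applies it; the standard preprocessing
#' step between raw counting and arm aggregation.
#'
#' @param counts A raw `bin_count_matrix`.
#' @param grid The GC-annotated `bin_grid`.
#' @param span Smoother span passed to [fit_gc_curve()].
#' @return A `bin_count_matrix` with stage `"gc_corrected"`.
#' @export
gc_correct <- function(counts, grid, span = 0.3) {
  out <- matrix(NA_real_, nrow = nrow(counts), ncol = ncol(counts),
                dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    curve <- fit_gc_curve(counts[i, ], grid, span = span)
    out[i, ] <- apply_gc_correction(counts[i, ], curve, grid)
  }
  bin_count_matrix(out, stage = "gc_corrected")
}
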