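#' Aggregate bin counts to arm read-fractions
#'
#' Sums (corrected) counts over each arm's usable bins and divides by the
#' sample total over all included arms, so each row sums to 1. Fractions,
#' not raw arm counts, are the z-scored quantity: they make samples of
#' different sequencing yield directly comparable. Missing bins are
#' excluded from numerator and denominator alike.
#'
#' @param counts A `bin_count_matrix` (GC-corrected in the standard
#'   pipeline; raw counts are accepted for diagnostic use).
#' @param grid The matching `bin_grid`.
#' @return Matrix samples x arms of fractions; rows sum to 1.
#' @export
arm_fractions <- function(counts, grid) {
  stopifnot(ncol(counts) == nrow(grid))
  arms <- unique(grid$arm)
  x <- unclass(counts)
  x[, !grid$usable] <- NA
  frac <- matrix(0, nrow(x), length(arms),
                 dimnames = list(rownames(x), arms))
  for (a in arms)
    frac[, a] <- rowSums(x[, grid$arm == a, drop = FALSE], na.rm = TRUE)
  tot <- rowSums(frac)
  zero <- tot <= 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(rownames(x)[zero], collapse = ", "),
         call. = FALSE)
  frac / tot
}

#' Fit a normal-control reference panel
#'
#' Per-arm sample mean and sample standard deviation (denominator n - 1) of
#' control arm fractions: the empirical null model for z-scores. The
#' control fractions are retained so leave-one-out scoring can refit the
#' panel without a given control.
#'
#' @param control_fractions Arm-fraction matrix of the controls (rows named
#'   by sample id).
#' @return List of class `reference_panel`: `mean`, `sd` (named by arm),
#'   `n_controls`, `control_ids`, `control_fractions`, `loo_supported`.
#' @export
fit_reference <- function(control_fractions) {
  n <- nrow(control_fractions)
  if (n < 3) stop("reference panel needs >= 3 controls", call. = FALSE)
  mu <- colMeans(control_fractions)
  sigma <- apply(control_fractions, 2, stats::sd)
  if (any(sigma == 0))
    stop("degenerate panel: zero variance for arm(s) ",
         paste(names(sigma)[sigma == 0], collapse = ", "), call. = FALSE)
  structure(list(mean = mu, sd = sigma, n_controls = n,
                 control_ids = rownames(control_fractions),
                 control_fractions = control_fractions,
                 loo_supported = TRUE),
            class = "reference_panel")
}

#' Arm z-scores against a reference panel
#'
#' `z = (f - mu) / sigma` per arm. For panel controls, with leave-one-out
#' enabled (default), `mu` and `sigma` are recomputed excluding that sample
#' so a control is never compared against a null it helped define —
#' self-inclusion deflates |z|.
#'
#' @param fractions Arm-fraction matrix (cases and/or controls).
#' @param panel A `reference_panel`.
#' @param control_ids Sample ids (rows of `fractions`) that are panel
#'   members; each must be present in the panel.
#' @param leave_one_out Logical (default `TRUE`).
#' @return Matrix samples x arms of z-scores.
#' @export
z_scores <- function(fractions, panel, control_ids = NULL,
                     leave_one_out = TRUE) {
  stopifnot(inherits(panel, "reference_panel"))
  arms <- names(panel$mean)
  stopifnot(identical(colnames(fractions), arms))
  missing <- setdiff(control_ids, panel$control_ids)
  if (length(missing))
    stop("control sample(s) not in the panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  z <- sweep(sweep(fractions, 2, panel$mean), 2, panel$sd, "/")
  if (leave_one_out && length(control_ids)) {
    for (id in intersect(control_ids, rownames(fractions))) {
      keep <- setdiff(panel$control_ids, id)
      sub <- panel$control_fractions[keep, , drop = FALSE]
      mu <- colMeans(sub)
      sigma <- apply(sub, 2, stats::sd)
      z[id, ] <- (fractions[id, ] - mu) / sigma
    }
  }
  z
}

#' Call arm-level gains and losses from z-scores
#'
#' Strict-threshold rule: `z > threshold` is a gain, `z < -threshold` a
#' loss, anything else (including the boundary exactly) neutral. A sample
#' is positive when at least one arm is non-neutral.
#'
#' @param z Matrix samples x arms of z-scores.
#' @param z_threshold Call threshold (default 2.96).
#' @return List of class `arm_callset`: `z`, `call` (character matrix),
#'   `sample_positive` (named logical), `z_threshold`.
#' @export
call_arms <- function(z, z_threshold = 2.96) {
  stopifnot(z_threshold > 0)
  call <- matrix("neutral", nrow(z), ncol(z), dimnames = dimnames(z))
  call[z > z_threshold] <- "gain"
  call[z < -z_threshold] <- "loss"
  structure(list(z = z, call = call,
                 sample_positive = apply(call != "neutral", 1, any),
                 z_threshold = z_threshold),
            class = "arm_callset")
}

#' Cohort-level detection performance
#'
#' Sensitivity = positive cases / cases, specificity = negative controls /
#' controls (both in percent), with positive cases stratified into
#' early (I-II) and late (III-IV) stage.
#'
#' @param calls An `arm_callset` covering every sample in `meta`.
#' @param meta Data frame with `sample_id`, `group`, `stage`.
#' @return List of class `cohort_eval`: `sensitivity`, `specificity`
#'   (percent), `counts` (named integer vector), `positives_by_stage`.
#' @export
evaluate_cohort <- function(calls, meta) {
  pos <- calls$sample_positive[meta$sample_id]
  if (anyNA(pos)) stop("samples missing from the call set", call. = FALSE)
  case <- meta$group == "case"
  n_cases <- sum(case); n_controls <- sum(!case)
  tp <- sum(pos & case); fp <- sum(pos & !case)
  early <- case & meta$stage %in% c("I", "II")
  late <- case & meta$stage %in% c("III", "IV")
  structure(list(
    sensitivity = 100 * tp / n_cases,
    specificity = 100 * (n_controls - fp) / n_controls,
    counts = c(cases = n_cases, controls = n_controls,
               case_positive = tp, case_negative = n_cases - tp,
               control_positive = fp, control_negative = n_controls - fp),
    positives_by_stage = c(early = sum(pos & early),
                           late = sum(pos & late))),
    class = "cohort_eval")
}

#' Per-arm alteration prevalence among positive cases
#'
#' Counts, for each arm, how many z-score-positive cases carry a gain and
#' how many a loss (each sample contributes at most one to each tally);
#' negative samples and controls contribute nothing.
#'
#' @param calls An `arm_callset`.
#' @param meta Cohort metadata.
#' @return Data frame `arm`, `gain_count`, `loss_count`, with attribute
#'   `n_positive_cases`.
#' @export
arm_prevalence <- function(calls, meta) {
  ids <- meta$sample_id[meta$group == "case"]
  ids <- ids[calls$sample_positive[ids]]
  sub <- calls$call[ids, , drop = FALSE]
  out <- data.frame(arm = colnames(sub),
                    gain_count = colSums(sub == "gain"),
                    loss_count = colSums(sub == "loss"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_positive_cases") <- length(ids)
  out
}

#' Write / read an arm call set
#'
#' `write_callset` writes `z.tsv` (samples x arms z matrix) and `calls.tsv`
#' (call labels) into a directory; the round trip through `read_callset` is
#' lossless.
#'
#' @param calls An `arm_callset`.
#' @param dir Output directory.
#' @export
write_callset <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.table(
    data.frame(sample_id = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(calls$z, "z.tsv")
  wr(calls$call, "calls.tsv")
  writeLines(as.character(calls$z_threshold),
             file.path(dir, "z_threshold.txt"))
  invisible(dir)
}

#' @rdname write_callset
#' @export
read_callset <- function(dir) {
  rd <- function(f) as.matrix(utils::read.table(
    file.path(dir, f), sep = "\t", header = TRUE, row.names = 1,
    check.names = FALSE))
  z <- rd("z.tsv")
  storage.mode(z) <- "double"
  thr <- as.numeric(readLines(file.path(dir, "z_threshold.txt")))
  out <- call_arms(z, thr)
  out$call <- rd("calls.tsv")  # preserve stored labels verbatim
  out
}

#' Export heatmap-ready matrices
#'
#' Writes the samples x arms z matrix and a tri-level call coding (gain
#' +1, neutral 0, loss -1) as TSV for plotting.
#'
#' @param calls An `arm_callset`.
#' @param path Output TSV path for the coded matrix; the z matrix goes to
#'   `<path>` with suffix `".z.tsv"` appended.
#' @return The coded matrix, invisibly.
#' @export
export_heatmap <- function(calls, path) {
  code <- matrix(0L, nrow(calls$call), ncol(calls$call),
                 dimnames = dimnames(calls$call))
  code[calls$call == "gain"] <- 1L
  code[calls$call == "loss"] <- -1L
  wr <- function(m, f) utils::write.table(
    data.frame(sample_id = rownames(m), m, check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  wr(code, path)
  wr(calls$z, paste0(path, ".z.tsv"))
  invisible(code)
}
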