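#' Default per-arm gain/loss probabilities for simulated lung-cancer cases
#'
#' Event probabilities apply to cases that carry any copy-number signal at
#' all (CNV-flat cases are drawn separately) and encode the per-arm
#' alteration frequencies reported for plasma-positive lung-cancer patients:
#' recurrent gains on 3q and 8q (7/21 each), 12p (6/21) and 7q (5/21);
#' recurrent losses on 22q (8/21), 3p (7/21) and 5q/16q/10q/15q (6/21 each);
#' 1p at 1/21 gain, 4/21 loss. Arms without a reported frequency get a 1/21
#' background rate in each direction.
#'
#' The `"separable"` variant gives every non-flat case the complete
#' five-arm signature the classifier work identifies as discriminative
#' (gains 3q, 8q; losses 3p, 10q, 22q) and silences the remaining arms, so
#' that every case is visible to a classifier restricted to any subset of
#' those arms. Independent sub-unit per-arm draws cannot guarantee that: a
#' case whose only events fall on arms a greedy gain-based selection
#' happens to drop becomes invisible to the final model.
#'
#' @param arms An `arm_table`.
#' @param variant `"full"` (default) or `"separable"`.
#' @return Data frame with columns `arm`, `gain_prob`, `loss_prob` over the
#'   included arms.
#' @export
default_arm_event_table <- function(arms, variant = c("full", "separable")) {
  variant <- match.arg(variant)
  arm <- arms$arm[arms$included]
  gain <- stats::setNames(rep(0, length(arm)), arm)
  loss <- gain
  if (variant == "full") {
    gain[] <- 1 / 21
    loss[] <- 1 / 21
    gain[c("3q", "8q")] <- 7 / 21
    gain["12p"] <- 6 / 21
    gain["7q"] <- 5 / 21
    loss["22q"] <- 8 / 21
    loss["3p"] <- 7 / 21
    loss[c("5q", "16q", "10q", "15q")] <- 6 / 21
    loss["1p"] <- 4 / 21
  } else {
    gain[c("3q", "8q")] <- 1
    loss[c("3p", "10q", "22q")] <- 1
  }
  data.frame(arm = arm, gain_prob = unname(gain[arm]),
             loss_prob = unname(loss[arm]), stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Assembles and validates the full set of generator parameters. Defaults
#' reproduce the study cohort structure: 41 cases with stage quotas
#' 20/6/11/4 (I-IV) drawn as exact quotas, 40 controls, case cfDNA
#' concentrations averaging 0.12 ng/uL (stage IV highest at 0.14) versus
#' 0.09 ng/uL in controls, ~10^6 counted reads per sample, quadratic GC
#' bias, negative-binomial overdispersion, and 20/41 of cases CNV-flat.
#' Tumour fractions by stage (means 0.10/0.15/0.20/0.30) are declared
#' assumptions: the study reports none.
#'
#' @param arms `arm_table` whose included arms the cohort covers.
#' @param n_cases,n_controls Cohort sizes.
#' @param stage_weights Named probabilities over stages I-IV for cases.
#' @param stage_quotas If `TRUE`, case stage counts are the exact rounded
#'   quotas `n_cases * stage_weights` instead of multinomial draws.
#' @param arm_event_table Per-arm gain/loss probabilities for non-flat
#'   cases (see [default_arm_event_table()]).
#' @param tumor_fraction_by_stage Data frame `stage`, `mean`, `sd`;
#'   tumour fraction is drawn normal and truncated to `[tf_min, 1]`.
#' @param tf_min Lower truncation for case tumour fraction.
#' @param concentration_by_group_stage Data frame `group`, `stage`,
#'   `meanlog`, `sdlog` of log-normal concentration distributions (ng/uL).
#' @param reads_per_sample Expected total counted reads per sample.
#' @param gc_bias Quadratic coefficients `c(a0, a1, a2)`; relative coverage
#'   `a0 + a1*gc + a2*gc^2`, floored at 0.05 and normalised to mean 1.
#' @param dispersion Negative-binomial overdispersion phi > 0
#'   (variance = mu + phi * mu^2).
#' @param fraction_flat_cases Probability a case carries no arm event.
#' @param seed Integer seed recorded in the config; the generator functions
#'   derive their streams from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(arms = build_arm_table("hg19"),
                       n_cases = 41, n_controls = 40,
                       stage_weights = c(I = 20, II = 6, III = 11, IV = 4) / 41,
                       stage_quotas = TRUE,
                       arm_event_table = default_arm_event_table(arms),
                       tumor_fraction_by_stage = data.frame(
                         stage = c("I", "II", "III", "IV"),
                         mean = c(0.10, 0.15, 0.20, 0.30),
                         sd = 0.05),
                       tf_min = 0.02,
                       concentration_by_group_stage = default_concentration_table(),
                       reads_per_sample = 1e6,
                       gc_bias = c(-1.8, 14, -17),
                       dispersion = 0.01,
                       fraction_flat_cases = 20 / 41,
                       seed = 1L) {
  cfg <- list(arms = arms, n_cases = n_cases, n_controls = n_controls,
              stage_weights = stage_weights, stage_quotas = stage_quotas,
              arm_event_table = arm_event_table,
              tumor_fraction_by_stage = tumor_fraction_by_stage,
              tf_min = tf_min,
              concentration_by_group_stage = concentration_by_group_stage,
              reads_per_sample = reads_per_sample, gc_bias = gc_bias,
              dispersion = dispersion,
              fraction_flat_cases = fraction_flat_cases,
              require_event_arms = NULL,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Log-normal concentration parameters calibrated so that with the 20/6/11/4
# stage quotas the case mean is 0.12 ng/uL with stage IV at 0.14 and range
# ~0.07-0.25, and the control mean is 0.09 with range ~0.06-0.15.
default_concentration_table <- function() {
  mean_to_meanlog <- function(m, sdlog) log(m) - sdlog^2 / 2
  sdlog_case <- 0.25
  sdlog_ctrl <- 0.22
  data.frame(
    group = c(rep("case", 4), "control"),
    stage = c("I", "II", "III", "IV", "none"),
    meanlog = c(mean_to_meanlog(c(0.1148, 0.1148, 0.125, 0.14), sdlog_case),
                mean_to_meanlog(0.09, sdlog_ctrl)),
    sdlog = c(rep(sdlog_case, 4), sdlog_ctrl),
    stringsAsFactors = FALSE)
}

#' Paper-matched simulation presets
#'
#' `separable = FALSE` (default) is the realistic cohort: the full arm-event
#' table and a 20/41 CNV-flat case fraction, which caps z-score sensitivity
#' near 50%. `separable = TRUE` is the idealised, fully classifiable cohort
#' used for classifier benchmarking: no flat cases, tumour fraction floored
#' at 0.1, and every case carrying the complete five-signature-arm profile
#' (see [default_arm_event_table()]).
#'
#' @param separable Logical.
#' @param seed Integer seed stored in the config.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
paper_sim_config <- function(separable = FALSE, seed = 1L, ...) {
  arms <- build_arm_table("hg19")
  if (!separable) return(sim_config(arms = arms, seed = seed, ...))
  sim_config(arms = arms,
             arm_event_table = default_arm_event_table(arms, "separable"),
             fraction_flat_cases = 0,
             tf_min = 0.1,
             seed = seed, ...)
}

validate_sim_config <- function(cfg) {
  et <- cfg$arm_event_table
  probs <- c(et$gain_prob, et$loss_prob, cfg$stage_weights,
             cfg$fraction_flat_cases)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (any(et$gain_prob + et$loss_prob > 1))
    stop("gain_prob + loss_prob > 1 for some arm", call. = FALSE)
  if (cfg$dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (cfg$n_cases < 0 || cfg$n_controls < 0) stop("negative cohort size", call. = FALSE)
  if (cfg$reads_per_sample <= 0) stop("reads_per_sample must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Draw cohort metadata and per-sample ground truth scalars
#'
#' Generates sample ids, group labels, case stages (exact quotas or
#' multinomial), log-normal cfDNA concentrations per group/stage, truncated
#' normal tumour fractions per stage (0 for controls), and ages. Fully
#' deterministic given the seed.
#'
#' @param config A `sim_config`.
#' @param seed Seed for this draw (default `config$seed`).
#' @return Data frame: `sample_id`, `group`, `stage`, `age`,
#'   `concentration`, `tf`.
#' @export
sample_cohort_meta <- function(config, seed = config$seed) {
  set.seed(seed)
  stages <- names(config$stage_weights)
  if (config$n_cases > 0) {
    if (config$stage_quotas) {
      quota <- round(config$stage_weights * config$n_cases)
      # repair rounding so the quotas sum to n_cases
      while (sum(quota) != config$n_cases) {
        i <- if (sum(quota) > config$n_cases) which.max(quota) else which.min(quota)
        quota[i] <- quota[i] + sign(config$n_cases - sum(quota))
      }
      case_stage <- rep(stages, quota)
    } else {
      case_stage <- sample(stages, config$n_cases, replace = TRUE,
                           prob = config$stage_weights)
    }
  } else case_stage <- character(0)
  meta <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(config$n_cases)),
                  sprintf("ctrl_%02d", seq_len(config$n_controls))),
    group = c(rep("case", config$n_cases), rep("control", config$n_controls)),
    stage = c(case_stage, rep("none", config$n_controls)),
    stringsAsFactors = FALSE)
  meta$age <- ifelse(meta$group == "case",
                     pmin(pmax(round(stats::rnorm(nrow(meta), 60, 8)), 44), 75),
                     pmin(pmax(round(stats::rnorm(nrow(meta), 31, 10)), 21), 66))
  ct <- config$concentration_by_group_stage
  key <- match(paste(meta$group, meta$stage), paste(ct$group, ct$stage))
  if (anyNA(key)) stop("no concentration parameters for some group/stage", call. = FALSE)
  meta$concentration <- stats::rlnorm(nrow(meta), ct$meanlog[key], ct$sdlog[key])
  tft <- config$tumor_fraction_by_stage
  meta$tf <- 0
  ic <- which(meta$group == "case")
  if (length(ic)) {
    tkey <- match(meta$stage[ic], tft$stage)
    tf <- stats::rnorm(length(ic), tft$mean[tkey], tft$sd[tkey])
    meta$tf[ic] <- pmin(pmax(tf, config$tf_min), 1)
  }
  meta
}

#' Draw per-arm integer copy states for a cohort
#'
#' Controls are always copy-neutral. A case is CNV-flat with probability
#' `fraction_flat_cases`; otherwise each arm independently gains (state 3)
#' or loses (state 1) with the probabilities in `arm_event_table`. When the
#' config names `require_event_arms`, non-flat profiles are redrawn until at
#' least one of those arms carries an event (rejection sampling; this is how
#' the separable preset guarantees classifier-visible signal).
#'
#' @param meta Output of [sample_cohort_meta()].
#' @param config A `sim_config`.
#' @param seed Seed (default `config$seed + 1`).
#' @return A `cohort_truth`: list with `meta` and integer `copy` matrix
#'   (samples x included arms; 2 neutral, 3 gain, 1 loss).
#' @export
draw_arm_profiles <- function(meta, config, seed = config$seed + 1L) {
  set.seed(seed)
  et <- config$arm_event_table
  narm <- nrow(et)
  copy <- matrix(2L, nrow = nrow(meta), ncol = narm,
                 dimnames = list(meta$sample_id, et$arm))
  need <- config$require_event_arms
  draw_profile <- function() {
    u <- stats::runif(narm)
    ifelse(u < et$gain_prob, 3L,
           ifelse(u < et$gain_prob + et$loss_prob, 1L, 2L))
  }
  for (i in which(meta$group == "case")) {
    if (stats::runif(1) < config$fraction_flat_cases) next
    for (attempt in 1:1000) {
      prof <- draw_profile()
      if (is.null(need) || any(prof[match(need, et$arm)] != 2L)) break
    }
    copy[i, ] <- prof
  }
  structure(list(meta = meta, copy = copy, arm = et$arm),
            class = "cohort_truth")
}

#' Simulate raw bin counts for a cohort
#'
#' For each sample the expected count of bin b is
#' `reads_per_sample * w_b * r_arm(b) * g(gc_b)`, where `w_b` is the bin's
#' share of a flat genome (equal for equal-width usable bins), `r = 1 +
#' tf * (c - 2) / 2` is the tumour-fraction-diluted relative coverage of the
#' bin's arm, and `g` is the quadratic GC-bias curve normalised to mean 1
#' over usable bins. Counts are negative-binomial with the configured
#' overdispersion. Unusable bins get zero counts, as in real counting.
#'
#' @param truth A `cohort_truth`.
#' @param grid A GC-annotated `bin_grid` over the same arms.
#' @param config A `sim_config`.
#' @param seed Seed (default `config$seed + 2`).
#' @return A raw `bin_count_matrix` (samples x bins).
#' @export
simulate_counts <- function(truth, grid, config, seed = config$seed + 2L) {
  set.seed(seed)
  usable <- grid$usable & !is.na(grid$gc)
  if (!any(usable)) stop("zero usable bins in the grid", call. = FALSE)
  g <- expected_gc_bias(grid$gc[usable], config$gc_bias)
  w <- 1 / sum(usable)
  arm_idx <- match(grid$arm[usable], truth$arm)
  if (anyNA(arm_idx))
    stop("grid contains arms absent from the truth profiles", call. = FALSE)
  meta <- truth$meta
  counts <- matrix(0L, nrow = nrow(meta), ncol = nrow(grid),
                   dimnames = list(meta$sample_id, grid$bin_id))
  size <- 1 / config$dispersion
  for (i in seq_len(nrow(meta))) {
    r <- 1 + meta$tf[i] * (truth$copy[i, ] - 2L) / 2
    lambda <- config$reads_per_sample * w * r[arm_idx] * g
    counts[i, usable] <- stats::rnbinom(sum(usable), mu = lambda, size = size)
  }
  bin_count_matrix(counts, stage = "raw")
}

# Quadratic GC bias evaluated at gc, floored at 0.05 and scaled to mean 1.
expected_gc_bias <- function(gc, coef) {
  g <- pmax(coef[1] + coef[2] * gc + coef[3] * gc^2, 0.05)
  g / mean(g)
}

#' One-call cohort simulation
#'
#' Runs [sample_cohort_meta()], [draw_arm_profiles()] and
#' [simulate_counts()] with seeds derived from `config$seed`.
#'
#' @param config A `sim_config`.
#' @param grid A GC-annotated `bin_grid`.
#' @return List with `truth` (`cohort_truth`), `meta` and raw `counts`.
#' @export
simulate_cohort <- function(config, grid) {
  meta <- sample_cohort_meta(config)
  truth <- draw_arm_profiles(meta, config)
  counts <- simulate_counts(truth, grid, config)
  list(truth = truth, meta = meta, counts = counts)
}

#' Write simulation outputs as plain text
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed): `counts.tsv`,
#'   `metadata.csv`, `truth.csv` (copy states wide, one column per arm).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_table(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.csv(sim$meta[, c("sample_id", "group", "stage", "age",
                                "concentration")],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  truth_df <- data.frame(sim$meta[, c("sample_id", "group", "stage", "tf",
                                      "concentration")],
                         sim$truth$copy, check.names = FALSE)
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
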