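toy_fraction_counts <- function() {
  arms <- data.frame(arm = c("Ap", "Aq"), chrom = "chrA",
                     start = c(0, 500000), end = c(400000, 900000),
                     included = TRUE)
  class(arms) <- c("arm_table", "data.frame")
  grid <- build_bin_grid(arms, 2e5)   # 2 bins per arm
  m <- matrix(c(15, 15, 35, 35,
                25, 25, 25, 25), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), grid$bin_id))
  list(grid = grid, counts = bin_count_matrix(m, "raw"))
}

test_that("arm fractions normalise arm sums to 1 per sample", {
  tf <- toy_fraction_counts()
  fr <- arm_fractions(tf$counts, tf$grid)
  expect_equal(unname(fr["s1", ]), c(0.3, 0.7))
  expect_equal(unname(fr["s2", ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(fr)), c(1, 1))

  zero <- tf$counts
  zero[2, ] <- 0
  expect_error(arm_fractions(bin_count_matrix(unclass(zero), "raw"), tf$grid),
               "s2")
})

test_that("reference panel records textbook per-arm mean and sd", {
  fr <- matrix(c(0.1, 0.9, 0.2, 0.8, 0.3, 0.7), 3, byrow = TRUE,
               dimnames = list(paste0("c", 1:3), c("Ap", "Aq")))
  panel <- fit_reference(fr)
  expect_equal(unname(panel$mean["Ap"]), 0.2)
  expect_equal(unname(panel$sd["Ap"]), 0.1)
  expect_equal(panel$n_controls, 3)
  expect_true(panel$loo_supported)

  expect_error(fit_reference(fr[1:2, ]), ">= 3")
  same <- matrix(0.5, 3, 2, dimnames = list(paste0("c", 1:3), c("Ap", "Aq")))
  expect_error(fit_reference(same), "zero variance")
})

test_that("z-scores follow (f - mu) / sigma and leave-one-out matches refit", {
  set.seed(42)
  fr <- matrix(rnorm(6 * 4, mean = 0.25, sd = 0.01), 6, 4,
               dimnames = list(paste0("c", 1:6), c("1p", "1q", "2p", "2q")))
  fr <- fr / rowSums(fr)
  panel <- fit_reference(fr)

  case <- matrix(panel$mean + c(0.003, 0, -0.001, 0), 1,
                 dimnames = list("x1", colnames(fr)))
  z_case <- z_scores(case, panel)
  expect_equal(unname(z_case[1, ]),
               unname(c(0.003, 0, -0.001, 0) / panel$sd))

  # hand-checked arithmetic: (0.033 - 0.030) / 0.001 = 3
  p2 <- panel
  p2$mean[] <- 0.030
  p2$sd[] <- 0.001
  f2 <- matrix(0.033, 1, 4, dimnames = list("y", colnames(fr)))
  expect_equal(unname(z_scores(f2, p2)[1, ]), rep(3, 4))

  # LOO against the brute-force refit oracle
  z_loo <- z_scores(fr, panel, control_ids = rownames(fr))
  for (id in rownames(fr)) {
    refit <- fit_reference(fr[setdiff(rownames(fr), id), ])
    expect_equal(z_loo[id, ], (fr[id, ] - refit$mean) / refit$sd,
                 tolerance = 1e-12)
  }
  # without LOO a control is scored against the full panel
  z_in <- z_scores(fr, panel, control_ids = rownames(fr),
                   leave_one_out = FALSE)
  expect_equal(z_in["c1", ], (fr["c1", ] - panel$mean) / panel$sd)
  expect_true(all(abs(z_in) <= abs(z_loo) + 1e-9))  # self-inclusion deflates

  expect_error(z_scores(fr, panel, control_ids = "ghost"), "ghost")
})

test_that("calls use strict thresholds with neutral boundary", {
  z <- matrix(c(3.5, 2.96, -3.0, -2.96, 0, 2.961), 1,
              dimnames = list("s", paste0("a", 1:6)))
  calls <- call_arms(z, 2.96)
  expect_equal(unname(calls$call[1, ]),
               c("gain", "neutral", "loss", "neutral", "neutral", "gain"))
  expect_true(calls$sample_positive["s"])
  flat <- call_arms(matrix(0, 1, 2, dimnames = list("f", c("a", "b"))))
  expect_false(flat$sample_positive["f"])
})

test_that("cohort evaluation computes stage-stratified sensitivity and specificity", {
  # all cases positive, all controls negative
  z <- rbind(matrix(5, 3, 2), matrix(0, 3, 2))
  dimnames(z) <- list(c(paste0("p", 1:3), paste0("n", 1:3)), c("1p", "1q"))
  meta <- data.frame(sample_id = rownames(z),
                     group = rep(c("case", "control"), each = 3),
                     stage = c("I", "II", "IV", "none", "none", "none"))
  ev <- evaluate_cohort(call_arms(z), meta)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 100)
  expect_equal(unname(ev$positives_by_stage), c(2L, 1L))

  # no positive cases
  z0 <- z
  z0[1:3, ] <- 0
  ev0 <- evaluate_cohort(call_arms(z0), meta)
  expect_equal(ev0$sensitivity, 0)
  expect_equal(sum(ev0$counts[c("case_positive", "case_negative")]), 3)
})

test_that("arm prevalence counts events only among positive cases", {
  z <- rbind(c(5, 0, 0), c(4, -4, 0), c(0, 0, 0), c(5, 0, 0))
  dimnames(z) <- list(c("p1", "p2", "p3", "n1"), c("8q", "22q", "5q"))
  meta <- data.frame(sample_id = rownames(z),
                     group = c("case", "case", "case", "control"),
                     stage = c("I", "II", "III", "none"))
  prev <- arm_prevalence(call_arms(z), meta)
  expect_equal(prev$gain_count[prev$arm == "8q"], 2)
  expect_equal(prev$loss_count[prev$arm == "22q"], 1)
  expect_equal(attr(prev, "n_positive_cases"), 2)
  expect_equal(sum(prev$gain_count) + sum(prev$loss_count), 3)
})

test_that("on a default-calibrated cohort prevalence recovers the event table", {
  grid <- mini_grid(bins_per_arm = 25)
  cfg <- mini_sim_config(seed = 17, n_cases = 300, n_controls = 40,
                         fraction_flat_cases = 0, tf_min = 0.15,
                         tumor_fraction_by_stage = data.frame(
                           stage = c("I", "II", "III", "IV"),
                           mean = 0.3, sd = 0.05))
  sim <- simulate_cohort(cfg, grid)
  fr <- arm_fractions(sim$counts, grid)
  ctrl <- sim$meta$sample_id[sim$meta$group == "control"]
  panel <- fit_reference(fr[ctrl, ])
  calls <- call_arms(z_scores(fr, panel, control_ids = ctrl))
  prev <- arm_prevalence(calls, sim$meta)
  npos <- attr(prev, "n_positive_cases")
  for (arm in c("3q", "22q")) {
    p <- cfg$arm_event_table[cfg$arm_event_table$arm == arm, ]
    obs <- (prev$gain_count + prev$loss_count)[prev$arm == arm] / npos
    expd <- p$gain_prob + p$loss_prob
    expect_lt(abs(obs - expd), 3 * sqrt(expd * (1 - expd) / npos))
  }
})

test_that("z-scores are invariant to per-sample depth scaling", {
  grid <- mini_grid(bins_per_arm = 10)
  cfg <- mini_sim_config(seed = 23, n_cases = 2, n_controls = 6,
                         bins_per_arm = 10)
  sim <- simulate_cohort(cfg, grid)
  corr <- gc_correct(sim$counts, grid)
  scaled <- unclass(corr)
  scaled[1, ] <- scaled[1, ] * 7.3
  ctrl <- sim$meta$sample_id[sim$meta$group == "control"]
  z1 <- z_scores(arm_fractions(corr, grid)[1, , drop = FALSE],
                 fit_reference(arm_fractions(corr, grid)[ctrl, ]))
  z2 <- z_scores(arm_fractions(bin_count_matrix(scaled, "gc_corrected"),
                               grid)[1, , drop = FALSE],
                 fit_reference(arm_fractions(corr, grid)[ctrl, ]))
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("call sets round-trip and heatmap coding is tri-level", {
  z <- matrix(c(3.5, -4, 0.5, 1), 2,
              dimnames = list(c("s1", "s2"), c("1p", "1q")))
  calls <- call_arms(z)
  dir <- tempfile()
  write_callset(calls, dir)
  back <- read_callset(dir)
  expect_equal(back$z, calls$z, tolerance = 1e-12)
  expect_equal(back$call, calls$call)
  expect_equal(back$z_threshold, 2.96)

  hm <- export_heatmap(calls, file.path(dir, "hm.tsv"))
  expect_equal(unname(hm), matrix(c(1L, -1L, 0L, 0L), 2))
  expect_true(file.exists(file.path(dir, "hm.tsv.z.tsv")))

  # empty call set still writes parseable files with headers
  empty <- call_arms(matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("1p", "1q"))))
  write_callset(empty, dir)
  expect_equal(nrow(utils::read.table(file.path(dir, "calls.tsv"),
                                      header = TRUE)), 0)
})
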