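# Fixtures are built in code at test time; nothing is stored on disk.

# A miniature two-chromosome arm table for grid/counting unit tests.
toy_arms <- function() {
  tab <- data.frame(
    arm = c("Ap", "Aq", "Bq"),
    chrom = c("chrA", "chrA", "chrB"),
    start = c(0, 500000, 0),
    end = c(400000, 1000000, 250000),
    included = TRUE,
    stringsAsFactors = FALSE)
  class(tab) <- c("arm_table", "data.frame")
  tab
}

# All 44 real arm names on tiny coordinates: every included arm gets
# `bins_per_arm` full windows (plus a dropped remainder), so cohort-level
# simulations stay fast while keeping the real arm vocabulary.
mini_arm_table <- function(bins_per_arm = 25, bin_size = 1e5) {
  real <- build_arm_table("hg19")
  len <- bins_per_arm * bin_size + bin_size %/% 2
  tab <- data.frame(
    arm = real$arm, chrom = real$chrom,
    start = ifelse(grepl("p$", real$arm), 0, len + bin_size),
    end = ifelse(grepl("p$", real$arm), len, 2 * len + bin_size),
    included = real$included, stringsAsFactors = FALSE)
  class(tab) <- c("arm_table", "data.frame")
  tab
}

mini_grid <- function(bins_per_arm = 25, bin_size = 1e5, gc_seed = 99) {
  annotate_gc_synthetic(
    build_bin_grid(mini_arm_table(bins_per_arm, bin_size), bin_size),
    seed = gc_seed)
}

# sim_config on the miniature arm table (keeps real arm names).
mini_sim_config <- function(..., bins_per_arm = 25, seed = 1L) {
  arms <- mini_arm_table(bins_per_arm)
  sim_config(arms = arms, arm_event_table = default_arm_event_table(arms),
             seed = seed, ...)
}

write_tiny_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

# Minimal SAM writer: records are lists with qname, flag, rname, pos (1-based),
# mapq, cigar. Sequences/qualities are placeholders.
write_tiny_sam <- function(records, seqlens, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens)))
  body <- vapply(records, function(r) {
    cig <- if (is.null(r$cigar)) "10M" else r$cigar
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, cig,
          "*", 0, 0, strrep("A", 10), strrep("I", 10), sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# Manually assembled cohort truth, bypassing the random profile draw.
manual_truth <- function(meta, arm_names, copy = NULL) {
  if (is.null(copy))
    copy <- matrix(2L, nrow(meta), length(arm_names),
                   dimnames = list(meta$sample_id, arm_names))
  structure(list(meta = meta, copy = copy, arm = arm_names),
            class = "cohort_truth")
}

manual_meta <- function(n, group = "control", stage = "none", tf = 0,
                        concentration = 0.1, prefix = group) {
  data.frame(sample_id = sprintf("%s_%03d", prefix, seq_len(n)),
             group = group, stage = stage, age = 50,
             concentration = concentration, tf = tf,
             stringsAsFactors = FALSE)
}

# Small deterministic feature sets (noise features plus one optionally
# class-shifted column) for classifier unit and oracle tests.
toy_features <- function(n = 40, p = 3, seed = 1, separation = 0) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  x[, 1] <- x[, 1] + separation * y
  meta <- data.frame(sample_id = rownames(x),
                     group = ifelse(y == 1, "case", "control"),
                     stage = ifelse(y == 1, "I", "none"),
                     concentration = 0.1)
  assemble_features(x, meta)
}

# Brute-force Shapley oracle over a booster's trees: the value function is
# the tree-path conditional expectation (untaken branches averaged by
# cover), evaluated by explicit recursion; attributions come from full
# power-set enumeration. Independent of the polynomial TreeSHAP path.
brute_force_shap <- function(bundle, x) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = bundle$booster))
  feats <- bundle$feature_names
  expvalue <- function(tree_df, node_id, s) {
    row <- tree_df[tree_df$ID == node_id, ]
    if (row$Feature == "Leaf") return(row$Gain)
    if (row$Feature %in% s) {
      nxt <- if (x[[row$Feature]] < row$Split) row$Yes else row$No
      return(expvalue(tree_df, nxt, s))
    }
    yes <- tree_df[tree_df$ID == row$Yes, ]
    no <- tree_df[tree_df$ID == row$No, ]
    (yes$Cover * expvalue(tree_df, row$Yes, s) +
       no$Cover * expvalue(tree_df, row$No, s)) / (yes$Cover + no$Cover)
  }
  v <- function(s) {
    sum(vapply(unique(dt$Tree), function(tr) {
      td <- dt[dt$Tree == tr, ]
      expvalue(td, td$ID[td$Node == 0], s)
    }, 0))
  }
  p <- length(feats)
  phi <- numeric(p)
  names(phi) <- feats
  subsets <- lapply(0:(2^p - 1), function(m) feats[bitwAnd(m, 2^(0:(p - 1))) > 0])
  for (j in feats) {
    for (s in subsets[!vapply(subsets, function(s) j %in% s, TRUE)]) {
      w <- factorial(length(s)) * factorial(p - length(s) - 1) / factorial(p)
      phi[j] <- phi[j] + w * (v(c(s, j)) - v(s))
    }
  }
  phi
}
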