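#' Tile chromosome arms with fixed-width bins
#'
#' Each included arm is tiled left-to-right with windows of exactly
#' `bin_size` bases; a trailing remainder shorter than `bin_size` is dropped
#' so every bin has identical width and count distributions are directly
#' comparable. Excluded arms contribute no bins.
#'
#' @param arms An `arm_table` from [build_arm_table()].
#' @param bin_size Window width in bases (default 100 kb).
#' @return A data frame of class `bin_grid` with columns `bin_id`
#'   (`"arm:start-end"`), `chrom`, `arm`, `start`, `end`, `gc` (NA until
#'   annotated) and `usable`; attribute `bin_size`.
#' @export
build_bin_grid <- function(arms, bin_size = 1e5) {
  stopifnot(bin_size > 0)
  validate_arm_table(arms)
  inc <- arms[arms$included, , drop = FALSE]
  pieces <- lapply(seq_len(nrow(inc)), function(i) {
    n <- floor((inc$end[i] - inc$start[i]) / bin_size)
    if (n == 0) return(NULL)
    start <- inc$start[i] + bin_size * (seq_len(n) - 1)
    data.frame(chrom = inc$chrom[i], arm = inc$arm[i],
               start = start, end = start + bin_size,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  if (is.null(grid) || nrow(grid) == 0)
    stop("bin_size ", bin_size, " exceeds every arm: empty grid", call. = FALSE)
  ord <- order(match(grid$chrom, unique(arms$chrom)), grid$start)
  grid <- grid[ord, ]
  grid$bin_id <- sprintf("%s:%d-%d", grid$arm, grid$start, grid$end)
  grid$gc <- NA_real_
  grid$usable <- TRUE
  rownames(grid) <- NULL
  grid <- grid[, c("bin_id", "chrom", "arm", "start", "end", "gc", "usable")]
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Annotate bins with GC fraction from a reference FASTA
#'
#' GC fraction is (G+C)/(A+C+G+T) over the bin; ambiguous bases are excluded
#' from the denominator. Bins with more than 50% ambiguous bases are marked
#' unusable and get a missing GC value.
#'
#' @param grid A `bin_grid`.
#' @param fasta Path to a FASTA file containing the grid's chromosomes.
#' @return The grid with `gc` and `usable` filled in.
#' @export
annotate_gc <- function(grid, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(grid$chrom), names(seqs))
  if (length(missing))
    stop("FASTA is missing chromosome(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    views <- Biostrings::Views(seqs[[ch]], start = grid$start[idx] + 1L,
                               end = grid$end[idx])
    freq <- Biostrings::letterFrequency(views, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    width <- grid$end[idx] - grid$start[idx]
    gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
    usable <- acgt / width >= 0.5
    grid$gc[idx] <- ifelse(usable, gc, NA_real_)
    grid$usable[idx] <- usable
  }
  grid
}

#' Assign synthetic GC fractions to a bin grid
#'
#' For simulation studies without a reference sequence: draws per-bin GC
#' from a Beta distribution centred near the genome-wide 0.41 with a
#' realistic spread. Clearly synthetic; use [annotate_gc()] for real data.
#'
#' @param grid A `bin_grid`.
#' @param mean,sd Target mean and standard deviation of the GC fractions.
#' @param seed Optional integer seed for reproducibility.
#' @return The grid with synthetic `gc` values, all bins usable.
#' @export
annotate_gc_synthetic <- function(grid, mean = 0.41, sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- sd^2
  stopifnot(v < mean * (1 - mean))
  k <- mean * (1 - mean) / v - 1
  grid$gc <- stats::rbeta(nrow(grid), mean * k, (1 - mean) * k)
  grid$usable <- TRUE
  grid
}

#' Write a bin grid as BED
#'
#' Columns: chrom, start, end, bin_id, gc (NA as "."), usable flag.
#' [read_bin_bed()] restores the grid.
#' @param grid A `bin_grid`.
#' @param path Output path.
#' @export
write_bin_bed <- function(grid, path) {
  gc <- ifelse(is.na(grid$gc), ".", format(grid$gc, digits = 8))
  utils::write.table(
    data.frame(grid$chrom, grid$start, grid$end, grid$bin_id, gc,
               as.integer(grid$usable)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_bed
#' @export
read_bin_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, na.strings = ".")
  grid <- data.frame(bin_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
                     arm = sub(":.*$", "", as.character(bed[[4]])),
                     start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]),
                     gc = as.numeric(bed[[5]]), usable = as.logical(as.integer(bed[[6]])),
                     stringsAsFactors = FALSE)
  widths <- unique(grid$end - grid$start)
  attr(grid, "bin_size") <- widths[1]
  class(grid) <- c("bin_grid", "data.frame")
  grid
}
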