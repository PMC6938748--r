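#' Count aligned reads per bin for one sample
#'
#' Streams a BAM (or plain SAM, converted on the fly) and tallies primary
#' aligned reads into the bin containing the leftmost aligned base, so each
#' read is counted at most once and boundary-spanning reads land in the left
#' bin. Unmapped, secondary, supplementary and duplicate-flagged reads are
#' skipped, as are reads below the mapping-quality cutoff (the stand-in for
#' a unique-mapping alignment filter) and reads outside any usable bin.
#'
#' @param alignments Path to a BAM or SAM file.
#' @param grid A `bin_grid`.
#' @param min_mapq Minimum mapping quality (default 30).
#' @param sample_id Row name for the resulting 1-sample matrix (default:
#'   file name without extension).
#' @return A 1 x nbins `bin_count_matrix` of raw integer counts.
#' @export
count_reads <- function(alignments, grid, min_mapq = 30, sample_id = NULL) {
  stopifnot(min_mapq >= 0)
  if (!file.exists(alignments))
    stop("cannot read alignment file: ", alignments, call. = FALSE)
  path <- alignments
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.(bam|sam)$", "", basename(alignments),
                     ignore.case = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "mapq"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$mapq) & rec$mapq >= min_mapq
  chrom <- as.character(rec$rname)[keep]
  pos0 <- rec$pos[keep] - 1L  # BAM pos is 1-based; grid is 0-based half-open
  counts <- integer(nrow(grid))
  for (ch in unique(chrom)) {
    idx <- which(grid$chrom == ch & grid$usable)
    if (!length(idx)) next
    p <- pos0[chrom == ch]
    hit <- findInterval(p, grid$start[idx])
    inside <- hit >= 1 & p < grid$end[idx][pmax(hit, 1)]
    tab <- tabulate(hit[inside], nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  m <- matrix(counts, nrow = 1,
              dimnames = list(sample_id, grid$bin_id))
  bin_count_matrix(m, stage = "raw")
}

#' Construct/validate a bin-count matrix
#'
#' Samples in rows, bins in columns; `stage` records whether the counts are
#' raw integers or GC-corrected reals. Raw counts must be non-negative
#' integers; corrected counts non-negative reals (NA marks masked bins).
#'
#' @param counts Numeric matrix with sample row names and bin-id column
#'   names.
#' @param stage `"raw"` or `"gc_corrected"`.
#' @return The matrix with class `bin_count_matrix` and a `stage` attribute.
#' @export
bin_count_matrix <- function(counts, stage = c("raw", "gc_corrected")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  vals <- counts[!is.na(counts)]
  if (any(vals < 0))
    stop("negative counts are not allowed", call. = FALSE)
  if (stage == "raw" && any(vals != round(vals)))
    stop("raw counts must be integers", call. = FALSE)
  attr(counts, "stage") <- stage
  class(counts) <- c("bin_count_matrix", class(unclass(counts)))
  counts
}

#' Read / write a bin-count table as TSV
#'
#' One row per sample; the header is `sample_id` followed by bin ids of the
#' form `arm:start-end`. The round trip is lossless for integer counts.
#'
#' @param path TSV path.
#' @param grid Optional `bin_grid`; when given, columns must match its bins
#'   exactly (schema check).
#' @param stage Stage tag to attach on read (default `"raw"`).
#' @return A `bin_count_matrix`.
#' @export
read_counts_table <- function(path, grid = NULL, stage = c("raw", "gc_corrected")) {
  stage <- match.arg(stage)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      row.names = 1, stringsAsFactors = FALSE),
    error = function(e) stop("count table schema error: ", conditionMessage(e),
                             call. = FALSE))
  if (ncol(tab) == 0) stop("count table schema error: no bin columns", call. = FALSE)
  m <- as.matrix(tab)
  if (!is.null(grid) && !identical(colnames(m), grid$bin_id))
    stop("count table columns do not match the bin grid", call. = FALSE)
  bin_count_matrix(m, stage = stage)
}

#' @rdname read_counts_table
#' @param counts A `bin_count_matrix` to write.
#' @export
write_counts_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts),
                   as.data.frame(unclass(counts), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
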