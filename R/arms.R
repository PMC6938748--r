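#' Chromosome arm definitions
#'
#' Builds the autosomal chromosome-arm table used as the coordinate backbone
#' for binning. For `"hg19"` an embedded cytoband-derived table is used:
#' the p arm spans `[0, centromere_start)` and the q arm
#' `[centromere_end, chrom_end)`, all coordinates 0-based half-open. The five
#' acrocentric short arms (13p, 14p, 15p, 21p, 22p) are present but flagged
#' `included = FALSE`; sex chromosomes are excluded entirely, so the included
#' set is the 39 autosomal arms conventionally analysed in arm-level
#' copy-number work.
#'
#' @param assembly Either `"hg19"` or the path to a BED file with columns
#'   chrom, start, end, arm name and (optionally) a fifth column of 0/1
#'   inclusion flags (default: all included).
#' @return A data frame of class `arm_table` with columns `arm`, `chrom`,
#'   `start`, `end`, `included`.
#' @examples
#' arms <- build_arm_table("hg19")
#' sum(arms$included)  # 39
#' @export
build_arm_table <- function(assembly = "hg19") {
  if (identical(assembly, "hg19")) {
    tab <- hg19_arm_table()
  } else if (is.character(assembly) && length(assembly) == 1 &&
             file.exists(assembly)) {
    tab <- read_arm_bed(assembly)
  } else {
    stop("unknown assembly '", assembly,
         "': use \"hg19\" or a path to an arm BED file", call. = FALSE)
  }
  validate_arm_table(tab)
  tab
}

# Embedded hg19 arm boundaries derived from the UCSC cytoband track:
# centromere = the two acen bands; chromosome lengths from the hg19 index.
hg19_arm_table <- function() {
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566)
  cen_start <- c(121500000, 90500000, 87900000, 48200000, 46100000, 58700000,
                 58000000, 43100000, 47300000, 38000000, 51600000, 33300000,
                 16300000, 16100000, 15800000, 34600000, 22200000, 15400000,
                 24400000, 25600000, 11288129, 13000000)
  cen_end <- c(128900000, 96800000, 93900000, 52700000, 50700000, 63300000,
               61700000, 48100000, 50700000, 42300000, 55700000, 38200000,
               19500000, 19100000, 20700000, 38600000, 25800000, 19000000,
               28600000, 29400000, 14300000, 17900000)
  chrom <- paste0("chr", 1:22)
  acrocentric_p <- c("13p", "14p", "15p", "21p", "22p")
  tab <- data.frame(
    arm      = c(paste0(1:22, "p"), paste0(1:22, "q")),
    chrom    = c(chrom, chrom),
    start    = c(rep(0, 22), cen_end),
    end      = c(cen_start, len),
    stringsAsFactors = FALSE
  )
  tab$included <- !(tab$arm %in% acrocentric_p)
  tab <- tab[order(match(tab$chrom, chrom), tab$start), ]
  rownames(tab) <- NULL
  class(tab) <- c("arm_table", "data.frame")
  tab
}

read_arm_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("arm BED needs chrom, start, end, name", call. = FALSE)
  tab <- data.frame(arm = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
                    start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]),
                    included = if (ncol(bed) >= 5) as.logical(as.integer(bed[[5]]))
                               else TRUE,
                    stringsAsFactors = FALSE)
  class(tab) <- c("arm_table", "data.frame")
  tab
}

validate_arm_table <- function(tab) {
  stopifnot(all(c("arm", "chrom", "start", "end", "included") %in% names(tab)))
  if (any(tab$start >= tab$end)) stop("arm with start >= end", call. = FALSE)
  if (anyDuplicated(tab$arm)) stop("duplicated arm names", call. = FALSE)
  # no two arms of a chromosome may overlap
  for (ch in unique(tab$chrom)) {
    a <- tab[tab$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
      stop("overlapping arms on ", ch, call. = FALSE)
  }
  invisible(tab)
}

#' Write an arm table as BED
#'
#' @param arms An `arm_table`.
#' @param path Output path; tab-separated BED (chrom, start, end, arm,
#'   included flag).
#' @export
write_arm_bed <- function(arms, path) {
  utils::write.table(
    data.frame(arms$chrom, arms$start, arms$end, arms$arm,
               as.integer(arms$included)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
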