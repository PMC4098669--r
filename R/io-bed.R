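#' Write genomic segments as BED3(+)
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the written start is `start_bp - 1` and the end is unchanged.
#'
#' @param segments data frame with columns `chrom`, `start_bp`, `end_bp`
#'   and optionally `name` (written as a fourth column).
#' @param path output path.
#' @export
write_bed <- function(segments, path) {
  if (nrow(segments) == 0L) {
    file.create(path)
    return(invisible(NULL))
  }
  start0 <- segments$start_bp - 1L
  if (any(segments$end_bp <= start0))
    stop("segment with end <= start after BED conversion")
  cols <- data.frame(segments$chrom, format(start0, scientific = FALSE, trim = TRUE),
                     format(segments$end_bp, scientific = FALSE, trim = TRUE))
  if (!is.null(segments$name)) cols <- cbind(cols, segments$name)
  utils::write.table(cols, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a BED3(+) file back into 1-based inclusive segments
#'
#' Involution partner of [write_bed()]: `start_bp = BED start + 1`,
#' `end_bp = BED end`.
#'
#' @param path BED file path.
#' @return data frame with `chrom`, `start_bp`, `end_bp` and `name` when a
#'   fourth column is present; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), stringsAsFactors = FALSE))
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(x[[1]]),
                    start_bp = as.integer(x[[2]]) + 1L,
                    end_bp = as.integer(x[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  out
}
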