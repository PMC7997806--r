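#' Read and write genomic regions as BED
#'
#' BED files are 0-based half-open on disk; internally the package uses
#' 1-based inclusive coordinates throughout (hg19 convention). The
#' conversion at this boundary is exact: internal start = BED start + 1,
#' internal end = BED end.
#'
#' @param path a BED file (3 or 4 columns: chrom, start, end\[, name\]).
#' @return `read_bed`: data.frame with chrom, start, end (1-based
#'   inclusive) and label. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(x) < 3) stop("BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(x[[1]]),
                    start = as.numeric(x[[2]]) + 1,
                    end = as.numeric(x[[3]]),
                    label = if (ncol(x) >= 4) as.character(x[[4]])
                            else sprintf("region%04d", seq_len(nrow(x))),
                    stringsAsFactors = FALSE)
  bad <- which(out$start > out$end)
  if (length(bad)) stop("empty/negative BED interval at row ", bad[1])
  out
}

#' @param regions data.frame with chrom, start, end (1-based inclusive) and
#'   optionally label.
#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  label <- if ("label" %in% names(regions)) regions$label
           else sprintf("region%04d", seq_len(nrow(regions)))
  lines <- paste(regions$chrom,
                 format(regions$start - 1, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 label, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
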