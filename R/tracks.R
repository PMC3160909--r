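#' Stepped genome score track
#'
#' A score track is a chromosome-indexed stepped function: non-overlapping
#' half-open intervals each carrying one value (e.g. a conservation score
#' or a probe intensity track).
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param value numeric step values.
#' @return data.frame of class `score_track`, sorted by `chrom` then
#'   `start`.
#' @export
score_track <- function(chrom, start, end, value) {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), value = as.numeric(value),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1) {
    same <- out$chrom[-1] == out$chrom[-nrow(out)]
    if (any(same & out$start[-1] < out$end[-nrow(out)]))
      stop("overlapping steps in score track")
  }
  class(out) <- c("score_track", "data.frame")
  out
}

#' Read a genome score track
#'
#' Supports 4-column bedGraph and WIG (both `fixedStep` and `variableStep`,
#' with `span`).  Overlapping steps are an error.
#'
#' @param path file path.
#' @param format `"bedgraph"` or `"wig"`; default guesses from the file
#'   extension.
#' @return a [score_track()].
#' @export
read_track <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedgraph"
  }
  format <- match.arg(format, c("bedgraph", "wig"))
  gr <- rtracklayer::import(path, format = if (format == "wig") "wig" else "bedGraph")
  score_track(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1,
              GenomicRanges::end(gr),
              gr$score)
}

#' Write a genome score track
#'
#' @param track a [score_track()].
#' @param path output path.
#' @param format `"bedgraph"` or `"wig"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  gr <- as_granges0(track$chrom, track$start, track$end)
  gr$score <- track$value
  rtracklayer::export(gr, path, format = if (format == "wig") "wig" else "bedGraph")
  invisible(path)
}
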