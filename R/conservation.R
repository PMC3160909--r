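#' Length-weighted mean conservation over regions
#'
#' Mean of the track's step values over each region, weighted by the
#' number of bases each step covers inside the region; bases covered by
#' no step contribute 0.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (length >= 1
#'   each).
#' @param track a [score_track()].
#' @return numeric vector of mean scores, one per region.
#' @export
mean_conservation <- function(regions, track) {
  if (any(regions$end - regions$start < 1)) stop("empty region")
  vapply(seq_len(nrow(regions)), function(i) {
    tr <- track[track$chrom == regions$chrom[i] &
                  track$end > regions$start[i] &
                  track$start < regions$end[i], , drop = FALSE]
    if (nrow(tr) == 0) return(0)
    w <- pmin(tr$end, regions$end[i]) - pmax(tr$start, regions$start[i])
    sum(w * tr$value) / (regions$end[i] - regions$start[i])
  }, numeric(1))
}
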