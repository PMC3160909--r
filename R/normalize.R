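#' Probe intensity matrix
#'
#' Tiled probe coordinates with one intensity column per sample.  Probes
#' are stored sorted by (chrom, start) with strictly increasing starts per
#' chromosome; intensities must be finite and, on the linear scale,
#' positive.
#'
#' @param probes data.frame with columns `chrom`, `start`, `end`.
#' @param intensity numeric matrix, rows = probes, columns = samples.
#' @param log2 logical flag: are the intensities log2-scale?
#' @return list of class `probe_matrix` with elements `probes`,
#'   `intensity`, `log2`.
#' @export
probe_matrix <- function(probes, intensity, log2 = FALSE) {
  probes <- as.data.frame(probes)
  intensity <- as.matrix(intensity)
  if (nrow(probes) != nrow(intensity))
    stop("probes and intensity disagree on probe count")
  ord <- order(probes$chrom, probes$start)
  probes <- probes[ord, , drop = FALSE]
  intensity <- intensity[ord, , drop = FALSE]
  rownames(probes) <- NULL
  if (nrow(probes) > 1) {
    same <- probes$chrom[-1] == probes$chrom[-nrow(probes)]
    if (any(same & diff(probes$start) <= 0))
      stop("probe starts must be strictly increasing within a chromosome")
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (!log2 && any(intensity <= 0))
    stop("linear-scale intensities must be positive")
  structure(list(probes = probes, intensity = intensity, log2 = log2),
            class = "probe_matrix")
}

#' Background-correct probe intensities
#'
#' `percentile_shift` subtracts each sample's low-percentile intensity
#' (default the 2nd percentile) and floors the result at a small positive
#' constant, preserving monotonicity; `none` is the identity.  Downstream
#' thresholds are percentile-based, so expression calls are insensitive to
#' this shift; it serves to put samples on a comparable baseline.
#'
#' @param pm a [probe_matrix()] on the linear scale.
#' @param method `"percentile_shift"` or `"none"`.
#' @param percentile percentile subtracted (proportion in `[0, 1)`).
#' @param floor small positive constant flooring the corrected values.
#' @return a corrected `probe_matrix` (linear scale).
#' @export
background_correct <- function(pm, method = c("percentile_shift", "none"),
                               percentile = 0.02, floor = 0.25) {
  method <- match.arg(method)
  if (pm$log2) stop("background correction expects linear-scale intensities")
  if (method == "none") return(pm)
  if (!is.finite(floor) || floor <= 0) stop("floor must be positive")
  bg <- apply(pm$intensity, 2, stats::quantile, probs = percentile,
              names = FALSE)
  pm$intensity <- pmax(sweep(pm$intensity, 2, bg, "-"), floor)
  pm
}

#' Quantile-normalize probe intensities across samples
#'
#' Forces every sample to share one common intensity distribution: each
#' sample's sorted vector becomes the across-sample mean of sorted vectors,
#' with ties receiving the mean of the quantiles they span.
#'
#' @param pm a [probe_matrix()] with >= 2 samples.
#' @return a normalized `probe_matrix` on the same scale.
#' @export
quantile_normalize <- function(pm) {
  if (ncol(pm$intensity) < 2) stop("quantile normalization needs >= 2 samples")
  pm$intensity <- limma::normalizeQuantiles(pm$intensity, ties = TRUE)
  pm
}

#' Log2-transform a linear-scale probe matrix
#'
#' @param pm a [probe_matrix()] on the linear scale.
#' @return the `probe_matrix` with log2 intensities (`log2 = TRUE`).
#' @export
log2_transform <- function(pm) {
  if (pm$log2) return(pm)
  if (any(pm$intensity <= 0)) stop("non-positive intensities cannot be logged")
  pm$intensity <- log2(pm$intensity)
  pm$log2 <- TRUE
  pm
}
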