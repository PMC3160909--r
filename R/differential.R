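#' Gene expression profiles from exon-block levels
#'
#' Per gene and condition, the median (log2) expression level across the
#' gene's probed exon blocks.  Genes with no probed exon block are
#' excluded.
#'
#' @param bx a `block_expression`.
#' @param ann a `gene_annotation`.
#' @param sources which annotation sources to profile (default `"ucsc"`).
#' @return data.frame of class `gene_profiles` with `gene_id` and one
#'   `level_<condition>` column per condition.
#' @export
gene_expression_profiles <- function(bx, ann, sources = "ucsc") {
  conditions <- names(level_cols(bx))
  lc <- level_cols(bx)
  exb <- bx[bx$kind == "exon" & bx$n_probes >= 1, , drop = FALSE]
  genes <- ann$genes$gene_id[ann$genes$source %in% sources]
  exb <- exb[exb$owner %in% genes, , drop = FALSE]
  sp <- split(seq_len(nrow(exb)), exb$owner)
  out <- data.frame(gene_id = names(sp), stringsAsFactors = FALSE)
  for (cc in conditions) {
    v <- exb[[lc[cc]]]
    out[[paste0("level_", cc)]] <- vapply(sp, function(i)
      stats::median(v[i]), numeric(1))
  }
  attr(out, "conditions") <- conditions
  rownames(out) <- NULL
  class(out) <- c("gene_profiles", "data.frame")
  out
}

#' Per-gene expression difference between two conditions
#'
#' @param profiles a [gene_expression_profiles()] result.
#' @param pair character vector `c(later, earlier)`; delta = later -
#'   earlier.
#' @return data.frame `gene_id`, `delta`.
#' @export
gene_delta <- function(profiles, pair) {
  stopifnot(length(pair) == 2)
  cols <- paste0("level_", pair)
  if (!all(cols %in% names(profiles)))
    stop("conditions not present in profiles: ",
         paste(setdiff(pair, sub("^level_", "", names(profiles))),
               collapse = ", "))
  data.frame(gene_id = profiles$gene_id,
             delta = profiles[[cols[1]]] - profiles[[cols[2]]],
             stringsAsFactors = FALSE)
}

#' Genome-local coordinate-perturbation permutation of probe intensities
#'
#' Destroys gene structure while preserving local intensity statistics:
#' within each chromosome, Gaussian noise (sd `coordinate_sd`) is added to
#' probe coordinates, probes are re-ranked by perturbed coordinate, and
#' the probe at original rank r receives the full intensity vector (all
#' samples jointly) of the probe at rank r of the perturbed ordering.  The
#' result is a permutation of intensity vectors: per-sample intensity
#' multisets are conserved exactly.
#'
#' @param pm a [probe_matrix()].
#' @param coordinate_sd Gaussian sd in bp; `NULL` means
#'   `min(1e6, chrom_length / 10)` per chromosome (keeps the null local on
#'   small genomes), taking chromosome length as the largest probe end.
#' @param eps optional numeric vector of perturbations (one per probe), to
#'   inject deterministic noise; overrides `coordinate_sd` draws.
#' @return the permuted `probe_matrix`.
#' @export
permute_probes_locally <- function(pm, coordinate_sd = NULL, eps = NULL) {
  probes <- pm$probes
  int <- pm$intensity
  for (chr in unique(probes$chrom)) {
    idx <- which(probes$chrom == chr)
    coord <- probes$start[idx]
    sd_chr <- if (is.null(coordinate_sd))
      min(1e6, max(probes$end[idx]) / 10) else coordinate_sd
    e <- if (is.null(eps)) stats::rnorm(length(idx), 0, sd_chr) else eps[idx]
    perm <- order(coord + e)
    int[idx, ] <- int[idx[perm], , drop = FALSE]
  }
  pm$intensity <- int
  pm
}

#' Permutation null for differential expression
#'
#' Generates `n_permutations` locally permuted datasets, re-fits the exon
#' block models and recomputes gene deltas for each condition pair, pools
#' the permuted deltas per pair, and takes the pair's significance
#' thresholds as the 1st and 99th percentiles (type-7 interpolation) of
#' the pooled distribution.
#'
#' @param pm the normalized log2-scale [probe_matrix()].
#' @param blocks a [build_blocks()] result (exon blocks are refit).
#' @param ann a `gene_annotation`.
#' @param design a [sample_design()].
#' @param pairs list of `c(later, earlier)` condition pairs.
#' @param n_permutations number of permuted datasets (>= 1; default 5).
#' @param coordinate_sd see [permute_probes_locally()].
#' @param lower_percentile,upper_percentile null percentiles (proportions).
#' @return list of class `de_null`: `thresholds` (data.frame pair x
#'   lower/upper), `pooled` (list of pooled delta vectors per pair),
#'   `n_permutations`.
#' @export
build_null <- function(pm, blocks, ann, design,
                       pairs = list(c("E13.5", "E11.5"),
                                    c("E15.5", "E13.5")),
                       n_permutations = 5, coordinate_sd = NULL,
                       lower_percentile = 0.01, upper_percentile = 0.99) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  exon_blocks <- blocks[blocks$kind == "exon", , drop = FALSE]
  pair_names <- vapply(pairs, function(p) paste(p, collapse = "_vs_"),
                       character(1))
  pooled <- stats::setNames(vector("list", length(pairs)), pair_names)
  for (k in seq_len(n_permutations)) {
    pmk <- permute_probes_locally(pm, coordinate_sd)
    bxk <- fit_block_model(exon_blocks, pmk, design)
    prof <- gene_expression_profiles(bxk, ann)
    for (j in seq_along(pairs)) {
      pooled[[j]] <- c(pooled[[j]], gene_delta(prof, pairs[[j]])$delta)
    }
  }
  thresholds <- data.frame(
    pair = pair_names,
    lower = vapply(pooled, stats::quantile, numeric(1),
                   probs = lower_percentile, names = FALSE, type = 7),
    upper = vapply(pooled, stats::quantile, numeric(1),
                   probs = upper_percentile, names = FALSE, type = 7),
    stringsAsFactors = FALSE)
  rownames(thresholds) <- NULL
  structure(list(thresholds = thresholds, pooled = pooled,
                 n_permutations = n_permutations),
            class = "de_null")
}

#' Three-valued differential calls against null thresholds
#'
#' `+1` iff delta strictly exceeds the upper null percentile, `-1` iff
#' strictly below the lower, else `0`.
#'
#' @param deltas data.frame from [gene_delta()].
#' @param lower,upper finite null thresholds.
#' @param pair optional pair label stored on the result.
#' @return data.frame `gene_id`, `pair`, `delta`, `call`, `lower`,
#'   `upper`.
#' @export
call_differential <- function(deltas, lower, upper, pair = NA_character_) {
  if (!is.finite(lower) || !is.finite(upper))
    stop("null thresholds must be finite")
  call <- integer(nrow(deltas))
  call[deltas$delta > upper] <- 1L
  call[deltas$delta < lower] <- -1L
  data.frame(gene_id = deltas$gene_id, pair = pair, delta = deltas$delta,
             call = call, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' Differential expression between stages, end to end
#'
#' Computes observed gene deltas for each pair, builds the permutation
#' null, and emits three-valued calls.
#'
#' @inheritParams build_null
#' @param bx the observed `block_expression` (all blocks).
#' @return list of class `de_result`: `calls` (one data.frame per pair,
#'   rbind-ed), `null` (the `de_null`), `profiles`.
#' @export
run_differential <- function(pm, blocks, bx, ann, design,
                             pairs = list(c("E13.5", "E11.5"),
                                          c("E15.5", "E13.5")),
                             n_permutations = 5, coordinate_sd = NULL,
                             lower_percentile = 0.01,
                             upper_percentile = 0.99) {
  prof <- gene_expression_profiles(bx, ann)
  null <- build_null(pm, blocks, ann, design, pairs, n_permutations,
                     coordinate_sd, lower_percentile, upper_percentile)
  calls <- do.call(rbind, lapply(seq_along(pairs), function(j) {
    call_differential(gene_delta(prof, pairs[[j]]),
                      null$thresholds$lower[j], null$thresholds$upper[j],
                      null$thresholds$pair[j])
  }))
  structure(list(calls = calls, null = null, profiles = prof),
            class = "de_result")
}
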