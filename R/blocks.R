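#' Build summarization blocks from annotation and probe layout
#'
#' The summarization unit of the pipeline: all probes overlapping one
#' annotated exon form a single exon block; intronic and intergenic space
#' is tiled by consecutive windows of `window` bp (step = width, last
#' window truncated at the region end).  Probes overlapping any exon
#' belong to exon blocks only; remaining probes are assigned to every
#' window they overlap.  Windows containing zero probes are kept, flagged
#' by `n_probes = 0`.
#'
#' @param ann a `gene_annotation`.
#' @param layout a [genome_layout()].
#' @param pm a [probe_matrix()].
#' @param window window width in bp for intron/intergenic tiling.
#' @param intergenic_sources which sources define intergenic space (see
#'   [intergenic_complement()]).
#' @return data.frame of class `block_set` with columns `block_id`,
#'   `kind` (exon/intron/intergenic), `chrom`, `start`, `end`, `owner`
#'   (gene id or NA), `region_id` (parent intron/intergenic region),
#'   `n_probes`, and a list-column `probe_idx` of row indices into `pm`.
#' @export
build_blocks <- function(ann, layout, pm, window = 500,
                         intergenic_sources = "both") {
  if (window < 1) stop("window must be >= 1")
  probes <- pm$probes
  if (nrow(probes) && window < max(probes$end - probes$start))
    stop("window smaller than probe length")
  pg <- as_granges0(probes$chrom, probes$start, probes$end)

  ex <- ann$exons
  exon_blocks <- data.frame(
    block_id = ex$exon_id, kind = "exon", chrom = ex$chrom,
    start = ex$start, end = ex$end, owner = ex$gene_id,
    region_id = NA_character_, stringsAsFactors = FALSE)

  # introns: per-gene gaps between exons
  introns <- intron_regions(ann)
  ig <- intergenic_complement(ann, layout, intergenic_sources)
  ig$region_id <- sprintf("ig%05d", seq_len(nrow(ig)))

  tile_region <- function(chrom, start, end, region_id, owner, kind) {
    ws <- seq(start, end - 1, by = window)
    we <- pmin(ws + window, end)
    data.frame(block_id = sprintf("%s.w%d", region_id, seq_along(ws)),
               kind = kind, chrom = chrom, start = ws, end = we,
               owner = owner, region_id = region_id,
               stringsAsFactors = FALSE)
  }
  intron_blocks <- if (nrow(introns))
    do.call(rbind, lapply(seq_len(nrow(introns)), function(i)
      tile_region(introns$chrom[i], introns$start[i], introns$end[i],
                  introns$region_id[i], introns$gene_id[i], "intron")))
    else NULL
  ig_blocks <- if (nrow(ig))
    do.call(rbind, lapply(seq_len(nrow(ig)), function(i)
      tile_region(ig$chrom[i], ig$start[i], ig$end[i],
                  ig$region_id[i], NA_character_, "intergenic")))
    else NULL

  blocks <- rbind(exon_blocks, intron_blocks, ig_blocks)
  rownames(blocks) <- NULL

  # probe assignment: exon-overlapping probes go to exon blocks only
  exonic <- rep(FALSE, nrow(probes))
  probe_idx <- vector("list", nrow(blocks))
  is_exon <- blocks$kind == "exon"
  if (any(is_exon) && nrow(probes)) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(blocks$chrom[is_exon], blocks$start[is_exon],
                  blocks$end[is_exon]), pg)
    exonic[S4Vectors::subjectHits(hits)] <- TRUE
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    probe_idx[which(is_exon)[as.integer(names(sp))]] <- sp
  }
  if (any(!is_exon) && any(!exonic)) {
    free <- which(!exonic)
    hits <- GenomicRanges::findOverlaps(
      as_granges0(blocks$chrom[!is_exon], blocks$start[!is_exon],
                  blocks$end[!is_exon]), pg[free])
    sp <- split(free[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    probe_idx[which(!is_exon)[as.integer(names(sp))]] <- sp
  }
  probe_idx[vapply(probe_idx, is.null, logical(1))] <- list(integer(0))
  blocks$n_probes <- vapply(probe_idx, length, integer(1))
  blocks$probe_idx <- probe_idx
  class(blocks) <- c("block_set", "data.frame")
  blocks
}

# per-gene intron intervals with region ids
intron_regions <- function(ann) {
  g <- ann$genes
  out <- lapply(seq_len(nrow(g)), function(i) {
    ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ex) < 2) return(NULL)
    ir <- IRanges::gaps(IRanges::IRanges(ex$start + 1, ex$end),
                        start = g$start[i] + 1, end = g$end[i])
    if (!length(ir)) return(NULL)
    data.frame(gene_id = g$gene_id[i], chrom = g$chrom[i],
               start = IRanges::start(ir) - 1, end = IRanges::end(ir),
               region_id = sprintf("%s.i%d", g$gene_id[i], seq_along(ir)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      region_id = character())
  out
}

#' Additive median polish of a probes x samples matrix
#'
#' Robust fit of `log2 I[p, s] = overall + affinity[p] + level[s] +
#' residual`, alternately sweeping row (probe) and column (sample)
#' medians, rows first.  Iterates until the largest median adjustment
#' drops below `tol` or `max_iter` sweeps.
#'
#' @param x numeric matrix (probes x samples).
#' @param tol convergence tolerance on the largest median adjustment.
#' @param max_iter iteration cap.
#' @return list with `overall`, `row` (probe affinities), `col` (sample
#'   levels relative to overall), `residuals`, `iterations`.
#' @export
median_polish <- function(x, tol = 1e-6, max_iter = 10L) {
  x <- as.matrix(x)
  nr <- nrow(x); nc <- ncol(x)
  t0 <- 0; re <- numeric(nr); ce <- numeric(nc)
  it <- 0L
  repeat {
    it <- it + 1L
    rdelta <- apply(x, 1L, stats::median)
    x <- x - rdelta
    re <- re + rdelta
    d1 <- stats::median(ce); ce <- ce - d1; t0 <- t0 + d1
    cdelta <- apply(x, 2L, stats::median)
    x <- x - rep(cdelta, each = nr)
    ce <- ce + cdelta
    d2 <- stats::median(re); re <- re - d2; t0 <- t0 + d2
    adj <- max(abs(c(rdelta, cdelta, d1, d2)))
    if (adj < tol || it >= max_iter) break
  }
  list(overall = t0, row = re, col = ce, residuals = x, iterations = it)
}

#' Fit the block summarization model
#'
#' For every block with at least one probe, fits the RMA-style additive
#' model by [median_polish()] on the log2 probes x samples submatrix and
#' reduces replicate sample levels to per-condition expression levels by
#' the arithmetic mean.  Empty blocks are flagged (`NA` levels).
#'
#' @param blocks a [build_blocks()] result (or any subset of its rows).
#' @param pm a log2-scale [probe_matrix()].
#' @param design a [sample_design()].
#' @param store_affinity keep per-probe affinities as a list-column?
#' @return data.frame of class `block_expression`: the block columns plus
#'   one `level_<condition>` column per condition and, optionally,
#'   `affinity`.
#' @export
fit_block_model <- function(blocks, pm, design, store_affinity = FALSE) {
  if (!pm$log2) stop("fit_block_model expects log2-scale intensities")
  conditions <- attr(design, "conditions")
  if (is.null(conditions)) conditions <- unique(design$condition)
  cond_cols <- lapply(conditions, function(cc)
    which(design$condition == cc))
  int <- pm$intensity
  nb <- nrow(blocks)
  levels_mat <- matrix(NA_real_, nb, length(conditions))
  aff <- if (store_affinity) vector("list", nb) else NULL
  pidx <- blocks$probe_idx
  np <- vapply(pidx, length, integer(1))
  fill_levels <- function(which_blocks, mu) {
    # mu: length(which_blocks) x n_samples matrix of sample levels
    for (c in seq_along(conditions))
      levels_mat[which_blocks, c] <<-
        rowMeans(mu[, cond_cols[[c]], drop = FALSE])
  }
  one <- which(np == 1)
  if (length(one)) {
    fill_levels(one, int[unlist(pidx[one]), , drop = FALSE])
    if (store_affinity) aff[one] <- list(0)
  }
  for (nr in sort(unique(np[np >= 2]))) {
    bs <- which(np == nr)
    rows <- unlist(pidx[bs])
    fit <- batch_median_polish(int[rows, , drop = FALSE], nr)
    fill_levels(bs, fit$mu)
    if (store_affinity)
      aff[bs] <- split(fit$row, rep(seq_along(bs), each = nr))
  }
  out <- as.data.frame(blocks)[c("block_id", "kind", "chrom", "start",
                                 "end", "owner", "region_id", "n_probes")]
  for (c in seq_along(conditions))
    out[[paste0("level_", conditions[c])]] <- levels_mat[, c]
  if (store_affinity) out$affinity <- aff
  attr(out, "conditions") <- conditions
  class(out) <- c("block_expression", "data.frame")
  out
}

# row medians via a vectorized compare-exchange (bubble) sorting network;
# fast for the narrow matrices that arise here (<= ~16 columns)
row_medians <- function(m) {
  nc <- ncol(m)
  if (nc == 1) return(m[, 1])
  cols <- lapply(seq_len(nc), function(j) m[, j])
  for (i in seq_len(nc - 1)) {
    for (j in seq_len(nc - i)) {
      a <- cols[[j]]; b <- cols[[j + 1]]
      cols[[j]] <- pmin(a, b); cols[[j + 1]] <- pmax(a, b)
    }
  }
  if (nc %% 2 == 1) cols[[(nc + 1) / 2]]
  else (cols[[nc / 2]] + cols[[nc / 2 + 1]]) / 2
}

# median polish of many g blocks of identical shape (nr probes x nc
# samples) at once; X stacks the blocks row-wise.  Same sweep order and
# convergence rule as median_polish(), applied to all blocks jointly
# (iteration stops when every block's largest adjustment is below tol).
batch_median_polish <- function(X, nr, tol = 1e-6, max_iter = 10L) {
  nc <- ncol(X)
  g <- nrow(X) / nr
  t0 <- numeric(g)
  re <- numeric(g * nr)
  ce <- matrix(0, g, nc)
  blk <- rep(seq_len(g), each = nr)
  per_block_col_medians <- function(v) {
    # v: length g*nr vector -> per-block median (over the nr rows)
    row_medians(matrix(v, nrow = g, byrow = TRUE))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    rdelta <- row_medians(X)
    X <- X - rdelta
    re <- re + rdelta
    d1 <- row_medians(ce)
    ce <- ce - d1
    t0 <- t0 + d1
    # per-block column medians: reshape to (g*nc) x nr and sweep
    cdelta <- vapply(seq_len(nc), function(j)
      per_block_col_medians(X[, j]), numeric(g))
    if (g == 1) cdelta <- matrix(cdelta, nrow = 1)
    X <- X - cdelta[blk, , drop = FALSE]
    ce <- ce + cdelta
    d2 <- per_block_col_medians(re)
    re <- re - d2[blk]
    t0 <- t0 + d2
    adj <- max(abs(rdelta), abs(cdelta), abs(d1), abs(d2))
    if (adj < tol || it >= max_iter) break
  }
  list(mu = t0 + ce, row = re, iterations = it)
}

level_cols <- function(bx) {
  conditions <- attr(bx, "conditions")
  if (is.null(conditions))
    conditions <- sub("^level_", "", grep("^level_", names(bx), value = TRUE))
  stats::setNames(paste0("level_", conditions), conditions)
}
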