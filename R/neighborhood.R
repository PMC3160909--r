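#' Distance cutoff grid for proximity profiles
#'
#' Cutoffs from 1 Kb to 1 Mb: step 1 Kb up to 20 Kb, 10 Kb up to 100 Kb,
#' 100 Kb up to 1 Mb (37 cutoffs).
#'
#' @return numeric vector of strictly increasing cutoffs in bp.
#' @export
distance_grid <- function() {
  c(seq(1e3, 20e3, by = 1e3), seq(30e3, 100e3, by = 1e4),
    seq(200e3, 1e6, by = 1e5))
}

# distance from each query interval to the nearest subject interval
# (gap distance, 0 on overlap/abutment, Inf when no subject shares the
# chromosome); interval-tree backed
min_dist_to <- function(query, subject) {
  if (nrow(query) == 0) return(numeric(0))
  d <- rep(Inf, nrow(query))
  if (nrow(subject) == 0) return(d)
  h <- GenomicRanges::distanceToNearest(
    as_granges0(query$chrom, query$start, query$end),
    as_granges0(subject$chrom, subject$start, subject$end),
    ignore.strand = TRUE)
  d[S4Vectors::queryHits(h)] <- S4Vectors::mcols(h)$distance
  d
}

#' Signal-centric proximity classification over a distance grid
#'
#' At each cutoff x, a signal is "close to expressed" if any expressed
#' gene lies within x bp, else "close to non-expressed" if any gene does
#' (expressed takes precedence), else "not close".  The three fractions
#' sum to 1 at every cutoff and the close fractions are non-decreasing in
#' x.
#'
#' @param signals data.frame with `chrom`, `start`, `end`.
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param gene_calls a [call_genes()] result.
#' @param condition stage whose expressed status is used.
#' @param grid cutoffs in bp.
#' @return data.frame `cutoff`, `close_expressed`, `close_nonexpressed`,
#'   `not_close` (fractions of signals).
#' @export
classify_proximity <- function(signals, genes, gene_calls, condition,
                               grid = distance_grid()) {
  expr_ids <- gene_calls$gene_id[
    gene_calls[[paste0("expressed_", condition)]] %in% TRUE]
  d_expr <- min_dist_to(signals, genes[genes$gene_id %in% expr_ids, ,
                                       drop = FALSE])
  d_any <- min_dist_to(signals, genes)
  n <- nrow(signals)
  out <- data.frame(cutoff = grid)
  out$close_expressed <- vapply(grid, function(x) sum(d_expr <= x) / n,
                                numeric(1))
  out$close_nonexpressed <- vapply(grid, function(x)
    sum(d_expr > x & d_any <= x) / n, numeric(1))
  out$not_close <- 1 - out$close_expressed - out$close_nonexpressed
  out
}

#' Monte-Carlo expectation for the proximity profile
#'
#' Redraws each signal's position uniformly over intergenic space
#' (preserving signal lengths), recomputes the signal-centric fractions,
#' and reports per-cutoff means and a 95% envelope over `n_draws`
#' replicates.  This is the "random placement" baseline against which the
#' observed profile is compared.
#'
#' @inheritParams classify_proximity
#' @param intergenic intergenic intervals (from
#'   [intergenic_complement()]) to draw positions from.
#' @param n_draws Monte-Carlo replicates (>= 1).
#' @param seed optional RNG seed for reproducibility.
#' @return data.frame with, per cutoff and class, `mean`, `lo` (2.5%),
#'   `hi` (97.5%) columns: `expected_close_expressed`, `lo_close_expressed`,
#'   etc.
#' @export
random_expectation <- function(signals, genes, gene_calls, condition,
                               intergenic, grid = distance_grid(),
                               n_draws = 100, seed = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lens <- signals$end - signals$start
  ig <- intergenic
  ig_len <- ig$end - ig$start
  draws_ce <- matrix(0, n_draws, length(grid))
  draws_cn <- matrix(0, n_draws, length(grid))
  for (k in seq_len(n_draws)) {
    # place each signal uniformly over intergenic space (by region,
    # weighted by length, position uniform within the region)
    ri <- sample(seq_len(nrow(ig)), length(lens), replace = TRUE,
                 prob = ig_len)
    pos <- floor(stats::runif(length(lens), 0,
                              pmax(1, ig_len[ri] - lens)))
    rnd <- data.frame(chrom = ig$chrom[ri], start = ig$start[ri] + pos,
                      end = ig$start[ri] + pos + lens)
    pr <- classify_proximity(rnd, genes, gene_calls, condition, grid)
    draws_ce[k, ] <- pr$close_expressed
    draws_cn[k, ] <- pr$close_nonexpressed
  }
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p, names = FALSE)
  data.frame(cutoff = grid,
             expected_close_expressed = colMeans(draws_ce),
             lo_close_expressed = q(draws_ce, 0.025),
             hi_close_expressed = q(draws_ce, 0.975),
             expected_close_nonexpressed = colMeans(draws_cn),
             lo_close_nonexpressed = q(draws_cn, 0.025),
             hi_close_nonexpressed = q(draws_cn, 0.975))
}

#' Gene-centric fraction of genes with a nearby intergenic signal
#'
#' Per cutoff and per call class (expressed / non-expressed), the
#' fraction of genes with at least one signal within x bp; optionally
#' restricted to the transcription-factor subset.
#'
#' @inheritParams classify_proximity
#' @param subset `"all"` or `"tf"` (uses the `is_tf` gene flag).
#' @return data.frame `cutoff`, `frac_expressed`, `frac_nonexpressed`,
#'   plus `n_expressed`, `n_nonexpressed` attributes.
#' @export
gene_fraction_with_signal <- function(genes, gene_calls, signals, condition,
                                      grid = distance_grid(),
                                      subset = c("all", "tf")) {
  subset <- match.arg(subset)
  g <- genes[genes$gene_id %in%
               gene_calls$gene_id[gene_calls$callable %in% TRUE], ,
             drop = FALSE]
  if (subset == "tf") g <- g[g$is_tf %in% TRUE, , drop = FALSE]
  expr_ids <- gene_calls$gene_id[
    gene_calls[[paste0("expressed_", condition)]] %in% TRUE]
  d <- min_dist_to(g, signals)  # symmetric metric: distance gene -> signal
  is_expr <- g$gene_id %in% expr_ids
  frac <- function(dd, x) if (length(dd)) sum(dd <= x) / length(dd) else NA
  out <- data.frame(cutoff = grid)
  out$frac_expressed <- vapply(grid, function(x) frac(d[is_expr], x),
                               numeric(1))
  out$frac_nonexpressed <- vapply(grid, function(x) frac(d[!is_expr], x),
                                  numeric(1))
  attr(out, "n_expressed") <- sum(is_expr)
  attr(out, "n_nonexpressed") <- sum(!is_expr)
  out
}

#' Gene neighborhoods: half-way to the next gene, capped
#'
#' A gene's neighborhood is its upstream and downstream flanks extending
#' half-way to the next annotated gene (primary source) or at most `cap`
#' bp, truncated at chromosome ends.  Neighborhoods of adjacent genes do
#' not overlap.
#'
#' @param genes primary-source gene table.
#' @param layout a [genome_layout()].
#' @param cap maximum flank extent in bp (default 50 Kb).
#' @return data.frame `gene_id`, `chrom`, `up_start`, `up_end`,
#'   `down_start`, `down_end` (either flank may be empty:
#'   start == end).
#' @export
gene_neighborhoods <- function(genes, layout, cap = 50000) {
  out <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    len <- layout$length[match(chr, layout$chrom)]
    n <- nrow(g)
    prev_end <- c(0, g$end[-n])
    next_start <- c(g$start[-1], len)
    # half-way boundary with the neighbour, capped
    up_start <- pmax(g$start - cap, g$start - floor((g$start - prev_end) / 2))
    up_start <- pmax(up_start, 0)
    down_end <- pmin(g$end + cap, g$end + floor((next_start - g$end) / 2))
    down_end <- pmin(down_end, len)
    out[[chr]] <- data.frame(gene_id = g$gene_id, chrom = chr,
                             up_start = up_start, up_end = g$start,
                             down_start = g$end, down_end = down_end,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Neighborhood coverage by unexplained intergenic signals
#'
#' Per call class, the fraction of genes whose neighborhood intersects at
#' least one signal, and the mean fraction of neighborhood length covered
#' by signals.
#'
#' @param genes primary-source gene table.
#' @param gene_calls a [call_genes()] result.
#' @param condition stage for expressed status.
#' @param signals signal regions (typically the `unexplained` category).
#' @param layout a [genome_layout()].
#' @param cap neighborhood cap in bp.
#' @return data.frame with one row per class (`expressed`,
#'   `nonexpressed`): `n_genes`, `frac_with_signal`, `mean_coverage`.
#' @export
neighborhood_coverage <- function(genes, gene_calls, condition, signals,
                                  layout, cap = 50000) {
  nb <- gene_neighborhoods(genes, layout, cap)
  expr_ids <- gene_calls$gene_id[
    gene_calls[[paste0("expressed_", condition)]] %in% TRUE]
  callable <- gene_calls$gene_id[gene_calls$callable %in% TRUE]
  nb <- nb[nb$gene_id %in% callable, , drop = FALSE]
  flanks <- data.frame(
    gene = rep(seq_len(nrow(nb)), 2),
    chrom = rep(nb$chrom, 2),
    start = c(nb$up_start, nb$down_start),
    end = c(nb$up_end, nb$down_end))
  flanks <- flanks[flanks$end > flanks$start, , drop = FALSE]
  hit <- logical(nrow(nb)); covg <- numeric(nrow(nb))
  total <- numeric(nrow(nb))
  if (nrow(flanks))
    total <- stats::setNames(
      vapply(split(flanks$end - flanks$start, flanks$gene), sum,
             numeric(1))[as.character(seq_len(nrow(nb)))], NULL)
  total[is.na(total)] <- 0
  if (nrow(signals) && nrow(flanks)) {
    sg <- IRanges::reduce(as_granges0(signals$chrom, signals$start,
                                      signals$end))
    fg <- as_granges0(flanks$chrom, flanks$start, flanks$end)
    ov <- GenomicRanges::findOverlaps(fg, sg, ignore.strand = TRUE)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      w <- pmin(flanks$end[qi], GenomicRanges::end(sg)[si]) -
        pmax(flanks$start[qi], GenomicRanges::start(sg)[si] - 1)
      cov_by_gene <- tapply(w, flanks$gene[qi], sum)
      gi <- as.integer(names(cov_by_gene))
      hit[gi] <- TRUE
      covg[gi] <- as.numeric(cov_by_gene) / total[gi]
    }
  }
  is_expr <- nb$gene_id %in% expr_ids
  cls <- function(sel) data.frame(
    n_genes = sum(sel),
    frac_with_signal = if (any(sel)) mean(hit[sel]) else NA,
    mean_coverage = if (any(sel)) mean(covg[sel]) else NA)
  out <- rbind(cbind(class = "expressed", cls(is_expr)),
               cbind(class = "nonexpressed", cls(!is_expr)))
  rownames(out) <- NULL
  out
}

#' Genes up-regulated from silent at the first stage
#'
#' Selects genes not expressed at the first stage but expressed at either
#' later stage, and computes their gene-centric proximity profiles
#' against the first-stage and last-stage signal sets.
#'
#' @param gene_calls a [call_genes()] result over three stages.
#' @param genes gene table.
#' @param signals_first,signals_last signal regions detected at the first
#'   and last stage.
#' @param grid distance cutoffs.
#' @return list: `gene_ids` (the selection), `profile_first`,
#'   `profile_last` (fraction of the selection with a signal within x).
#' @export
select_upregulated_from_silent <- function(gene_calls, genes,
                                           signals_first, signals_last,
                                           grid = distance_grid()) {
  conditions <- attr(gene_calls, "conditions")
  if (is.null(conditions))
    conditions <- sub("^expressed_",
                      "", grep("^expressed_", names(gene_calls), value = TRUE))
  first <- paste0("expressed_", conditions[1])
  later <- paste0("expressed_", conditions[-1])
  sel <- gene_calls$callable %in% TRUE &
    !(gene_calls[[first]] %in% TRUE) &
    (gene_calls[[later[1]]] %in% TRUE | gene_calls[[later[2]]] %in% TRUE)
  ids <- gene_calls$gene_id[sel]
  g <- genes[genes$gene_id %in% ids, , drop = FALSE]
  prof <- function(sig) {
    if (nrow(g) == 0) return(data.frame(cutoff = grid, frac = NA))
    d <- min_dist_to(g, sig)
    data.frame(cutoff = grid,
               frac = vapply(grid, function(x) mean(d <= x), numeric(1)))
  }
  list(gene_ids = ids,
       profile_first = prof(signals_first),
       profile_last = prof(signals_last))
}
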