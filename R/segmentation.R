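#' Segmentation parameters
#'
#' @param min_region_length minimum genomic span (bp) of a reported
#'   transcribed region.
#' @param max_unspotted_gap largest probe-free stretch (bp) allowed inside
#'   an intronic region; larger gaps split the region.
#' @param flank_distance bp within which an intergenic region counts as
#'   flanking a gene annotation.
#' @param ensembl_min_overlap bp of overlap with an ensembl model needed
#'   for the `ensembl_overlap` category.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_region_length = 300,
                                max_unspotted_gap = 100,
                                flank_distance = 100,
                                ensembl_min_overlap = 200) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) >= 0))
  class(p) <- "segmentation_params"
  p
}

#' Detect intronic or intergenic transcribed regions
#'
#' Merges adjacent above-threshold window blocks within the same intron
#' or intergenic region into maximal runs; a run's length is its genomic
#' span.  Intronic runs are additionally split wherever a probe-free
#' stretch longer than `max_unspotted_gap` occurs, and every candidate is
#' re-checked against `min_region_length`.
#'
#' @param block_calls output of [call_blocks()].
#' @param pm the [probe_matrix()] (probe coordinates define unspotted
#'   stretches).
#' @param kind `"intronic"` or `"intergenic"`.
#' @param condition stage whose expressed flags drive detection.
#' @param params a [segmentation_params()].
#' @return data.frame of class `signal_regions`: `signal_id`, `chrom`,
#'   `start`, `end`, `kind`, `condition`, `owner` (gene id for intronic).
#' @export
detect_signal_regions <- function(block_calls, pm,
                                  kind = c("intergenic", "intronic"),
                                  condition, params = segmentation_params()) {
  kind <- match.arg(kind)
  block_kind <- if (kind == "intronic") "intron" else "intergenic"
  flag_col <- paste0("expressed_", condition)
  if (!flag_col %in% names(block_calls))
    stop("no expressed flags for condition ", condition)
  b <- block_calls[block_calls$kind == block_kind, , drop = FALSE]
  b <- b[order(b$region_id, b$start), , drop = FALSE]
  out <- list()
  for (rid in unique(b$region_id)) {
    rb <- b[b$region_id == rid, , drop = FALSE]
    expr <- rb[[flag_col]]
    if (!any(expr)) next
    r <- rle(expr)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    for (run in which(r$values)) {
      s <- rb$start[starts_i[run]]
      e <- rb$end[ends_i[run]]
      pieces <- data.frame(start = s, end = e)
      if (kind == "intronic")
        pieces <- split_at_unspotted(s, e, rb$chrom[1], pm,
                                     params$max_unspotted_gap)
      pieces <- pieces[pieces$end - pieces$start >=
                         params$min_region_length, , drop = FALSE]
      if (nrow(pieces))
        out[[length(out) + 1]] <- data.frame(
          chrom = rb$chrom[1], start = pieces$start, end = pieces$end,
          kind = kind, condition = condition,
          owner = if (kind == "intronic") rb$owner[1] else NA_character_,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               kind = character(), condition = character(),
               owner = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(signal_id = sprintf("%s_%s_%04d", substr(kind, 1, 5),
                                   condition, seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  class(out) <- c("signal_regions", "data.frame")
  out
}

# split [s, e) wherever probe-free internal stretches exceed max_gap
split_at_unspotted <- function(s, e, chrom, pm, max_gap) {
  pr <- pm$probes
  pr <- pr[pr$chrom == chrom & pr$end > s & pr$start < e, , drop = FALSE]
  if (nrow(pr) == 0) return(data.frame(start = s, end = e))
  cov <- IRanges::reduce(IRanges::IRanges(pmax(pr$start, s) + 1,
                                          pmin(pr$end, e)))
  gaps <- IRanges::gaps(cov, start = s + 1, end = e)
  big <- gaps[IRanges::width(gaps) > max_gap]
  if (!length(big)) return(data.frame(start = s, end = e))
  keep <- IRanges::gaps(big, start = s + 1, end = e)
  data.frame(start = IRanges::start(keep) - 1, end = IRanges::end(keep))
}

#' Classify intergenic transcribed regions against the annotation
#'
#' Mutually exclusive, exhaustive categories applied in precedence order:
#' `flanking_ucsc` (within `flank_distance` of a primary-source gene
#' span), `ensembl_overlap` (overlapping an ensembl model by at least
#' `ensembl_min_overlap` bp), `ensembl_flanking` (within `flank_distance`
#' of an ensembl model), else `unexplained`.
#'
#' @param regions a [detect_signal_regions()] result (intergenic).
#' @param ann a `gene_annotation` carrying both sources.
#' @param params a [segmentation_params()].
#' @return `regions` with a `category` column added.
#' @export
classify_intergenic <- function(regions, ann, params = segmentation_params()) {
  ug <- ann$genes[ann$genes$source == "ucsc", , drop = FALSE]
  eg <- ann$genes[ann$genes$source == "ensembl", , drop = FALSE]
  n <- nrow(regions)
  category <- rep("unexplained", n)
  min_dist <- function(r, genes) {
    gi <- genes[genes$chrom == regions$chrom[r], , drop = FALSE]
    if (nrow(gi) == 0) return(Inf)
    min(interval_distance(regions$chrom[r], regions$start[r], regions$end[r],
                          gi$chrom, gi$start, gi$end))
  }
  max_overlap <- function(r, genes) {
    gi <- genes[genes$chrom == regions$chrom[r], , drop = FALSE]
    if (nrow(gi) == 0) return(0)
    max(pmax(0, pmin(regions$end[r], gi$end) -
               pmax(regions$start[r], gi$start)))
  }
  for (r in seq_len(n)) {
    if (min_dist(r, ug) <= params$flank_distance) {
      category[r] <- "flanking_ucsc"
    } else if (max_overlap(r, eg) >= params$ensembl_min_overlap) {
      category[r] <- "ensembl_overlap"
    } else if (min_dist(r, eg) <= params$flank_distance) {
      category[r] <- "ensembl_flanking"
    }
  }
  regions$category <- category
  regions
}

#' Tabulate intergenic classification categories
#'
#' @param regions a [classify_intergenic()] result.
#' @return named numeric vector over the four categories plus `total`;
#'   the categories always sum to the total (classification is a
#'   partition).
#' @export
count_categories <- function(regions) {
  cats <- c("flanking_ucsc", "ensembl_overlap", "ensembl_flanking",
            "unexplained")
  counts <- vapply(cats, function(k) sum(regions$category == k), numeric(1))
  c(counts, total = nrow(regions))
}

#' Genes with intronic signal, and how many are themselves expressed
#'
#' @param intronic_regions a [detect_signal_regions()] result of kind
#'   `"intronic"` for one condition.
#' @param gene_calls a [call_genes()] result.
#' @param condition the stage to take expressed status from; defaults to
#'   the regions' condition.
#' @return named vector `c(genes_with_signal, of_which_expressed)`.
#' @export
intronic_gene_summary <- function(intronic_regions, gene_calls,
                                  condition = NULL) {
  if (is.null(condition)) condition <- unique(intronic_regions$condition)[1]
  gids <- unique(intronic_regions$owner)
  gids <- gids[!is.na(gids)]
  expr_col <- paste0("expressed_", condition)
  expressed <- gene_calls$gene_id[gene_calls[[expr_col]] %in% TRUE]
  c(genes_with_signal = length(gids),
    of_which_expressed = length(intersect(gids, expressed)))
}
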