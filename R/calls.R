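#' Expression thresholds from intergenic blocks
#'
#' The expression threshold is the 99th percentile of the distribution of
#' expression levels over blocks annotated as intergenic (probed blocks
#' only), computed with linear interpolation between order statistics at
#' rank `p * (n - 1) + 1` (R quantile type 7).  Default scope is
#' per-(condition, chromosome); cells with fewer than `min_blocks`
#' intergenic blocks fall back to the per-condition global threshold with
#' a warning.
#'
#' @param bx a `block_expression` (from [fit_block_model()]).
#' @param scope `"per_chromosome"` or `"global"`.
#' @param percentile threshold percentile (proportion; default 0.99).
#' @param min_blocks minimum intergenic blocks per scope cell.
#' @return data.frame of class `threshold_set` with columns `condition`,
#'   `chrom` (`*` for global), `threshold`.
#' @export
compute_thresholds <- function(bx, scope = c("per_chromosome", "global"),
                               percentile = 0.99, min_blocks = 100) {
  scope <- match.arg(scope)
  conditions <- names(level_cols(bx))
  ig <- bx[bx$kind == "intergenic" & bx$n_probes >= 1, , drop = FALSE]
  if (nrow(ig) == 0) stop("no probed intergenic blocks: cannot set thresholds")
  lc <- level_cols(bx)
  global <- vapply(conditions, function(cc)
    stats::quantile(ig[[lc[cc]]], percentile, names = FALSE, type = 7),
    numeric(1))
  if (scope == "global") {
    out <- data.frame(condition = conditions, chrom = "*",
                      threshold = global, stringsAsFactors = FALSE)
  } else {
    chroms <- unique(bx$chrom[bx$kind == "intergenic"])
    out <- expand.grid(condition = conditions, chrom = chroms,
                       stringsAsFactors = FALSE)
    out$threshold <- NA_real_
    fell_back <- FALSE
    for (i in seq_len(nrow(out))) {
      cell <- ig[ig$chrom == out$chrom[i], , drop = FALSE]
      if (nrow(cell) < min_blocks) {
        out$threshold[i] <- global[[out$condition[i]]]
        fell_back <- TRUE
      } else {
        out$threshold[i] <- stats::quantile(cell[[lc[out$condition[i]]]],
                                            percentile, names = FALSE,
                                            type = 7)
      }
    }
    if (fell_back)
      warning("some (condition, chromosome) cells had < ", min_blocks,
              " intergenic blocks; global threshold used there")
  }
  rownames(out) <- NULL
  class(out) <- c("threshold_set", "data.frame")
  out
}

lookup_threshold <- function(thresholds, condition, chrom) {
  key <- paste(thresholds$condition, thresholds$chrom)
  th <- thresholds$threshold[match(paste(condition, chrom), key)]
  miss <- is.na(th)
  if (any(miss)) {
    th[miss] <- thresholds$threshold[
      match(paste(condition[miss], "*"), key)]
  }
  if (anyNA(th)) stop("missing threshold for some (condition, chromosome)")
  th
}

#' Call blocks expressed against the thresholds
#'
#' A block is expressed in a condition iff its level strictly exceeds the
#' threshold for that (condition, chromosome); blocks without probes are
#' never expressed.
#'
#' @param bx a `block_expression`.
#' @param thresholds a [compute_thresholds()] result.
#' @return `bx` with one logical `expressed_<condition>` column per
#'   condition added (class `block_calls`).
#' @export
call_blocks <- function(bx, thresholds) {
  conditions <- names(level_cols(bx))
  lc <- level_cols(bx)
  for (cc in conditions) {
    th <- lookup_threshold(thresholds, rep(cc, nrow(bx)), bx$chrom)
    expr <- !is.na(bx[[lc[cc]]]) & bx[[lc[cc]]] > th & bx$n_probes >= 1
    bx[[paste0("expressed_", cc)]] <- expr
  }
  class(bx) <- unique(c("block_calls", class(bx)))
  bx
}

#' Call exon blocks expressed
#'
#' [call_blocks()] restricted to exon blocks.
#'
#' @inheritParams call_blocks
#' @return exon rows of the `block_calls`.
#' @export
call_exons <- function(bx, thresholds) {
  out <- call_blocks(bx, thresholds)
  out[out$kind == "exon", , drop = FALSE]
}

fraction_calls <- function(exon_ids_by_unit, exon_calls, conditions,
                           fraction) {
  probed <- exon_calls$block_id[exon_calls$n_probes >= 1]
  em <- as.matrix(exon_calls[paste0("expressed_", conditions)])
  rownames(em) <- exon_calls$block_id
  t(vapply(exon_ids_by_unit, function(ids) {
    ids <- intersect(ids, probed)
    if (length(ids) == 0) return(rep(NA, length(conditions)))
    colMeans(em[ids, , drop = FALSE]) >= fraction
  }, logical(length(conditions))))
}

#' Call genes expressed from exon calls
#'
#' A gene is expressed in a condition when at least `fraction` (default
#' 50%) of its probed exon blocks are expressed; the gene's exon set is
#' the deduplicated union of its transcripts' exons.  Small-RNA-biotype
#' genes with span <= `small_rna_min_length` are excluded from calling
#' entirely; genes with zero probed exon blocks are flagged uncallable
#' (`NA` calls).
#'
#' @param ann a `gene_annotation`.
#' @param exon_calls output of [call_exons()].
#' @param fraction inclusive expressed-exon fraction cutoff.
#' @param small_rna_min_length bp; smallRNA genes at or below this span
#'   are not considered.
#' @return data.frame of class `gene_calls`: `gene_id`, `callable`, one
#'   logical `expressed_<condition>` per condition.
#' @export
call_genes <- function(ann, exon_calls, fraction = 0.5,
                       small_rna_min_length = 100) {
  conditions <- grep("^expressed_", names(exon_calls), value = TRUE)
  conditions <- sub("^expressed_", "", conditions)
  g <- ann$genes
  considered <- !(g$biotype == "smallRNA" &
                    (g$end - g$start) <= small_rna_min_length)
  ids_by_gene <- split(ann$exons$exon_id, ann$exons$gene_id)[
    g$gene_id[considered]]
  calls <- fraction_calls(ids_by_gene, exon_calls, conditions, fraction)
  out <- data.frame(gene_id = g$gene_id[considered],
                    callable = !is.na(calls[, 1]),
                    stringsAsFactors = FALSE)
  for (c in seq_along(conditions))
    out[[paste0("expressed_", conditions[c])]] <- calls[, c]
  attr(out, "conditions") <- conditions
  attr(out, "excluded") <- g$gene_id[!considered]
  class(out) <- c("gene_calls", "data.frame")
  out
}

#' Call transcripts expressed from exon calls
#'
#' A transcript is expressed in a condition when at least `fraction`
#' (default 80%) of its probed exon blocks are expressed.  Transcripts of
#' excluded small-RNA genes are not considered.
#'
#' @inheritParams call_genes
#' @return data.frame of class `transcript_calls`.
#' @export
call_transcripts <- function(ann, exon_calls, fraction = 0.8,
                             small_rna_min_length = 100) {
  conditions <- grep("^expressed_", names(exon_calls), value = TRUE)
  conditions <- sub("^expressed_", "", conditions)
  g <- ann$genes
  excluded_genes <- g$gene_id[g$biotype == "smallRNA" &
                                (g$end - g$start) <= small_rna_min_length]
  tx <- ann$transcripts[!ann$transcripts$gene_id %in% excluded_genes, ,
                        drop = FALSE]
  te <- ann$transcript_exons
  ids_by_tx <- split(te$exon_id, te$transcript_id)[tx$transcript_id]
  calls <- fraction_calls(ids_by_tx, exon_calls, conditions, fraction)
  out <- data.frame(transcript_id = tx$transcript_id,
                    gene_id = tx$gene_id,
                    callable = !is.na(calls[, 1]),
                    stringsAsFactors = FALSE)
  for (c in seq_along(conditions))
    out[[paste0("expressed_", conditions[c])]] <- calls[, c]
  attr(out, "conditions") <- conditions
  class(out) <- c("transcript_calls", "data.frame")
  out
}

#' Three-stage overlap partition of expressed-gene sets
#'
#' Partitions the union of three expressed-gene sets into the seven
#' non-empty cells of the 3-set Venn diagram and re-derives per-stage
#' totals (each total is the sum of the four cells containing that
#' stage).
#'
#' @param sets either a named list of three character vectors of expressed
#'   gene ids, or a `gene_calls` data.frame (callable genes are used).
#' @param universe optional common gene universe; defaults to the union.
#'   Ids outside the universe are an error.
#' @return list of class `stage_partition` with elements `cells` (named
#'   7-vector, names like `"E11.5&E13.5"`), `totals` (named 3-vector),
#'   `conditions`.
#' @export
partition_stages <- function(sets, universe = NULL) {
  if (is.data.frame(sets)) {
    conditions <- sub("^expressed_",
                      "", grep("^expressed_", names(sets), value = TRUE))
    keep <- sets$callable %in% TRUE
    sets <- lapply(conditions, function(cc)
      sets$gene_id[keep & sets[[paste0("expressed_", cc)]] %in% TRUE])
    names(sets) <- conditions
  }
  if (length(sets) != 3) stop("partition_stages expects exactly 3 sets")
  conditions <- names(sets)
  all_ids <- unique(unlist(sets))
  if (!is.null(universe)) {
    if (length(setdiff(all_ids, universe)))
      stop("expressed ids outside the shared gene universe")
  }
  mem <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) mem <- matrix(mem, nrow = 1)
  key <- mem %*% c(4, 2, 1)  # A=4, B=2, C=1
  cell_names <- c("100" = conditions[1],
                  "010" = conditions[2],
                  "001" = conditions[3],
                  "110" = paste(conditions[1], conditions[2], sep = "&"),
                  "101" = paste(conditions[1], conditions[3], sep = "&"),
                  "011" = paste(conditions[2], conditions[3], sep = "&"),
                  "111" = paste(conditions, collapse = "&"))
  codes <- c("100" = 4, "010" = 2, "001" = 1, "110" = 6, "101" = 5,
             "011" = 3, "111" = 7)
  cells <- vapply(codes, function(k) sum(key == k), numeric(1))
  names(cells) <- cell_names[names(codes)]
  totals <- vapply(seq_along(conditions), function(i)
    sum(cells[grepl(conditions[i], names(cells), fixed = TRUE)]),
    numeric(1))
  names(totals) <- conditions
  structure(list(cells = cells, totals = totals, conditions = conditions),
            class = "stage_partition")
}

#' Construct synthetic gene sets realizing given partition cells
#'
#' Given the seven Venn-cell counts, builds three gene-id sets whose
#' [partition_stages()] result reproduces them exactly.  Cell names use
#' the same `"A"`, `"A&B"`, `"A&B&C"` convention as `partition_stages()`.
#'
#' @param cells named numeric vector of 7 cell counts.
#' @param conditions the three stage labels, in order.
#' @return named list of three character vectors.
#' @export
sets_from_partition <- function(cells,
                                conditions = c("E11.5", "E13.5", "E15.5")) {
  wanted <- c(conditions,
              paste(conditions[1], conditions[2], sep = "&"),
              paste(conditions[1], conditions[3], sep = "&"),
              paste(conditions[2], conditions[3], sep = "&"),
              paste(conditions, collapse = "&"))
  if (!all(names(cells) %in% wanted))
    stop("unknown cell name(s): ",
         paste(setdiff(names(cells), wanted), collapse = ", "))
  counts <- stats::setNames(rep(0, 7), wanted)
  counts[names(cells)] <- cells
  sets <- stats::setNames(vector("list", 3), conditions)
  off <- 0
  for (i in seq_along(wanted)) {
    n <- counts[i]
    if (n == 0) next
    ids <- sprintf("gene%06d", off + seq_len(n))
    off <- off + n
    members <- strsplit(wanted[i], "&", fixed = TRUE)[[1]]
    for (m in members) sets[[m]] <- c(sets[[m]], ids)
  }
  sets
}

#' Two-decimal percentage, truncated
#'
#' Formats `100 * num / den` truncated (not rounded) to two decimals, the
#' convention of the summary tabulations this package mirrors.
#'
#' @param num,den numerator and denominator counts.
#' @param with_counts append `"(num/den)"`?
#' @return character vector like `"41.17%"`.
#' @export
format_pct <- function(num, den, with_counts = FALSE) {
  pct <- ifelse(den > 0, floor(100 * 100 * num / den + 1e-9) / 100, NA)
  out <- sprintf("%.2f%%", pct)
  if (with_counts) out <- sprintf("%s (%d/%d)", out, num, den)
  out
}

#' Summary table of expression calls
#'
#' Per-stage counts and truncated two-decimal percentages of expressed
#' exon blocks, transcripts and genes, plus the biotype breakdown among
#' expressed genes (coding / antisense / non-coding), mirroring the
#' headline tabulation layout.
#'
#' @param exon_calls,transcript_calls,gene_calls call tables.
#' @param ann the `gene_annotation`.
#' @return data.frame with columns `row`, one formatted column per stage.
#' @export
summarize_calls <- function(exon_calls, transcript_calls, gene_calls, ann) {
  conditions <- attr(gene_calls, "conditions")
  fmt_block <- function(calls, id_col) {
    callable <- calls$callable %in% TRUE
    vapply(conditions, function(cc)
      format_pct(sum(calls[[paste0("expressed_", cc)]][callable]),
                 sum(callable), with_counts = TRUE), character(1))
  }
  exon_probed <- exon_calls$n_probes >= 1
  exon_row <- vapply(conditions, function(cc)
    format_pct(sum(exon_calls[[paste0("expressed_", cc)]][exon_probed]),
               sum(exon_probed), with_counts = TRUE), character(1))
  tx_row <- fmt_block(transcript_calls)
  gene_row <- fmt_block(gene_calls)
  bio <- ann$genes$biotype[match(gene_calls$gene_id, ann$genes$gene_id)]
  bio_group <- ifelse(bio == "coding", "coding",
                      ifelse(bio == "antisense", "antisense", "noncoding"))
  bio_rows <- lapply(c("coding", "antisense", "noncoding"), function(bg) {
    vapply(conditions, function(cc) {
      expr <- gene_calls$callable %in% TRUE &
        gene_calls[[paste0("expressed_", cc)]] %in% TRUE
      format_pct(sum(expr & bio_group == bg), sum(expr), with_counts = TRUE)
    }, character(1))
  })
  out <- rbind(exon_row, tx_row, gene_row, bio_rows[[1]], bio_rows[[2]],
               bio_rows[[3]])
  out <- data.frame(row = c("Exons", "Transcripts", "Genes",
                            "Gene models: coding", "Gene models: antisense",
                            "Gene models: non-coding"),
                    out, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- c("row", conditions)
  rownames(out) <- NULL
  out
}
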