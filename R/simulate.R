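#' Simulation parameters
#'
#' Parameters of the synthetic tiling-array study.  Defaults describe a
#' two-chromosome 12-Mb toy genome tiled at the resolution of a 25-mer /
#' 35-bp-spacing whole-genome design, with 300 annotated genes of which
#' 40% are expressed (log2 shift +3.0 over background), per-probe affinity
#' effects (sd 0.5), replicate noise (sd 0.3), 30 planted differentially
#' expressed genes (2.0 log2 units), and 40 planted intergenic transcribed
#' regions whose placement is enriched 4-fold within 10 kb of expressed
#' genes.  The planted signal occupies well under 1% of intergenic
#' windows, so the 99th-percentile threshold stays in the background mode
#' as it does on real genomes.  A quarter of the planted intergenic
#' signals are placed over ensembl-only gene models, emulating intergenic
#' transcription that is identifiable via the secondary annotation
#' source.
#'
#' @param seed integer RNG seed; fixing it fixes every emitted object.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of primary-source (ucsc-like) genes.
#' @param exon_count_range,exon_length_range,intron_length_range gene
#'   structure ranges (bp).
#' @param probe_length,probe_spacing tiling design (bp).
#' @param fraction_expressed proportion of genes expressed.
#' @param expressed_shift log2 intensity added over expressed exons.
#' @param probe_affinity_sd,replicate_noise_sd log2-scale noise terms.
#' @param background_mean mean background log2 intensity.
#' @param n_de_genes,de_effect planted differential expression.
#' @param n_intergenic_signals,intergenic_signal_length_range planted
#'   intergenic transcribed regions.
#' @param intergenic_near_expressed_enrichment odds multiplier for placing
#'   an intergenic signal within `enrichment_distance` of an expressed
#'   gene (1 = uniform over intergenic space).
#' @param enrichment_distance bp defining "near" for the enrichment.
#' @param fraction_signals_on_ensembl proportion of planted intergenic
#'   signals placed over an ensembl-only gene model.
#' @param n_intronic_signals,intronic_signal_length_range planted intronic
#'   transcribed regions.
#' @param n_unspotted_gaps,unspotted_gap_length probe-free windows deleted
#'   from the tiling (exercises the intronic gap rule).
#' @param fraction_tf proportion of genes flagged as transcription factors.
#' @param fraction_ensembl_only ensembl-only gene count as a fraction of
#'   `n_genes`.
#' @param conservation_base mean conservation score of the synthetic track.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 6e6,
                       n_genes = 300L,
                       exon_count_range = c(4L, 8L),
                       exon_length_range = c(100L, 300L),
                       intron_length_range = c(200L, 1000L),
                       probe_length = 25L,
                       probe_spacing = 35L,
                       fraction_expressed = 0.40,
                       expressed_shift = 3.0,
                       probe_affinity_sd = 0.5,
                       replicate_noise_sd = 0.3,
                       background_mean = 6.0,
                       n_de_genes = 30L,
                       de_effect = 2.0,
                       n_intergenic_signals = 40L,
                       intergenic_signal_length_range = c(600L, 3000L),
                       intergenic_near_expressed_enrichment = 4,
                       enrichment_distance = 10000L,
                       fraction_signals_on_ensembl = 0.25,
                       n_intronic_signals = 60L,
                       intronic_signal_length_range = c(400L, 1500L),
                       n_unspotted_gaps = 20L,
                       unspotted_gap_length = 150L,
                       fraction_tf = 0.06,
                       fraction_ensembl_only = 0.15,
                       conservation_base = 0.15) {
  p <- as.list(environment())
  stopifnot(p$probe_spacing >= 1, p$probe_length >= 1,
            p$fraction_expressed >= 0, p$fraction_expressed <= 1,
            p$fraction_tf >= 0, p$fraction_tf <= 1,
            p$fraction_signals_on_ensembl >= 0,
            p$fraction_signals_on_ensembl <= 1,
            all(p$exon_count_range >= 1), all(p$exon_length_range >= 1),
            all(p$intron_length_range >= 1), p$chrom_length > 0)
  class(p) <- "sim_params"
  p
}

#' Sample design of the staged study
#'
#' @param conditions ordered condition (stage) labels.
#' @param n_replicates replicates per condition (>= 1).
#' @return data.frame with columns `sample_id`, `condition`, `replicate`;
#'   class `sample_design`.
#' @export
sample_design <- function(conditions = c("E11.5", "E13.5", "E15.5"),
                          n_replicates = 2L) {
  stopifnot(n_replicates >= 1)
  out <- data.frame(
    sample_id = paste0(rep(conditions, each = n_replicates), "_r",
                       rep(seq_len(n_replicates), length(conditions))),
    condition = rep(conditions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(conditions)),
    stringsAsFactors = FALSE)
  attr(out, "conditions") <- conditions
  class(out) <- c("sample_design", "data.frame")
  out
}

# place n intervals of given lengths uniformly on [0, chrom_len) without
# overlapping `occupied` (2-col matrix start,end) or each other
place_disjoint <- function(lengths, chrom_len, occupied, max_try = 500L) {
  placed <- matrix(numeric(0), ncol = 2)
  occ_s <- occupied[, 1]; occ_e <- occupied[, 2]
  for (len in lengths) {
    ok <- FALSE
    for (k in seq_len(max_try)) {
      s <- floor(stats::runif(1, 0, chrom_len - len))
      e <- s + len
      if (!any(s < occ_e & e > occ_s)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place interval after ", max_try,
                  " tries; reduce n_genes or counts, or enlarge the genome")
    placed <- rbind(placed, c(s, e))
    occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
  }
  placed
}

# fixed stage-pattern mixture for expressed genes (E11.5, E13.5, E15.5);
# emulates the ~95% three-stage overlap of the observed data
stage_patterns <- function() {
  list(prob = c(0.90, 0.04, 0.02, 0.02, 0.01, 0.005, 0.005),
       pattern = list(c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE),
                      c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                      c(TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE),
                      c(FALSE, TRUE, FALSE)))
}

#' Simulate a toy genome and two-source annotation
#'
#' Generates the genome layout, gene models from both annotation sources
#' (primary `ucsc`-like genes plus short `ensembl`-only models standing in
#' for miRNA/snoRNA/pseudogene annotations), transcript structure, and the
#' expression/differential-expression ground truth.  Deterministic for a
#' fixed `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list with elements `layout`, `annotation`, `truth` (list with
#'   `genes` and, after [simulate_intensities()], `signals`), `params`.
#' @export
simulate_genome <- function(params = sim_params()) {
  set.seed(params$seed)
  conditions <- c("E11.5", "E13.5", "E15.5")
  layout <- genome_layout(paste0("chr", seq_len(params$n_chromosomes)),
                          rep(params$chrom_length, params$n_chromosomes))

  n <- params$n_genes
  if (n > 0) {
    ec <- sample(seq(params$exon_count_range[1], params$exon_count_range[2]),
                 n, replace = TRUE)
    gene_chrom <- sample(layout$chrom, n, replace = TRUE,
                         prob = layout$length / sum(layout$length))
  } else {
    ec <- integer(0); gene_chrom <- character(0)
  }

  genes <- list(); exons <- list(); txs <- list(); tes <- list()
  occ_by_chr <- stats::setNames(
    lapply(layout$chrom, function(x) matrix(numeric(0), ncol = 2)),
    layout$chrom)
  for (i in seq_len(n)) {
    ex_len <- sample(seq(params$exon_length_range[1],
                         params$exon_length_range[2]), ec[i], replace = TRUE)
    in_len <- if (ec[i] > 1)
      sample(seq(params$intron_length_range[1],
                 params$intron_length_range[2]), ec[i] - 1, replace = TRUE)
      else integer(0)
    glen <- sum(ex_len) + sum(in_len)
    chr <- gene_chrom[i]
    pl <- place_disjoint(glen, params$chrom_length, occ_by_chr[[chr]])
    occ_by_chr[[chr]] <- rbind(occ_by_chr[[chr]], pl)
    gs <- pl[1, 1]
    offs <- cumsum(c(0, utils::head(ex_len, -1) + in_len))
    gid <- sprintf("g%04d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chr, start = gs,
                             end = gs + glen,
                             strand = sample(c("+", "-"), 1),
                             source = "ucsc", biotype = NA_character_,
                             is_tf = FALSE, stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(
      exon_id = sprintf("%s.e%d", gid, seq_len(ec[i])), gene_id = gid,
      chrom = chr, start = gs + offs, end = gs + offs + ex_len,
      stringsAsFactors = FALSE)
    # transcript 1 = all exons; optionally a second, contiguous subset
    tx1 <- paste0(gid, ".t1")
    txs[[i]] <- data.frame(transcript_id = tx1, gene_id = gid,
                           stringsAsFactors = FALSE)
    tes[[i]] <- data.frame(transcript_id = tx1,
                           exon_id = exons[[i]]$exon_id,
                           stringsAsFactors = FALSE)
    if (ec[i] >= 3 && stats::runif(1) < 0.5) {
      a <- sample(seq_len(ec[i] - 1), 1)
      b <- sample(seq(a + 1, ec[i]), 1)
      tx2 <- paste0(gid, ".t2")
      txs[[i]] <- rbind(txs[[i]],
                        data.frame(transcript_id = tx2, gene_id = gid))
      tes[[i]] <- rbind(tes[[i]],
                        data.frame(transcript_id = tx2,
                                   exon_id = exons[[i]]$exon_id[a:b]))
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), source = character(),
               biotype = character(), is_tf = logical())
  if (n > 0) {
    genes$biotype <- sample(c("coding", "antisense", "noncoding"), n,
                            replace = TRUE, prob = c(0.90, 0.025, 0.075))
    genes$is_tf <- stats::runif(n) < params$fraction_tf
  }

  # ensembl-only models: short, intergenic relative to the primary source
  n_ens <- round(params$fraction_ensembl_only * n)
  ens_genes <- list(); ens_exons <- list(); ens_txs <- list(); ens_tes <- list()
  for (j in seq_len(n_ens)) {
    chr <- sample(layout$chrom, 1, prob = layout$length / sum(layout$length))
    len <- sample(80:600, 1)
    pl <- place_disjoint(len, params$chrom_length, occ_by_chr[[chr]])
    occ_by_chr[[chr]] <- rbind(occ_by_chr[[chr]], pl)
    gid <- sprintf("ens%04d", j)
    ens_genes[[j]] <- data.frame(
      gene_id = gid, chrom = chr, start = pl[1, 1], end = pl[1, 2],
      strand = sample(c("+", "-"), 1), source = "ensembl",
      biotype = sample(c("smallRNA", "pseudogene", "retrotransposed"), 1,
                       prob = c(0.4, 0.3, 0.3)),
      is_tf = FALSE, stringsAsFactors = FALSE)
    ens_exons[[j]] <- data.frame(exon_id = paste0(gid, ".e1"), gene_id = gid,
                                 chrom = chr, start = pl[1, 1], end = pl[1, 2],
                                 stringsAsFactors = FALSE)
    ens_txs[[j]] <- data.frame(transcript_id = paste0(gid, ".t1"),
                               gene_id = gid, stringsAsFactors = FALSE)
    ens_tes[[j]] <- data.frame(transcript_id = paste0(gid, ".t1"),
                               exon_id = paste0(gid, ".e1"),
                               stringsAsFactors = FALSE)
  }
  all_genes <- rbind(genes, if (n_ens) do.call(rbind, ens_genes))
  all_exons <- rbind(if (length(exons)) do.call(rbind, exons) else
                       data.frame(exon_id = character(), gene_id = character(),
                                  chrom = character(), start = numeric(),
                                  end = numeric()),
                     if (n_ens) do.call(rbind, ens_exons))
  all_txs <- rbind(if (length(txs)) do.call(rbind, txs) else
                     data.frame(transcript_id = character(), gene_id = character()),
                   if (n_ens) do.call(rbind, ens_txs))
  all_tes <- rbind(if (length(tes)) do.call(rbind, tes) else
                     data.frame(transcript_id = character(), exon_id = character()),
                   if (n_ens) do.call(rbind, ens_tes))
  ann <- gene_annotation(all_genes, all_exons, all_txs, all_tes)

  # ground truth: expression pattern per stage, planted DE
  expr <- matrix(FALSE, nrow(all_genes), 3,
                 dimnames = list(all_genes$gene_id, conditions))
  if (n > 0) {
    base_expr <- stats::runif(n) < params$fraction_expressed
    sp <- stage_patterns()
    pick <- sample(seq_along(sp$prob), n, replace = TRUE,
                   prob = sp$prob / sum(sp$prob))
    for (i in which(base_expr)) expr[i, ] <- sp$pattern[[pick[i]]]
  }
  de <- matrix(0L, nrow(all_genes), 2,
               dimnames = list(all_genes$gene_id,
                               c("E13.5_vs_E11.5", "E15.5_vs_E13.5")))
  shift <- matrix(0, nrow(all_genes), 3,
                  dimnames = dimnames(expr))
  shift[expr] <- params$expressed_shift
  all3 <- which(rowSums(expr) == 3 & all_genes$source == "ucsc")
  n_de <- min(params$n_de_genes, length(all3))
  if (n_de > 0) {
    de_idx <- sample(all3, n_de)
    pair <- rep(1:2, length.out = n_de)
    dir <- rep(c(1L, -1L), length.out = n_de)
    for (k in seq_len(n_de)) {
      i <- de_idx[k]
      de[i, pair[k]] <- dir[k]
      if (pair[k] == 1) {         # change at E13.5, persists at E15.5
        shift[i, 2:3] <- shift[i, 2:3] + dir[k] * params$de_effect
      } else {                    # change at E15.5 only
        shift[i, 3] <- shift[i, 3] + dir[k] * params$de_effect
      }
    }
  }
  truth_genes <- data.frame(gene_id = all_genes$gene_id,
                            source = all_genes$source,
                            expressed_E11.5 = expr[, 1],
                            expressed_E13.5 = expr[, 2],
                            expressed_E15.5 = expr[, 3],
                            de_E13.5_vs_E11.5 = de[, 1],
                            de_E15.5_vs_E13.5 = de[, 2],
                            stringsAsFactors = FALSE)

  sim <- list(layout = layout, annotation = ann,
              truth = list(genes = truth_genes, shift = shift,
                           occupied = occ_by_chr),
              params = params)
  sig_ig <- plant_intergenic_signals(sim)
  sig_in <- plant_intronic_signals(sim)
  sim$truth$intergenic_signals <- sig_ig
  sim$truth$intronic_signals <- sig_in
  sim$truth$signals <- rbind(
    sig_ig[, c("signal_id", "chrom", "start", "end", "kind")],
    sig_in[, c("signal_id", "chrom", "start", "end", "kind")])
  sim
}

# accept/reject placement of intergenic signals with proximity enrichment
plant_intergenic_signals <- function(sim) {
  params <- sim$params
  layout <- sim$layout
  ann <- sim$annotation
  truth <- sim$truth
  n_sig <- params$n_intergenic_signals
  if (n_sig == 0)
    return(data.frame(signal_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), kind = character(),
                      on_ensembl = logical(), ensembl_gene_id = character()))
  expressed_any <- truth$genes$gene_id[
    truth$genes$expressed_E11.5 | truth$genes$expressed_E13.5 |
      truth$genes$expressed_E15.5]
  eg <- ann$genes[ann$genes$gene_id %in% expressed_any &
                    ann$genes$source == "ucsc", , drop = FALSE]
  occ <- truth$occupied
  enr <- params$intergenic_near_expressed_enrichment
  ens <- ann$genes[ann$genes$source == "ensembl", , drop = FALSE]
  n_on_ens <- round(params$fraction_signals_on_ensembl * n_sig)
  n_on_ens <- min(n_on_ens, nrow(ens))
  rows <- list()
  # signals over ensembl-only models: the signal covers the model and may
  # extend into surrounding intergenic space
  if (n_on_ens > 0) {
    pick <- sample(seq_len(nrow(ens)), n_on_ens)
    for (k in seq_len(n_on_ens)) {
      g <- ens[pick[k], ]
      len <- sample(seq(params$intergenic_signal_length_range[1],
                        params$intergenic_signal_length_range[2]), 1)
      len <- max(len, g$end - g$start)
      pad <- len - (g$end - g$start)
      left <- sample(0:pad, 1)
      s <- max(0, g$start - left)
      e <- min(sim$layout$length[match(g$chrom, layout$chrom)], s + len)
      rows[[length(rows) + 1]] <-
        data.frame(chrom = g$chrom, start = s, end = e, kind = "intergenic",
                   on_ensembl = TRUE, ensembl_gene_id = g$gene_id,
                   stringsAsFactors = FALSE)
    }
  }
  # remaining signals: uniform over intergenic space, enriched near
  # expressed genes via accept/reject
  n_free <- n_sig - length(rows)
  guard <- 0
  while (n_free > 0 && guard < 200000) {
    guard <- guard + 1
    chr <- sample(layout$chrom, 1, prob = layout$length / sum(layout$length))
    len <- sample(seq(params$intergenic_signal_length_range[1],
                      params$intergenic_signal_length_range[2]), 1)
    s <- floor(stats::runif(1, 0, layout$length[match(chr, layout$chrom)] - len))
    e <- s + len
    o <- occ[[chr]]
    if (nrow(o) && any(s < o[, 2] & e > o[, 1])) next
    ec <- eg[eg$chrom == chr, , drop = FALSE]
    d <- if (nrow(ec)) min(pmax(ec$start - e, s - ec$end, 0)) else Inf
    w <- if (d <= params$enrichment_distance) max(enr, 1) else
      if (enr >= 1) 1 else 1 / enr  # enr<1 depletes near placements
    if (stats::runif(1) > w / max(enr, 1, 1 / max(enr, 1e-9))) next
    occ[[chr]] <- rbind(occ[[chr]], c(s, e))
    rows[[length(rows) + 1]] <-
      data.frame(chrom = chr, start = s, end = e, kind = "intergenic",
                 on_ensembl = FALSE, ensembl_gene_id = NA_character_,
                 stringsAsFactors = FALSE)
    n_free <- n_free - 1
  }
  if (n_free > 0) stop("could not place intergenic signals; genome too full")
  out <- do.call(rbind, rows)
  out$signal_id <- sprintf("sig%04d", seq_len(nrow(out)))
  out[, c("signal_id", "chrom", "start", "end", "kind", "on_ensembl",
          "ensembl_gene_id")]
}

plant_intronic_signals <- function(sim) {
  params <- sim$params
  ann <- sim$annotation
  n_sig <- params$n_intronic_signals
  empty <- data.frame(signal_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), kind = character(),
                      gene_id = character(), gene_expressed_any = logical())
  if (n_sig == 0) return(empty)
  # introns = gene span minus exons, per primary-source gene
  g <- ann$genes[ann$genes$source == "ucsc", , drop = FALSE]
  tg <- sim$truth$genes
  expr_any <- tg$expressed_E11.5 | tg$expressed_E13.5 | tg$expressed_E15.5
  names(expr_any) <- tg$gene_id
  introns <- lapply(g$gene_id, function(gid) {
    gi <- g[g$gene_id == gid, ]
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    ir <- IRanges::gaps(IRanges::IRanges(ex$start + 1, ex$end),
                        start = gi$start + 1, end = gi$end)
    if (!length(ir)) return(NULL)
    data.frame(gene_id = gid, chrom = gi$chrom,
               start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  introns <- do.call(rbind, introns)
  if (is.null(introns) || nrow(introns) == 0) return(empty)
  introns$len <- introns$end - introns$start
  # 70% of intronic signals inside expressed genes, 30% inside silent ones
  introns$expr <- expr_any[introns$gene_id]
  rows <- list()
  for (k in seq_len(n_sig)) {
    want_expr <- stats::runif(1) < 0.7
    cand <- introns[introns$expr == want_expr &
                      introns$len >= params$intronic_signal_length_range[1], ,
                    drop = FALSE]
    if (nrow(cand) == 0)
      cand <- introns[introns$len >=
                        params$intronic_signal_length_range[1], , drop = FALSE]
    if (nrow(cand) == 0) break
    i <- sample(seq_len(nrow(cand)), 1)
    len <- sample(seq(params$intronic_signal_length_range[1],
                      min(params$intronic_signal_length_range[2],
                          cand$len[i])), 1)
    s <- cand$start[i] + floor(stats::runif(1, 0, cand$len[i] - len + 1))
    rows[[length(rows) + 1]] <-
      data.frame(chrom = cand$chrom[i], start = s, end = s + len,
                 kind = "intronic", gene_id = cand$gene_id[i],
                 gene_expressed_any = cand$expr[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$signal_id <- sprintf("isig%04d", seq_len(nrow(out)))
  out[, c("signal_id", "chrom", "start", "end", "kind", "gene_id",
          "gene_expressed_any")]
}

#' Simulate probe intensities for the staged design
#'
#' Lays out 25-mer probes at the configured spacing, deletes probes in the
#' configured unspotted gaps, plants intronic and intergenic transcribed
#' regions, and draws raw linear-scale intensities: probe log2 intensity =
#' background + expressed shift (over expressed exons of that stage and
#' over planted signals) + per-probe affinity (shared across samples) +
#' replicate noise.  The returned matrix is on the raw linear scale so the
#' full normalization path is exercised.
#'
#' @param sim output of [simulate_genome()].
#' @param design a [sample_design()] (3 conditions x 2 replicates by
#'   default).
#' @return `sim` with elements `probes` (a `probe_matrix`), `design`, and
#'   `truth$signals` added.
#' @export
simulate_intensities <- function(sim, design = sample_design()) {
  params <- sim$params
  set.seed(params$seed + 1L)
  conditions <- attr(design, "conditions")
  layout <- sim$layout

  sig_ig <- sim$truth$intergenic_signals
  sig_in <- sim$truth$intronic_signals

  probes <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    st <- seq(0, layout$length[i] - params$probe_length,
              by = params$probe_spacing)
    data.frame(chrom = layout$chrom[i], start = st,
               end = st + params$probe_length, stringsAsFactors = FALSE)
  }))
  # delete probes in unspotted gaps (placed inside introns when possible)
  gaps <- NULL
  if (params$n_unspotted_gaps > 0) {
    gp <- list()
    for (k in seq_len(params$n_unspotted_gaps)) {
      chr <- sample(layout$chrom, 1)
      s <- floor(stats::runif(1, 0,
                              layout$length[match(chr, layout$chrom)] -
                                params$unspotted_gap_length))
      gp[[k]] <- data.frame(chrom = chr, start = s,
                            end = s + params$unspotted_gap_length)
    }
    gaps <- do.call(rbind, gp)
    hit <- GenomicRanges::findOverlaps(
      as_granges0(probes$chrom, probes$start, probes$end),
      as_granges0(gaps$chrom, gaps$start, gaps$end))
    if (length(hit)) probes <- probes[-unique(S4Vectors::queryHits(hit)), ]
  }
  rownames(probes) <- NULL
  np <- nrow(probes)
  pg <- as_granges0(probes$chrom, probes$start, probes$end)

  # per-probe per-condition log2 shift
  shift_mat <- matrix(0, np, length(conditions))
  ex <- sim$annotation$exons
  if (nrow(ex)) {
    hits <- GenomicRanges::findOverlaps(
      pg, as_granges0(ex$chrom, ex$start, ex$end))
    if (length(hits)) {
      pi <- S4Vectors::queryHits(hits)
      gi <- match(ex$gene_id[S4Vectors::subjectHits(hits)],
                  rownames(sim$truth$shift))
      for (c in seq_along(conditions)) {
        v <- sim$truth$shift[gi, c]
        # a probe overlapping several exons takes the max shift
        agg <- tapply(v, pi, max)
        shift_mat[as.integer(names(agg)), c] <-
          pmax(shift_mat[as.integer(names(agg)), c], unlist(agg))
      }
    }
  }
  for (sig in list(sig_ig, sig_in)) {
    if (nrow(sig)) {
      hits <- GenomicRanges::findOverlaps(
        pg, as_granges0(sig$chrom, sig$start, sig$end))
      if (length(hits)) {
        pi <- unique(S4Vectors::queryHits(hits))
        shift_mat[pi, ] <- pmax(shift_mat[pi, ], params$expressed_shift)
      }
    }
  }

  affinity <- stats::rnorm(np, 0, params$probe_affinity_sd)
  intensity <- matrix(0, np, nrow(design),
                      dimnames = list(NULL, design$sample_id))
  cond_idx <- match(design$condition, conditions)
  for (s in seq_len(nrow(design))) {
    log2i <- params$background_mean + affinity + shift_mat[, cond_idx[s]] +
      stats::rnorm(np, 0, params$replicate_noise_sd)
    intensity[, s] <- 2 ^ log2i
  }

  sim$probes <- probe_matrix(probes, intensity, log2 = FALSE)
  sim$design <- design
  sim$unspotted_gaps <- gaps
  sim
}

#' Simulate a conservation score track
#'
#' Uniform-width steps (100 bp) with values clamped to `[0, 1]`.
#'
#' @param layout a [genome_layout()].
#' @param params a [sim_params()]; `conservation_base` sets the mean.
#' @param mode `"noisy"` (default) or `"constant"`.
#' @param step_width step width in bp.
#' @return a [score_track()].
#' @export
simulate_conservation <- function(layout, params = sim_params(),
                                  mode = c("noisy", "constant"),
                                  step_width = 100) {
  mode <- match.arg(mode)
  set.seed(params$seed + 2L)
  out <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    st <- seq(0, layout$length[i] - 1, by = step_width)
    en <- pmin(st + step_width, layout$length[i])
    v <- if (mode == "constant") rep(params$conservation_base, length(st))
         else pmin(1, pmax(0, stats::rnorm(length(st),
                                           params$conservation_base, 0.1)))
    data.frame(chrom = layout$chrom[i], start = st, end = en, value = v)
  }))
  score_track(out$chrom, out$start, out$end, out$value)
}

#' Simulate a full study
#'
#' Convenience wrapper: genome + annotation + intensities + conservation.
#'
#' @param params a [sim_params()].
#' @param design a [sample_design()].
#' @return simulation list (see [simulate_genome()],
#'   [simulate_intensities()]) with a `conservation` track added.
#' @export
simulate_study <- function(params = sim_params(), design = sample_design()) {
  sim <- simulate_genome(params)
  sim <- simulate_intensities(sim, design)
  sim$conservation <- simulate_conservation(sim$layout, params)
  sim
}

#' Write a simulated study to disk
#'
#' Emits annotation (GFF3 per source), one raw-intensity bedGraph per
#' sample, the conservation WIG, truth TSVs, the sample design TSV, and a
#' key-value manifest recording parameters and file paths.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  for (src in c("ucsc", "ensembl")) {
    ann_s <- subset_annotation(sim$annotation, src)
    write_annotation(ann_s, fp(paste0("annotation_", src, ".gff3")), "gff")
  }
  utils::write.table(sim$layout, fp("layout.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$design, fp("design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in seq_len(nrow(sim$design))) {
    tr <- score_track(sim$probes$probes$chrom, sim$probes$probes$start,
                      sim$probes$probes$end, sim$probes$intensity[, s])
    write_track(tr, fp(paste0("raw_", sim$design$sample_id[s], ".bedgraph")),
                "bedgraph")
  }
  if (!is.null(sim$conservation))
    write_track(sim$conservation, fp("conservation.wig"), "wig")
  utils::write.table(sim$truth$genes, fp("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$signals))
    utils::write.table(sim$truth$signals, fp("truth_signals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  pk <- sim$params[!vapply(sim$params, is.null, logical(1))]
  manifest <- c(
    sprintf("param.%s=%s", names(pk),
            vapply(pk, function(x) paste(x, collapse = ","), character(1))),
    sprintf("file.%s=%s",
            c("layout", "design", "truth_genes"),
            c("layout.tsv", "design.tsv", "truth_genes.tsv")))
  writeLines(manifest, fp("manifest.txt"))
  invisible(dir)
}

#' Restrict an annotation to one source
#'
#' @param ann a `gene_annotation`.
#' @param source `"ucsc"` or `"ensembl"`.
#' @return a `gene_annotation` containing only that source's models.
#' @export
subset_annotation <- function(ann, source) {
  keep <- ann$genes$source %in% source
  gids <- ann$genes$gene_id[keep]
  ex <- ann$exons[ann$exons$gene_id %in% gids, , drop = FALSE]
  tx <- ann$transcripts[ann$transcripts$gene_id %in% gids, , drop = FALSE]
  te <- ann$transcript_exons[
    ann$transcript_exons$transcript_id %in% tx$transcript_id, , drop = FALSE]
  gene_annotation(ann$genes[keep, , drop = FALSE], ex, tx, te)
}
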