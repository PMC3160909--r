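#' Genome layout
#'
#' A genome layout is the coordinate space every other object lives on: an
#' ordered set of chromosomes with lengths.  All coordinates in this package
#' are 0-based half-open `[start, end)`; conversion to the 1-based closed
#' convention of GFF3 (and of GenomicRanges internally) happens only at I/O
#' boundaries.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return A `data.frame` of class `genome_layout` with columns `chrom`,
#'   `length`.
#' @export
genome_layout <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  out <- data.frame(chrom = as.character(chrom), length = length,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Gene annotation container
#'
#' Bundles gene models, their exons, and the transcript structure from one or
#' two annotation sources (a `ucsc`-like primary source and an
#' `ensembl`-like complement).  Validated on construction: exons must lie
#' within their gene span, be pairwise disjoint and sorted; every transcript
#' maps to exactly one gene.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `*`), `source` (`ucsc` or `ensembl`),
#'   `biotype` (one of `coding`, `noncoding`, `antisense`, `pseudogene`,
#'   `retrotransposed`, `smallRNA`), `is_tf` (logical).
#' @param exons data.frame with columns `exon_id`, `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param transcript_exons data.frame with columns `transcript_id`,
#'   `exon_id`.
#' @return A list of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, transcripts, transcript_exons) {
  ann <- structure(list(genes = as.data.frame(genes),
                        exons = as.data.frame(exons),
                        transcripts = as.data.frame(transcripts),
                        transcript_exons = as.data.frame(transcript_exons)),
                   class = "gene_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  g <- ann$genes; e <- ann$exons
  if (nrow(g) == 0) return(invisible(ann))
  if (anyDuplicated(g$gene_id)) stop("gene_id values must be unique")
  if (any(g$end - g$start < 1)) stop("gene span length must be >= 1")
  bad_bio <- setdiff(unique(g$biotype),
                     c("coding", "noncoding", "antisense", "pseudogene",
                       "retrotransposed", "smallRNA"))
  if (length(bad_bio)) stop("unknown biotype: ", paste(bad_bio, collapse = ", "))
  if (nrow(e)) {
    idx <- match(e$gene_id, g$gene_id)
    if (anyNA(idx)) stop("exon refers to unknown gene_id")
    out_of_span <- e$start < g$start[idx] | e$end > g$end[idx]
    if (any(out_of_span))
      stop("exon outside gene span for gene_id: ",
           paste(unique(e$gene_id[out_of_span]), collapse = ", "))
    # disjoint + sorted within gene
    ord <- order(idx, e$start)
    es <- e$start[ord]; ee <- e$end[ord]; gi <- idx[ord]
    same <- gi[-1] == gi[-length(gi)]
    if (length(es) > 1 && any(same & es[-1] < ee[-length(ee)]))
      stop("exons overlap within a gene")
  }
  tr <- ann$transcripts
  if (nrow(tr)) {
    if (anyDuplicated(tr$transcript_id)) stop("transcript_id values must be unique")
    if (anyNA(match(tr$gene_id, g$gene_id)))
      stop("transcript refers to unknown gene_id")
    te <- ann$transcript_exons
    if (nrow(te)) {
      if (anyNA(match(te$transcript_id, tr$transcript_id)))
        stop("transcript_exons refers to unknown transcript_id")
      if (anyNA(match(te$exon_id, e$exon_id)))
        stop("transcript_exons refers to unknown exon_id")
    }
  }
  invisible(ann)
}

# GRanges helpers: internal 0-based half-open -> GRanges 1-based closed
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

#' Intergenic complement of an annotation
#'
#' Maximal intervals covering no base of any gene span, strand-ignored.
#' Together with the union of gene spans the result tiles each chromosome
#' exactly.  By default gene spans from both annotation sources are used
#' (see `sources`).
#'
#' @param ann a `gene_annotation` (or a genes data.frame).
#' @param layout a `genome_layout`.
#' @param sources which annotation sources define genic space:
#'   `"both"` (default), `"ucsc"`, or `"ensembl"`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted by chromosome (layout order) then start.
#' @export
intergenic_complement <- function(ann, layout, sources = "both") {
  genes <- if (inherits(ann, "gene_annotation")) ann$genes else as.data.frame(ann)
  if (!identical(sources, "both"))
    genes <- genes[genes$source %in% sources, , drop = FALSE]
  out <- lapply(seq_len(nrow(layout)), function(i) {
    chr <- layout$chrom[i]; len <- layout$length[i]
    gi <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(gi) == 0)
      return(data.frame(chrom = chr, start = 0, end = len))
    if (any(gi$start < 0 | gi$end > len))
      stop("gene outside chromosome bounds on ", chr)
    red <- IRanges::reduce(IRanges::IRanges(start = gi$start + 1, end = gi$end))
    gaps <- IRanges::gaps(red, start = 1, end = len)
    data.frame(chrom = chr,
               start = IRanges::start(gaps) - 1,
               end = IRanges::end(gaps))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$end > out$start, , drop = FALSE]
}

#' Gap distance between genomic intervals
#'
#' Vectorized distance between half-open intervals: 0 if they overlap or
#' abut, the gap length otherwise, and `Inf` when the intervals sit on
#' different chromosomes (a sentinel, not an error).
#'
#' @param chrom1,start1,end1 first interval(s), 0-based half-open.
#' @param chrom2,start2,end2 second interval(s).
#' @return numeric vector of distances in bp.
#' @export
interval_distance <- function(chrom1, start1, end1, chrom2, start2, end2) {
  d <- pmax(start1 - end2, start2 - end1, 0)
  d[as.character(chrom1) != as.character(chrom2)] <- Inf
  d
}

#' Read a gene annotation file
#'
#' Supported dialects: BED (native 0-based half-open; BED12 blocks are
#' exons, BED6 or fewer columns means a single-exon gene) and GFF3 (1-based
#' closed, converted on read).  GFF3 carries the full gene model:
#' `gene` features with `biotype` and `is_tf` attributes, `transcript`
#' features with `Parent`, `exon` features with `Parent` transcript(s).
#' BED carries one line per gene; biotype defaults to `coding`.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff"`.
#' @param source annotation source label to stamp on the genes
#'   (`"ucsc"` or `"ensembl"`).
#' @return a `gene_annotation`.
#' @export
read_annotation <- function(path, format = c("bed", "gff"),
                            source = c("ucsc", "ensembl")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "bed") read_annotation_bed(path, source)
  else read_annotation_gff(path, source)
}

read_annotation_bed <- function(path, source) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED in ", path, ": ",
                                          conditionMessage(e)))
  n <- length(gr)
  ids <- if (!is.null(gr$name)) as.character(gr$name) else sprintf("gene%05d", seq_len(n))
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", "*", as.character(GenomicRanges::strand(gr))),
    source = source, biotype = "coding", is_tf = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(gr$blocks)) {
    bl <- gr$blocks
    ex <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- bl[[i]]
      data.frame(gene_id = ids[i],
                 start = genes$start[i] + IRanges::start(b) - 1,
                 end = genes$start[i] + IRanges::end(b))
    }))
  } else {
    ex <- data.frame(gene_id = ids, start = genes$start, end = genes$end)
  }
  ex <- data.frame(exon_id = sprintf("%s.e%d", ex$gene_id,
                                     stats::ave(seq_len(nrow(ex)), ex$gene_id,
                                                FUN = seq_along)),
                   gene_id = ex$gene_id,
                   chrom = genes$chrom[match(ex$gene_id, genes$gene_id)],
                   start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  tr <- data.frame(transcript_id = paste0(ids, ".t1"), gene_id = ids,
                   stringsAsFactors = FALSE)
  te <- data.frame(transcript_id = paste0(ex$gene_id, ".t1"),
                   exon_id = ex$exon_id, stringsAsFactors = FALSE)
  gene_annotation(genes, ex, tr, te)
}

read_annotation_gff <- function(path, source) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 in ", path, ": ",
                                          conditionMessage(e)))
  typ <- as.character(gr$type)
  gg <- gr[typ == "gene"]
  genes <- data.frame(
    gene_id = as.character(gg$ID),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg) - 1,
    end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    source = source,
    biotype = if (!is.null(gg$biotype)) ifelse(is.na(gg$biotype), "coding",
                                               as.character(gg$biotype))
              else "coding",
    is_tf = if (!is.null(gg$is_tf)) as.character(gg$is_tf) %in% c("true", "TRUE", "1")
            else FALSE,
    stringsAsFactors = FALSE)
  tg <- gr[typ %in% c("transcript", "mRNA")]
  tr_parent <- vapply(tg$Parent, function(p) p[1], character(1))
  transcripts <- data.frame(transcript_id = as.character(tg$ID),
                            gene_id = tr_parent, stringsAsFactors = FALSE)
  eg <- gr[typ == "exon"]
  exon_ids <- as.character(eg$ID)
  exons <- data.frame(
    exon_id = exon_ids,
    gene_id = transcripts$gene_id[match(vapply(eg$Parent, `[`, character(1), 1),
                                        transcripts$transcript_id)],
    chrom = as.character(GenomicRanges::seqnames(eg)),
    start = GenomicRanges::start(eg) - 1,
    end = GenomicRanges::end(eg),
    stringsAsFactors = FALSE)
  te <- do.call(rbind, lapply(seq_along(eg), function(i) {
    data.frame(transcript_id = as.character(eg$Parent[[i]]),
               exon_id = exon_ids[i], stringsAsFactors = FALSE)
  }))
  # an exon shared by several transcripts appears once per (tx, exon) pair;
  # deduplicate the exon table itself
  keep <- !duplicated(exons$exon_id)
  exons <- exons[keep, , drop = FALSE]
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  rownames(exons) <- NULL
  gene_annotation(genes, exons, transcripts,
                  if (is.null(te)) data.frame(transcript_id = character(),
                                              exon_id = character())
                  else te)
}

#' Write a gene annotation file
#'
#' Inverse of [read_annotation()].  GFF3 preserves the full model (biotype,
#' TF flag, transcript structure); BED12 preserves spans and exon
#' coordinates only.
#'
#' @param ann a `gene_annotation`.
#' @param path output path.
#' @param format `"bed"` or `"gff"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("bed", "gff")) {
  format <- match.arg(format)
  g <- ann$genes
  if (format == "bed") {
    lines <- vapply(seq_len(nrow(g)), function(i) {
      ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0,
            if (g$strand[i] %in% c("+", "-")) g$strand[i] else ".",
            g$start[i], g$end[i], "0,0,0", nrow(ex),
            paste0(paste(ex$end - ex$start, collapse = ","), ","),
            paste0(paste(ex$start - g$start[i], collapse = ","), ","),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
  } else {
    tx <- ann$transcripts
    te <- ann$transcript_exons
    strand_chr <- ifelse(g$strand %in% c("+", "-"), g$strand, ".")
    gl <- sprintf("%s\ttiletx\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s;is_tf=%s",
                  g$chrom, g$start + 1, g$end, strand_chr, g$gene_id,
                  g$biotype, tolower(g$is_tf))
    gidx <- match(tx$gene_id, g$gene_id)
    tl <- sprintf("%s\ttiletx\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                  g$chrom[gidx], g$start[gidx] + 1, g$end[gidx],
                  strand_chr[gidx], tx$transcript_id, tx$gene_id)
    parents <- vapply(split(te$transcript_id, te$exon_id),
                      paste, character(1), collapse = ",")
    e <- ann$exons
    ep <- parents[e$exon_id]
    eidx <- match(e$gene_id, g$gene_id)
    el <- sprintf("%s\ttiletx\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                  e$chrom, e$start + 1, e$end, strand_chr[eidx],
                  e$exon_id, ep)
    writeLines(c("##gff-version 3", gl, tl, el), path)
  }
  invisible(path)
}
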