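# shared in-code fixtures and a cached default-parameter study run

# small annotation: one gene, configurable exon layout
toy_annotation <- function(gene_id = "gA", chrom = "chr1", exon_starts,
                           exon_ends, strand = "+", source = "ucsc",
                           biotype = "coding", is_tf = FALSE) {
  n <- length(exon_starts)
  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = min(exon_starts), end = max(exon_ends),
                      strand = strand, source = source, biotype = biotype,
                      is_tf = is_tf, stringsAsFactors = FALSE)
  exons <- data.frame(exon_id = sprintf("%s.e%d", gene_id, seq_len(n)),
                      gene_id = gene_id, chrom = chrom, start = exon_starts,
                      end = exon_ends, stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
                   stringsAsFactors = FALSE)
  te <- data.frame(transcript_id = paste0(gene_id, ".t1"),
                   exon_id = exons$exon_id, stringsAsFactors = FALSE)
  gene_annotation(genes, exons, tx, te)
}

combine_annotations <- function(...) {
  parts <- list(...)
  gene_annotation(do.call(rbind, lapply(parts, `[[`, "genes")),
                  do.call(rbind, lapply(parts, `[[`, "exons")),
                  do.call(rbind, lapply(parts, `[[`, "transcripts")),
                  do.call(rbind, lapply(parts, `[[`, "transcript_exons")))
}

# block-expression table built directly (for threshold/call unit tests)
toy_bx <- function(kind, chrom, start, end, levels, n_probes = 5,
                   owner = NA_character_, region_id = NA_character_,
                   conditions = c("E11.5", "E13.5", "E15.5")) {
  n <- length(start)
  out <- data.frame(block_id = sprintf("b%03d", seq_len(n)), kind = kind,
                    chrom = chrom, start = start, end = end, owner = owner,
                    region_id = region_id,
                    n_probes = rep_len(n_probes, n),
                    stringsAsFactors = FALSE)
  levels <- as.matrix(levels)
  for (c in seq_along(conditions))
    out[[paste0("level_", conditions[c])]] <-
      if (ncol(levels) == 1) levels[, 1] else levels[, c]
  attr(out, "conditions") <- conditions
  class(out) <- c("block_expression", "data.frame")
  out
}

toy_gene_calls <- function(gene_id, e1, e2 = e1, e3 = e1) {
  out <- data.frame(gene_id = gene_id, callable = TRUE,
                    expressed_E11.5 = e1, expressed_E13.5 = e2,
                    expressed_E15.5 = e3, stringsAsFactors = FALSE)
  attr(out, "conditions") <- c("E11.5", "E13.5", "E15.5")
  class(out) <- c("gene_calls", "data.frame")
  out
}

# brute-force gap distance: enumerate every base pair; the gap is the
# number of bases strictly between the closest occupied bases (oracle,
# small intervals only)
brute_distance <- function(s1, e1, s2, e2) {
  a <- s1:(e1 - 1); b <- s2:(e2 - 1)
  m <- min(abs(outer(a, b, "-")))
  if (m == 0) 0 else m - 1
}

# one full default-parameter study + pipeline, computed once per test run
.run_cache <- new.env(parent = emptyenv())
cached_default_run <- function() {
  if (is.null(.run_cache$res)) {
    sim <- simulate_study(sim_params(seed = 1))
    cfg <- pipeline_config(seed = 1, n_random_draws = 40)
    .run_cache$sim <- sim
    .run_cache$res <- run_pipeline(sim, cfg)
  }
  list(sim = .run_cache$sim, res = .run_cache$res)
}

# small, fast study for smoke-level tests (overridable defaults)
small_params <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L, chrom_length = 8e5,
                   n_genes = 40L, n_de_genes = 6L,
                   n_intergenic_signals = 8L, n_intronic_signals = 10L,
                   n_unspotted_gaps = 4L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
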