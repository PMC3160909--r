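#' Pipeline configuration
#'
#' Every tunable of the analysis, with the defaults used throughout:
#' 500-bp summarization windows, 99th-percentile expression thresholds
#' (per condition and chromosome), 80% / 50% expressed-exon fractions for
#' transcript / gene calls, 100-bp small-RNA minimum, 300-bp minimum
#' region length, 100-bp unspotted gap and flanking distances, 200-bp
#' ensembl overlap, 5 local permutations with 1st/99th-percentile
#' significance, and a 50-Kb neighborhood cap.
#'
#' @param window summarization window (bp).
#' @param threshold_percentile expression-threshold percentile.
#' @param threshold_scope `"per_chromosome"` or `"global"`.
#' @param transcript_fraction,gene_fraction expressed-exon fraction
#'   cutoffs.
#' @param small_rna_min_length bp.
#' @param min_region_length,max_unspotted_gap,flank_distance,ensembl_min_overlap
#'   segmentation parameters (bp).
#' @param permutation_sd coordinate-perturbation sd in bp (`NULL`: 1 Mb
#'   capped at a tenth of the chromosome length).
#' @param n_permutations permuted datasets for the null.
#' @param de_lower,de_upper null percentiles for differential calls.
#' @param neighborhood_cap bp.
#' @param intergenic_sources sources defining intergenic space (`"both"`,
#'   `"ucsc"`, or `"ensembl"`).
#' @param n_random_draws Monte-Carlo draws for the proximity baseline.
#' @param seed RNG seed for the permutation and Monte-Carlo stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 500,
                            threshold_percentile = 0.99,
                            threshold_scope = "per_chromosome",
                            transcript_fraction = 0.80,
                            gene_fraction = 0.50,
                            small_rna_min_length = 100,
                            min_region_length = 300,
                            max_unspotted_gap = 100,
                            flank_distance = 100,
                            ensembl_min_overlap = 200,
                            permutation_sd = NULL,
                            n_permutations = 5,
                            de_lower = 0.01,
                            de_upper = 0.99,
                            neighborhood_cap = 50000,
                            intergenic_sources = "both",
                            n_random_draws = 50,
                            seed = 1L) {
  p <- as.list(environment())
  class(p) <- "pipeline_config"
  p
}

#' Run the full analysis pipeline
#'
#' Normalization -> block summarization -> thresholds and expression
#' calls -> stage partition and summary -> differential expression
#' against the permutation null -> intronic/intergenic segmentation and
#' classification -> proximity and neighborhood statistics -> optional
#' conservation scoring.  Deterministic given `config$seed` and the
#' simulation seed.
#'
#' @param sim a simulated study from [simulate_study()] (or a compatible
#'   list with `layout`, `annotation`, `probes`, `design`, optionally
#'   `conservation`).
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, report TSV/BED files and
#'   a run manifest are written there.
#' @return list of class `pipeline_result` with elements `thresholds`,
#'   `block_calls`, `gene_calls`, `transcript_calls`, `partition`,
#'   `summary`, `de`, `regions` (per condition, classified),
#'   `category_counts`, `intronic_summary`, `proximity`, `expectation`,
#'   `gene_fractions`, `neighborhood`, `upregulated`, `conservation_means`.
#' @export
run_pipeline <- function(sim, config = pipeline_config(), outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)
  ann <- sim$annotation
  design <- sim$design
  conditions <- attr(design, "conditions")

  pm <- stage("normalize", {
    pm <- background_correct(sim$probes)
    pm <- quantile_normalize(pm)
    log2_transform(pm)
  })
  blocks <- stage("blocks",
    build_blocks(ann, sim$layout, pm, window = config$window,
                 intergenic_sources = config$intergenic_sources))
  bx <- stage("fit", fit_block_model(blocks, pm, design))
  thresholds <- stage("thresholds",
    compute_thresholds(bx, scope = config$threshold_scope,
                       percentile = config$threshold_percentile))
  bcalls <- stage("calls", call_blocks(bx, thresholds))
  exon_calls <- bcalls[bcalls$kind == "exon", , drop = FALSE]
  gcalls <- stage("gene calls",
    call_genes(ann, exon_calls, config$gene_fraction,
               config$small_rna_min_length))
  tcalls <- stage("transcript calls",
    call_transcripts(ann, exon_calls, config$transcript_fraction,
                     config$small_rna_min_length))
  ucsc_ids <- ann$genes$gene_id[ann$genes$source == "ucsc"]
  gcalls_ucsc <- gcalls[gcalls$gene_id %in% ucsc_ids, , drop = FALSE]
  attr(gcalls_ucsc, "conditions") <- conditions
  partition <- stage("partition", partition_stages(gcalls_ucsc))
  summary_tab <- stage("summary",
    summarize_calls(exon_calls, tcalls, gcalls, ann))
  de <- stage("differential",
    run_differential(pm, blocks, bx, ann, design,
                     n_permutations = config$n_permutations,
                     coordinate_sd = config$permutation_sd,
                     lower_percentile = config$de_lower,
                     upper_percentile = config$de_upper))
  seg_par <- segmentation_params(config$min_region_length,
                                 config$max_unspotted_gap,
                                 config$flank_distance,
                                 config$ensembl_min_overlap)
  regions <- list(); category_counts <- list(); intronic_summary <- list()
  for (cc in conditions) {
    ig <- stage("segmentation",
      detect_signal_regions(bcalls, pm, "intergenic", cc, seg_par))
    ig <- stage("classification", classify_intergenic(ig, ann, seg_par))
    io <- stage("segmentation",
      detect_signal_regions(bcalls, pm, "intronic", cc, seg_par))
    regions[[cc]] <- list(intergenic = ig, intronic = io)
    category_counts[[cc]] <- count_categories(ig)
    intronic_summary[[cc]] <- intronic_gene_summary(io, gcalls, cc)
  }
  ugenes <- ann$genes[ann$genes$source == "ucsc", , drop = FALSE]
  first <- conditions[1]; last <- conditions[length(conditions)]
  unexplained_first <- regions[[first]]$intergenic[
    regions[[first]]$intergenic$category == "unexplained", , drop = FALSE]
  intergenic_space <- intergenic_complement(ann, sim$layout,
                                            config$intergenic_sources)
  proximity <- stage("proximity",
    classify_proximity(regions[[first]]$intergenic, ugenes, gcalls, first))
  expectation <- stage("expectation",
    random_expectation(regions[[first]]$intergenic, ugenes, gcalls, first,
                       intergenic_space, n_draws = config$n_random_draws))
  gene_fracs <- stage("gene fractions", list(
    all = gene_fraction_with_signal(ugenes, gcalls,
                                    regions[[first]]$intergenic, first),
    tf = gene_fraction_with_signal(ugenes, gcalls,
                                   regions[[first]]$intergenic, first,
                                   subset = "tf")))
  nbh <- stage("neighborhood",
    neighborhood_coverage(ugenes, gcalls, first, unexplained_first,
                          sim$layout, config$neighborhood_cap))
  upreg <- stage("upregulated",
    select_upregulated_from_silent(gcalls_ucsc, ugenes,
                                   regions[[first]]$intergenic,
                                   regions[[last]]$intergenic))
  cons <- if (!is.null(sim$conservation) && nrow(unexplained_first))
    stage("conservation",
          mean_conservation(unexplained_first, sim$conservation))
    else numeric(0)

  res <- structure(list(thresholds = thresholds, block_calls = bcalls,
                        gene_calls = gcalls, transcript_calls = tcalls,
                        partition = partition, summary = summary_tab,
                        de = de, regions = regions,
                        category_counts = category_counts,
                        intronic_summary = intronic_summary,
                        proximity = proximity, expectation = expectation,
                        gene_fractions = gene_fracs, neighborhood = nbh,
                        upregulated = upreg, conservation_means = cons,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_reports(res, sim, outdir)
  res
}

write_pipeline_reports <- function(res, sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  wt <- function(x, f) utils::write.table(x, fp(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(res$thresholds, "thresholds.tsv")
  wt(res$gene_calls, "gene_calls.tsv")
  wt(data.frame(cell = names(res$partition$cells),
                count = unname(res$partition$cells)), "partition.tsv")
  wt(res$summary, "summary.tsv")
  wt(res$de$calls, "de_calls.tsv")
  cc_tab <- do.call(rbind, lapply(names(res$category_counts), function(cc)
    data.frame(condition = cc, t(res$category_counts[[cc]]))))
  wt(cc_tab, "category_counts.tsv")
  for (cc in names(res$regions)) {
    ig <- res$regions[[cc]]$intergenic
    if (nrow(ig))
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", ig$chrom,
                         as.integer(ig$start), as.integer(ig$end),
                         ig$category),
                 fp(sprintf("intergenic_regions_%s.bed", cc)))
  }
  wt(res$proximity, "proximity.tsv")
  wt(res$expectation, "proximity_expected.tsv")
  wt(res$neighborhood, "neighborhood.tsv")
  cfg <- res$config
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  writeLines(c(sprintf("config.%s=%s", names(cfg),
                       vapply(cfg, function(x) paste(x, collapse = ","),
                              character(1))),
               sprintf("sim.seed=%s", sim$params$seed)),
             fp("manifest.txt"))
  invisible(outdir)
}
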