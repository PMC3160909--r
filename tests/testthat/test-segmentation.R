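mk_block_calls <- function(kind, region_id, start, end, expressed,
                           owner = NA_character_, chrom = "chr1") {
  out <- data.frame(block_id = sprintf("w%03d", seq_along(start)),
                    kind = kind, chrom = chrom, start = start, end = end,
                    owner = owner, region_id = region_id,
                    n_probes = 10, stringsAsFactors = FALSE)
  out$expressed_E11.5 <- expressed
  out
}

dense_pm <- function(len = 10000, spacing = 35) {
  st <- seq(0, len - 25, by = spacing)
  probe_matrix(data.frame(chrom = "chr1", start = st, end = st + 25),
               matrix(1, length(st), 2), log2 = TRUE)
}

test_that("adjacent above-threshold windows merge into one region", {
  bc <- mk_block_calls("intergenic", "ig1", c(0, 500, 1000, 1500),
                       c(500, 1000, 1500, 2000),
                       c(TRUE, TRUE, FALSE, FALSE))
  r <- detect_signal_regions(bc, dense_pm(), "intergenic", "E11.5")
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0)
  expect_equal(r$end, 1000)
})

test_that("runs shorter than the minimum length are discarded", {
  bc <- mk_block_calls("intergenic", "ig1", c(0, 500), c(500, 750),
                       c(FALSE, TRUE))
  r <- detect_signal_regions(bc, dense_pm(), "intergenic", "E11.5")
  expect_equal(nrow(r), 0)  # 250 bp < 300 bp
  bc2 <- mk_block_calls("intergenic", "ig1", c(0, 500), c(500, 850),
                        c(FALSE, TRUE))
  expect_equal(nrow(detect_signal_regions(bc2, dense_pm(), "intergenic",
                                          "E11.5")), 1)
})

test_that("intronic runs split at probe-free stretches over 100 bp", {
  bc <- mk_block_calls("intron", "g1.i1", c(0, 500, 1000),
                       c(500, 1000, 1500), rep(TRUE, 3), owner = "g1")
  # probes everywhere except [600, 750): a 150-bp unspotted stretch
  st <- seq(0, 1475, by = 35)
  st <- st[st + 25 <= 600 | st >= 750]
  pm <- probe_matrix(data.frame(chrom = "chr1", start = st, end = st + 25),
                     matrix(1, length(st), 2), log2 = TRUE)
  r <- detect_signal_regions(bc, pm, "intronic", "E11.5")
  expect_equal(nrow(r), 2)
  expect_true(all(r$end - r$start >= 300))
  expect_lt(r$end[1], 750)
  expect_gte(r$start[2], 600)
  # intergenic detection ignores the gap rule
  bc_ig <- mk_block_calls("intergenic", "ig1", bc$start, bc$end,
                          rep(TRUE, 3))
  expect_equal(nrow(detect_signal_regions(bc_ig, pm, "intergenic",
                                          "E11.5")), 1)
})

mk_genes <- function(ids, chrom, start, end, source) {
  data.frame(gene_id = ids, chrom = chrom, start = start, end = end,
             strand = "+", source = source, biotype = "coding",
             is_tf = FALSE, stringsAsFactors = FALSE)
}

mk_regions <- function(start, end, chrom = "chr1") {
  n <- length(start)
  data.frame(signal_id = sprintf("s%d", seq_len(n)),
             chrom = rep_len(chrom, n), start = start, end = end,
             kind = rep_len("intergenic", n),
             condition = rep_len("E11.5", n),
             owner = rep_len(NA_character_, n),
             stringsAsFactors = FALSE)
}

test_that("classification precedence: flanking UCSC wins over ensembl overlap", {
  ann <- list(genes = rbind(
    mk_genes("u1", "chr1", 5000, 6000, "ucsc"),
    mk_genes("e1", "chr1", 6100, 7000, "ensembl")))
  # region 50 bp from the ucsc gene AND overlapping the ensembl gene
  r <- classify_intergenic(mk_regions(6050, 6500), ann)
  expect_equal(r$category, "flanking_ucsc")
  # far from everything
  r2 <- classify_intergenic(mk_regions(20000, 20500), ann)
  expect_equal(r2$category, "unexplained")
  # overlap >= 200 bp with ensembl only
  r3 <- classify_intergenic(mk_regions(6500, 6800), ann)
  expect_equal(r3$category, "ensembl_overlap")
  # within 100 bp of ensembl, overlap < 200
  r4 <- classify_intergenic(mk_regions(7050, 7400), ann)
  expect_equal(r4$category, "ensembl_flanking")
})

test_that("published per-stage category counts sum to the printed totals", {
  f <- system.file("extdata", "intergenic_category_counts.tsv",
                   package = "tiletx")
  tab <- read.delim(f, comment.char = "#")
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$flanking_ucsc[i] + tab$ensembl_overlap[i] +
                   tab$ensembl_flanking[i] + tab$unexplained[i],
                 tab$total[i])
  expect_equal(tab$total, c(7408, 7471, 7477))
})

test_that("categories always partition detected regions on synthetic data", {
  run <- cached_default_run()
  for (cc in c("E11.5", "E13.5", "E15.5")) {
    counts <- run$res$category_counts[[cc]]
    expect_equal(unname(sum(counts[1:4])), unname(counts["total"]))
    ig <- run$res$regions[[cc]]$intergenic
    expect_false(any(is.na(ig$category)))
  }
})

test_that("region counts are monotone in the length and flank parameters", {
  run <- cached_default_run()
  bc <- run$res$block_calls
  sim <- run$sim
  pm <- log2_transform(sim$probes)
  n_by_min <- vapply(c(300, 600, 1200), function(ml)
    nrow(detect_signal_regions(bc, pm, "intergenic", "E11.5",
                               segmentation_params(min_region_length = ml))),
    numeric(1))
  expect_true(all(diff(n_by_min) <= 0))
  ig <- run$res$regions[["E11.5"]]$intergenic
  unex <- vapply(c(0, 100, 1000), function(fd)
    sum(classify_intergenic(ig[setdiff(names(ig), "category")],
                            sim$annotation,
                            segmentation_params(flank_distance = fd))$category
        == "unexplained"),
    numeric(1))
  expect_true(all(diff(unex) <= 0))
})

test_that("intronic gene summary counts owners and their expressed subset", {
  empty <- mk_regions(numeric(0), numeric(0))
  empty$kind <- character(0); empty$owner <- character(0)
  gc <- toy_gene_calls(c("g1", "g2", "g3"), c(TRUE, TRUE, FALSE))
  expect_equal(unname(intronic_gene_summary(empty, gc, "E11.5")), c(0, 0))
  regs <- mk_regions(c(0, 100, 200, 300), c(400, 500, 600, 700))
  regs$kind <- "intronic"
  regs$owner <- c("g1", "g1", "g2", "g3")
  s <- intronic_gene_summary(regs, gc, "E11.5")
  expect_equal(unname(s), c(3, 2))
  # brute-force containment oracle on a random fixture
  set.seed(4)
  owners <- sample(sprintf("g%d", 1:20), 30, replace = TRUE)
  regs2 <- mk_regions(seq(0, by = 1000, length.out = 30),
                      seq(400, by = 1000, length.out = 30))
  regs2$owner <- owners
  gc2 <- toy_gene_calls(sprintf("g%d", 1:20), sample(c(TRUE, FALSE), 20,
                                                     replace = TRUE))
  s2 <- intronic_gene_summary(regs2, gc2, "E11.5")
  expect_equal(unname(s2[1]), length(unique(owners)))
  expect_equal(unname(s2[2]),
               sum(unique(owners) %in% gc2$gene_id[gc2$expressed_E11.5]))
})

test_that("planted intergenic signals are detected with high overlap", {
  run <- cached_default_run()
  sim <- run$sim
  ig <- run$res$regions[["E11.5"]]$intergenic
  truth <- sim$truth$intergenic_signals
  truth <- truth[!truth$on_ensembl, ]  # only signals inside searched space
  truth <- truth[truth$end - truth$start >= 600, ]
  jac <- vapply(seq_len(nrow(truth)), function(i) {
    same <- ig[ig$chrom == truth$chrom[i], ]
    if (!nrow(same)) return(0)
    ov <- pmax(0, pmin(same$end, truth$end[i]) -
                 pmax(same$start, truth$start[i]))
    un <- pmax(same$end, truth$end[i]) - pmin(same$start, truth$start[i])
    max(ov / un)
  }, numeric(1))
  detected <- jac > 0
  expect_gte(mean(detected), 0.9)
  expect_gte(mean(jac[detected]), 0.7)
})
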