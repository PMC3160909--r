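mk_sig <- function(start, end, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end, stringsAsFactors = FALSE)
}

mk_g <- function(ids, start, end, chrom = "chr1", is_tf = FALSE) {
  data.frame(gene_id = ids, chrom = chrom, start = start, end = end,
             strand = "+", source = "ucsc", biotype = "coding",
             is_tf = is_tf, stringsAsFactors = FALSE)
}

test_that("the distance grid has the prescribed spacing", {
  g <- distance_grid()
  expect_equal(g[1], 1000)
  expect_equal(g[length(g)], 1e6)
  expect_true(all(diff(g) > 0))
  expect_equal(sum(g <= 20000), 20)
  expect_equal(diff(g)[20:27], rep(10000, 8))
  expect_equal(diff(g)[28:36], rep(100000, 9))
})

test_that("signal proximity classes switch at the distance cutoff", {
  genes <- mk_g("gE", 10000, 12000)
  gc <- toy_gene_calls("gE", TRUE)
  sig <- mk_sig(4000, 5000)  # 5 kb from the gene
  pr <- classify_proximity(sig, genes, gc, "E11.5", grid = c(1000, 10000))
  expect_equal(pr$close_expressed, c(0, 1))
  expect_equal(pr$not_close, c(1, 0))
  none <- classify_proximity(sig, genes[0, ], gc, "E11.5")
  expect_true(all(none$not_close == 1))
})

test_that("proximity fractions sum to one, are monotone, and match brute force", {
  set.seed(15)
  genes <- mk_g(sprintf("g%02d", 1:12), seq(0, by = 80000, length.out = 12),
                seq(4000, by = 80000, length.out = 12))
  expr <- c(rep(TRUE, 5), rep(FALSE, 7))
  gc <- toy_gene_calls(genes$gene_id, expr)
  ss <- sort(sample(seq(5000, 870000, by = 37), 20))
  sig <- mk_sig(ss, ss + 600)
  grid <- distance_grid()
  pr <- classify_proximity(sig, genes, gc, "E11.5", grid)
  expect_equal(pr$close_expressed + pr$close_nonexpressed + pr$not_close,
               rep(1, length(grid)))
  expect_true(all(diff(pr$close_expressed) >= 0))
  expect_true(all(diff(pr$close_expressed + pr$close_nonexpressed) >= 0))
  # brute-force all-pairs oracle at a few cutoffs
  for (x in c(1000, 20000, 100000)) {
    cls <- vapply(seq_len(nrow(sig)), function(i) {
      d <- vapply(seq_len(nrow(genes)), function(j)
        interval_distance(sig$chrom[i], sig$start[i], sig$end[i],
                          genes$chrom[j], genes$start[j], genes$end[j]),
        numeric(1))
      if (any(d[expr] <= x)) "e" else if (any(d <= x)) "n" else "o"
    }, character(1))
    expect_equal(pr$close_expressed[grid == x], mean(cls == "e"))
    expect_equal(pr$close_nonexpressed[grid == x], mean(cls == "n"))
  }
})

test_that("gene-centric fractions respect subsetting and saturation", {
  genes <- mk_g(c("gA", "gB"), c(0, 50000), c(4000, 54000),
                is_tf = c(TRUE, FALSE))
  gc <- toy_gene_calls(genes$gene_id, c(TRUE, FALSE))
  no_sig <- gene_fraction_with_signal(genes, gc, mk_sig(numeric(0),
                                                        numeric(0)),
                                      "E11.5")
  expect_true(all(no_sig$frac_expressed == 0))
  sig <- mk_sig(20000, 21000)
  gf <- gene_fraction_with_signal(genes, gc, sig, "E11.5",
                                  grid = c(1000, 1e6))
  expect_equal(gf$frac_expressed, c(0, 1))   # saturates at chromosome scale
  expect_equal(gf$frac_nonexpressed, c(0, 1))
  tf <- gene_fraction_with_signal(genes, gc, sig, "E11.5",
                                  grid = c(20000), subset = "tf")
  expect_equal(attr(tf, "n_expressed"), 1)
  expect_equal(attr(tf, "n_nonexpressed"), 0)
  expect_equal(tf$frac_expressed, 1)  # gA is 15 kb away
})

test_that("neighborhoods extend half-way to the next gene, capped at 50 kb", {
  layout <- genome_layout("chr1", 1e6)
  g <- mk_g(c("gA", "gB"), c(100000, 164000), c(104000, 168000))
  nb <- gene_neighborhoods(g, layout)  # 60 kb apart -> 30 kb each side
  expect_equal(nb$down_end[nb$gene_id == "gA"], 104000 + 30000)
  expect_equal(nb$up_start[nb$gene_id == "gB"], 164000 - 30000)
  g2 <- mk_g(c("gA", "gB"), c(100000, 304000), c(104000, 308000))
  nb2 <- gene_neighborhoods(g2, layout)  # 200 kb apart -> capped at 50 kb
  expect_equal(nb2$down_end[nb2$gene_id == "gA"], 104000 + 50000)
  expect_equal(nb2$up_start[nb2$gene_id == "gB"], 304000 - 50000)
  # adjacent neighborhoods never overlap
  expect_lte(nb$down_end[nb$gene_id == "gA"],
             nb$up_start[nb$gene_id == "gB"])
})

test_that("neighborhood coverage matches a per-base oracle", {
  layout <- genome_layout("chr1", 300000)
  g <- mk_g(c("gA", "gB"), c(100000, 220000), c(110000, 230000))
  gc <- toy_gene_calls(g$gene_id, c(TRUE, FALSE))
  sig <- mk_sig(c(95000, 140000), c(98000, 141000))
  cov <- neighborhood_coverage(g, gc, "E11.5", sig, layout)
  # gA neighborhood: [50000,100000) up, [110000,160000) down (both capped)
  base <- rep(FALSE, 300000)
  base[(50000 + 1):100000] <- TRUE
  base[(110000 + 1):160000] <- TRUE
  sigbase <- rep(FALSE, 300000)
  sigbase[(95000 + 1):98000] <- TRUE
  sigbase[(140000 + 1):141000] <- TRUE
  expect_equal(cov$frac_with_signal[cov$class == "expressed"], 1)
  expect_equal(cov$mean_coverage[cov$class == "expressed"],
               sum(base & sigbase) / sum(base))
  expect_equal(cov$frac_with_signal[cov$class == "nonexpressed"], 0)
})

test_that("upregulated-from-silent selection filters on first-stage calls", {
  gc <- toy_gene_calls(c("gAll", "gGain", "gLate", "gOff"),
                       e1 = c(TRUE, FALSE, FALSE, FALSE),
                       e2 = c(TRUE, TRUE, FALSE, FALSE),
                       e3 = c(TRUE, TRUE, TRUE, FALSE))
  genes <- mk_g(gc$gene_id, c(0, 1e4, 2e4, 3e4) + 1,
                c(0, 1e4, 2e4, 3e4) + 4000)
  sel <- select_upregulated_from_silent(gc, genes, mk_sig(5000, 5600),
                                        mk_sig(25000, 25600))
  expect_setequal(sel$gene_ids, c("gGain", "gLate"))
  expect_equal(nrow(sel$profile_first), length(distance_grid()))
})

test_that("random placement baseline is reproducible and self-consistent", {
  set.seed(20)
  layout <- genome_layout("chr1", 1e6)
  genes <- mk_g(sprintf("g%02d", 1:10),
                seq(50000, by = 90000, length.out = 10),
                seq(54000, by = 90000, length.out = 10))
  gc <- toy_gene_calls(genes$gene_id, rep(c(TRUE, FALSE), 5))
  ig <- intergenic_complement(genes, layout)
  ss <- seq(10000, 900000, length.out = 15)
  sig <- mk_sig(ss, ss + 800)
  e1 <- random_expectation(sig, genes, gc, "E11.5", ig, n_draws = 30,
                           seed = 42)
  e2 <- random_expectation(sig, genes, gc, "E11.5", ig, n_draws = 30,
                           seed = 42)
  expect_identical(e1, e2)
  expect_true(all(e1$lo_close_expressed <= e1$hi_close_expressed))
  expect_true(all(e1$expected_close_expressed >= e1$lo_close_expressed -
                    1e-12))
})
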