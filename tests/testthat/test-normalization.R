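make_pm <- function(intensity, spacing = 35, log2 = FALSE) {
  n <- nrow(intensity)
  probe_matrix(data.frame(chrom = "chr1", start = (0:(n - 1)) * spacing,
                          end = (0:(n - 1)) * spacing + 25),
               intensity, log2 = log2)
}

test_that("background correction subtracts the 2nd percentile and floors", {
  set.seed(3)
  x <- matrix(stats::rlnorm(600, 3, 1), 100, 6)
  pm <- make_pm(x)
  expect_identical(background_correct(pm, "none")$intensity, pm$intensity)
  corr <- background_correct(pm, "percentile_shift", floor = 0.25)
  oracle <- pmax(sweep(x, 2, apply(x, 2, quantile, 0.02), "-"), 0.25)
  expect_equal(corr$intensity, oracle)
  # constant sample degenerates to the floor everywhere
  const <- make_pm(matrix(5, 50, 6))
  expect_true(all(background_correct(const)$intensity == 0.25))
  expect_error(background_correct(pm, floor = 0), "positive")
})

test_that("quantile normalization maps samples onto the mean distribution", {
  pm <- make_pm(cbind(c(2, 4, 6), c(3, 6, 9)))
  qn <- quantile_normalize(pm)
  expect_equal(unname(qn$intensity),
               cbind(c(2.5, 5, 7.5), c(2.5, 5, 7.5)))
  same <- make_pm(cbind(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(unname(quantile_normalize(same)$intensity),
               unname(same$intensity))
  set.seed(4)
  rnd <- make_pm(matrix(stats::rlnorm(1200), 200, 6))
  qn2 <- quantile_normalize(rnd)$intensity
  sorted <- apply(qn2, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  expect_error(quantile_normalize(make_pm(matrix(1:5, 5, 1))), ">= 2")
})

test_that("window blocks tile introns from the region 5' end, truncating the last", {
  ann <- toy_annotation(exon_starts = c(1000, 2300), exon_ends = c(1100, 2400))
  # intron spans [1100, 2300): 1200 bp
  layout <- genome_layout("chr1", 10000)
  st <- seq(0, 9970, by = 35)
  pm <- probe_matrix(data.frame(chrom = "chr1", start = st, end = st + 25),
                     matrix(1, length(st), 6))
  blocks <- build_blocks(ann, layout, pm)
  intron <- blocks[blocks$kind == "intron", ]
  expect_equal(intron$start, c(1100, 1600, 2100))
  expect_equal(intron$end, c(1600, 2100, 2300))
  expect_error(build_blocks(ann, layout, pm, window = 10), "probe length")
})

test_that("all probes overlapping an exon form a single exon block", {
  ann <- toy_annotation(exon_starts = 1000, exon_ends = 1500)
  layout <- genome_layout("chr1", 5000)
  st <- seq(0, 4970, by = 35)
  pm <- probe_matrix(data.frame(chrom = "chr1", start = st, end = st + 25),
                     matrix(1, length(st), 6))
  blocks <- build_blocks(ann, layout, pm)
  exon <- blocks[blocks$kind == "exon", ]
  expect_equal(nrow(exon), 1)
  manual <- sum(st + 25 > 1000 & st < 1500)
  expect_equal(exon$n_probes, manual)
  expect_equal(manual, 15)
})

test_that("probe memberships match a brute-force overlap oracle", {
  sim <- simulate_study(small_params(seed = 13, n_genes = 50L))
  pm <- log2_transform(sim$probes)
  blocks <- build_blocks(sim$annotation, sim$layout, pm)
  pr <- pm$probes
  ex <- sim$annotation$exons
  # oracle: exon-overlapping probes assigned to every overlapping exon;
  # remaining probes to every window they overlap
  exonic <- rep(FALSE, nrow(pr))
  n_exon_members <- 0
  for (i in seq_len(nrow(ex))) {
    ov <- pr$chrom == ex$chrom[i] & pr$end > ex$start[i] &
      pr$start < ex$end[i]
    exonic <- exonic | ov
    n_exon_members <- n_exon_members + sum(ov)
  }
  expect_equal(sum(blocks$n_probes[blocks$kind == "exon"]), n_exon_members)
  win <- blocks[blocks$kind != "exon", ]
  free <- pr[!exonic, ]
  n_win_members <- 0
  for (i in seq_len(nrow(win)))
    n_win_members <- n_win_members +
      sum(free$chrom == win$chrom[i] & free$end > win$start[i] &
            free$start < win$end[i])
  expect_equal(sum(win$n_probes), n_win_members)
})

test_that("median polish recovers a noiseless additive model exactly", {
  mu <- c(4, 4.2, 6, 6.1, 8, 8.3)          # sample levels
  a <- c(-0.4, -0.1, 0, 0.2, 0.9)          # probe affinities, median 0
  x <- outer(a, mu, "+")
  design <- sample_design()
  blocks <- data.frame(block_id = "b1", kind = "exon", chrom = "chr1",
                       start = 0, end = 100, owner = "g",
                       region_id = NA, n_probes = 5)
  blocks$probe_idx <- list(1:5)
  pm <- list(probes = data.frame(chrom = "chr1", start = (0:4) * 35,
                                 end = (0:4) * 35 + 25),
             intensity = x, log2 = TRUE)
  class(pm) <- "probe_matrix"
  bx <- fit_block_model(blocks, pm, design, store_affinity = TRUE)
  expect_equal(bx$level_E11.5, mean(mu[1:2]))
  expect_equal(bx$level_E13.5, mean(mu[3:4]))
  expect_equal(bx$level_E15.5, mean(mu[5:6]))
  expect_equal(sort(bx$affinity[[1]]), sort(a))
})

test_that("a single-probe block takes the probe's per-condition means", {
  design <- sample_design()
  blocks <- data.frame(block_id = "b1", kind = "exon", chrom = "chr1",
                       start = 0, end = 100, owner = "g",
                       region_id = NA, n_probes = 1)
  blocks$probe_idx <- list(2L)
  x <- matrix(rnorm(18), 3, 6)
  pm <- list(probes = data.frame(chrom = "chr1", start = (0:2) * 35,
                                 end = (0:2) * 35 + 25),
             intensity = x, log2 = TRUE)
  class(pm) <- "probe_matrix"
  bx <- fit_block_model(blocks, pm, design, store_affinity = TRUE)
  expect_equal(bx$level_E11.5, mean(x[2, 1:2]))
  expect_equal(bx$level_E15.5, mean(x[2, 5:6]))
  expect_equal(bx$affinity[[1]], 0)
})

test_that("median polish agrees with the stats::medpolish oracle", {
  set.seed(7)
  x <- matrix(rnorm(18), 3, 6)
  x[2, 4] <- x[2, 4] + 5  # one outlier cell
  mine <- median_polish(x, tol = 0, max_iter = 10)
  oracle <- suppressWarnings(
    stats::medpolish(x, eps = 0, maxiter = 10, trace.iter = FALSE))
  expect_equal(mine$overall + mine$col,
               unname(oracle$overall + oracle$col), tolerance = 1e-12)
  expect_equal(mine$row, unname(oracle$row), tolerance = 1e-12)
  # batched path gives the same answer
  batched <- tiletx:::batch_median_polish(x, 3, tol = 0, max_iter = 10)
  expect_equal(batched$mu[1, ], unname(oracle$overall + oracle$col),
               tolerance = 1e-12)
})

test_that("fit is probe-order invariant; a per-sample constant moves only that sample", {
  set.seed(8)
  x <- matrix(rnorm(42, 7), 7, 6)
  design <- sample_design()
  mk <- function(xx, idx) {
    blocks <- data.frame(block_id = "b1", kind = "exon", chrom = "chr1",
                         start = 0, end = 300, owner = "g",
                         region_id = NA, n_probes = 7)
    blocks$probe_idx <- list(idx)
    pm <- list(probes = data.frame(chrom = "chr1", start = (0:6) * 35,
                                   end = (0:6) * 35 + 25),
               intensity = xx, log2 = TRUE)
    class(pm) <- "probe_matrix"
    fit_block_model(blocks, pm, design, store_affinity = TRUE)
  }
  b1 <- mk(x, 1:7)
  b2 <- mk(x[7:1, ], 1:7)  # same block, probes presented reversed
  expect_equal(b1$level_E13.5, b2$level_E13.5, tolerance = 1e-10)
  # shifting one replicate by a constant moves (essentially) only that
  # sample's level; with row-first sweeps the absorption is approximate,
  # bounded by the robustness of the row medians
  x2 <- x; x2[, 3] <- x2[, 3] + 2  # shift one E13.5 replicate
  b3 <- mk(x2, 1:7)
  expect_equal(b3$level_E13.5, b1$level_E13.5 + 1, tolerance = 0.02)
  expect_equal(b3$level_E11.5, b1$level_E11.5, tolerance = 0.02)
  expect_equal(sort(b3$affinity[[1]]), sort(b1$affinity[[1]]),
               tolerance = 0.2)
})

test_that("exon-block levels recover the planted shift over intergenic background", {
  # quantile normalization + log2 + median polish only: the percentile
  # background shift rescales the low end of the log scale by design, so
  # the recovery property is about the summarization path
  run <- cached_default_run()
  sim <- run$sim
  pm <- log2_transform(quantile_normalize(sim$probes))
  blocks <- build_blocks(sim$annotation, sim$layout, pm)
  tg <- sim$truth$genes
  stable <- tg$gene_id[tg$expressed_E11.5 & tg$de_E13.5_vs_E11.5 == 0 &
                         tg$de_E15.5_vs_E13.5 == 0]
  keep_ex <- blocks$kind == "exon" & blocks$owner %in% stable &
    blocks$n_probes >= 1
  igb_idx <- which(blocks$kind == "intergenic" & blocks$n_probes >= 1)
  # background windows: away from planted signals; a subsample suffices
  sig <- sim$truth$signals
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(blocks$chrom[igb_idx],
                           IRanges::IRanges(blocks$start[igb_idx] + 1,
                                            blocks$end[igb_idx])),
    GenomicRanges::GRanges(sig$chrom, IRanges::IRanges(sig$start + 1,
                                                       sig$end)))
  bg_idx <- setdiff(igb_idx, igb_idx[unique(S4Vectors::queryHits(hit))])
  set.seed(1)
  bg_idx <- sample(bg_idx, 2000)
  bx <- fit_block_model(blocks[c(which(keep_ex), bg_idx), ], pm,
                        sim$design)
  diff_obs <- mean(bx$level_E11.5[bx$kind == "exon"]) -
    mean(bx$level_E11.5[bx$kind == "intergenic"])
  expect_lt(abs(diff_obs - sim$params$expressed_shift), 0.2)
})
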