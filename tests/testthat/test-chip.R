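test_that("window tiling keeps or drops the terminal partial tile by half-width", {
  t1 <- tile_windows(tibble::tibble(chrom = "c", length = 100000))
  expect_equal(nrow(t1), 10)
  expect_equal(t1$end[10], 100000)

  t2 <- tile_windows(tibble::tibble(chrom = "c", length = 104999))
  expect_equal(nrow(t2), 10)

  t3 <- tile_windows(tibble::tibble(chrom = "c", length = 105001))
  expect_equal(nrow(t3), 11)
  expect_equal(c(t3$start[11], t3$end[11]), c(100000, 105001))
})

test_that("RPKM quantification follows the formula and its symmetries", {
  q <- fix_quant(counts = c(100, 0))
  expect_equal(q$rpkm[1], 10)  # 100 / (10 kb * 1e6/1e6)
  expect_equal(q$rpkm[2], 0)
  expect_equal(q$log2_rpkm[2], log2(2^-4))

  # doubling count and library leaves RPKM unchanged
  q2 <- fix_quant(counts = c(200, 0), lib = 2e6)
  expect_equal(q2$rpkm[1], q$rpkm[1])

  expect_error(fix_quant(counts = c(-1, 5)), "negative")
})

test_that("artifact masking is strict and uses per-set means", {
  q <- fix_quant(counts = c(60, 61, 10))  # RPKM 6.00, 6.10, 1.0
  q$replicate_set <- "set1"
  mask <- mask_artifacts(q)
  expect_identical(mask$artifact, c(FALSE, TRUE, FALSE))  # strict >

  # RPKM window1: i1 = 10, i2 = 2; pooled-set mean 6 is not strictly > 6,
  # but i1's own set mean 10 is
  q2 <- dplyr::bind_rows(
    fix_quant(counts = c(100, 10), sample = "i1"),
    fix_quant(counts = c(20, 10), sample = "i2"))
  mask2 <- mask_artifacts(q2, sample_sets = c(i1 = "s1", i2 = "s2"))
  expect_identical(mask2$artifact, c(TRUE, FALSE))
  mask3 <- mask_artifacts(q2, sample_sets = c(i1 = "s", i2 = "s"))
  expect_identical(mask3$artifact, c(FALSE, FALSE))

  expect_error(mask_artifacts(q[0, ]), "input")
})

test_that("planted artifact windows are recovered on a full-scale-like genome", {
  # a large sparse genome so uniform input background RPKM is <= 2
  g <- make_genome(chrom_sizes = c(chr1 = 2e8, chr2 = 2e8, chr3 = 2e8),
                   cpg_rate = 1e-6, n_cgis = 5, n_genes = 20, n_ervs = 0,
                   seed = 31)
  td <- sample_truth_domains(g, n_domains = 10, width = 50000, seed = 32)
  sim <- simulate_chip(g, td, n_artifact_windows = 50, artifact_fold = 10,
                       seed = 33)
  q <- quantify_rpkm(sim$counts)
  bg_rpkm <- stats::median(q$rpkm[q$role == "input"])
  expect_lte(bg_rpkm, 2)
  mask <- mask_artifacts(q[q$role == "input", ], rpkm_threshold = 6)
  masked <- mask[mask$artifact, c("chrom", "start", "end")]
  truth <- sim$truth$artifact_windows
  hit <- dplyr::inner_join(masked, truth, by = c("chrom", "start", "end"))
  expect_gte(nrow(hit), 48)              # sensitivity >= 48/50
  expect_lte(nrow(masked) - nrow(hit), 2)  # at most 2 false positives
})

test_that("enrichment calls are strict in log2 RPKM and respect the mask", {
  pc <- 2^-4
  thr_rpkm <- 2^2.5 - pc  # RPKM at which log2(rpkm + pc) == 2.5 exactly
  q <- tibble::tibble(chrom = "chr1",
                      start = c(0, 10000, 20000),
                      end = c(10000, 20000, 30000),
                      sample = "s1",
                      count = 0,
                      rpkm = c(thr_rpkm, thr_rpkm * 0.999, thr_rpkm * 1.001))
  q$log2_rpkm <- log2(q$rpkm + pc)
  called <- call_enriched_windows(q)
  expect_identical(called$called, c(FALSE, FALSE, TRUE))  # boundary strict

  mask <- tibble::tibble(chrom = "chr1", start = 20000, end = 30000,
                         artifact = TRUE)
  called2 <- call_enriched_windows(q, mask = mask)
  expect_false(any(called2$called))

  q0 <- fix_quant(counts = rep(0, 5))
  expect_false(any(call_enriched_windows(q0)$called))
})

test_that("window merging obeys the gap rule and is idempotent", {
  w <- tibble::tibble(chrom = "chr1", start = c(0, 20000),
                      end = c(10000, 30000))
  m <- merge_windows(w, max_gap = 10000)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 30000))

  w2 <- tibble::tibble(chrom = "chr1", start = c(0, 20001),
                       end = c(10000, 30001))
  expect_equal(nrow(merge_windows(w2, max_gap = 10000)), 2)

  m2 <- merge_windows(m[, c("chrom", "start", "end")], max_gap = 10000)
  expect_equal(m2[, c("chrom", "start", "end")],
               m[, c("chrom", "start", "end")])

  expect_error(merge_windows(tibble::tibble(
    chrom = "chr1", start = c(20000, 0), end = c(30000, 10000))), "sorted")
})

test_that("merging equals the brute-force interval-union oracle", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    starts <- sort(sample(0:40, n)) * 10L
    widths <- sample(1:4, n, replace = TRUE) * 10L
    iv <- tibble::tibble(chrom = "c", start = starts, end = starts + widths)
    iv <- iv[!duplicated(iv$start), ]
    gap <- sample(c(0L, 10L, 20L), 1)
    got <- merge_windows(iv, max_gap = gap)
    want <- merge_oracle(iv, gap = gap)
    expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("domain calls are invariant to window input order", {
  g <- fix_genome()
  td <- sample_truth_domains(g, n_domains = 20, width = 40000, seed = 41)
  sim <- simulate_chip(g, td, seed = 42)
  q <- quantify_rpkm(sim$counts)
  thr <- stats::median(q$log2_rpkm[q$sample == "chip_rep1"]) + log2(6) / 2
  called <- call_enriched_windows(q, thr, sample = "chip_rep1")
  shuf <- q[sample(nrow(q)), ]
  called2 <- call_enriched_windows(shuf, thr, sample = "chip_rep1")
  expect_equal(called, called2)
})

test_that("random-domain counts match the Bernoulli run expectation", {
  wins <- tile_windows(tibble::tibble(chrom = "c", length = 2.7e8))
  expect_equal(nrow(wins), 27000)
  n <- 3467
  rd <- sample_random_domains(wins, n = n, max_gap = 10000, seed = 55)
  # windows i, j merge iff at most one unselected window sits between, so
  # a domain starts at a selected window preceded by two unselected ones
  p <- n / nrow(wins)
  expected <- nrow(wins) * p * (1 - p)^2
  expect_lt(abs(nrow(rd) - expected) / expected, 0.05)
  expect_equal(sum(rd$n_windows), n)

  rd1 <- sample_random_domains(wins, n = 1, seed = 1)
  expect_equal(nrow(rd1), 1)
  expect_equal(rd1$end - rd1$start, 10000)

  all_d <- sample_random_domains(wins, n = nrow(wins), seed = 2)
  expect_equal(nrow(all_d), 1)  # one chromosome, all adjacent

  expect_error(sample_random_domains(wins, n = nrow(wins) + 1, seed = 3))
})

test_that("composite profiles are flat under uniform signal and peaked on domains", {
  q <- fix_quant(counts = rep(100, 50), width = 10000)
  regions <- tibble::tibble(chrom = "chr1", start = c(100000, 300000),
                            end = c(160000, 340000))
  prof <- composite_profile(regions, q)
  expect_lt(max(prof$signal) - min(prof$signal), 1e-9)
  expect_equal(nrow(prof), 30)  # 5 + 20 + 5 bins, one sample

  g <- fix_genome()
  td <- sample_truth_domains(g, n_domains = 20, width = 50000, seed = 61)
  sim <- simulate_chip(g, td, enrichment_fold = 6, seed = 62)
  qq <- quantify_rpkm(sim$counts)
  qq <- qq[qq$sample == "chip_rep1", ]
  prof2 <- composite_profile(td, qq)
  interior <- mean(prof2$signal[prof2$zone == "interior"])
  flank <- mean(prof2$signal[prof2$zone != "interior"])
  expect_gt(interior - flank, log2(3))

  expect_error(composite_profile(regions[0, ], q), "non-empty")
})

test_that("promoter classification is strand-aware with upward boundaries", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                          chrom = "chr1",
                          start = c(1000, 5000, 9000, 20000),
                          end = c(3000, 8000, 10000, 30000),
                          strand = c("+", "+", "-", "+"))
  fpkm <- c(g1 = 0, g2 = 0.1, g3 = 1, g4 = 0.5)
  cgis <- tibble::tibble(chrom = "chr1", start = 900, end = 1100)
  pr <- classify_promoters(genes, fpkm, cgis)
  expect_equal(pr$expression_class,
               c("not_expressed", "low", "high", "low"))
  # minus-strand gene ending at 10,000: promoter [9500, 10500)
  expect_equal(c(pr$start[3], pr$end[3]), c(9500, 10500))
  expect_identical(pr$cgi_promoter, c(TRUE, FALSE, FALSE, FALSE))

  genes$strand[1] <- NA
  expect_error(classify_promoters(genes, fpkm), "strand")
})
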