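make_counts <- function(m, ids = sprintf("g%03d", seq_len(nrow(m)))) {
  dplyr::bind_cols(tibble::tibble(gene_id = ids), tibble::as_tibble(m))
}

test_that("log-CPM follows the formula and is depth-invariant", {
  counts <- make_counts(cbind(s1 = c(1000, 0, 999000)))
  lc <- log_cpm(counts)
  expect_equal(lc$s1[1], log2(1000 + 1))
  expect_equal(lc$s1[2], log2(0 + 1))

  # scaling a library by 10 leaves CPM unchanged for proportional counts
  counts10 <- make_counts(cbind(s1 = 10 * c(1000, 0, 999000)))
  expect_equal(log_cpm(counts10)$s1, lc$s1)
})

test_that("median-of-ratios size factors behave and recover truth", {
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(size_factors(make_counts(m))), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30), b = 2 * c(10, 20, 30))
  sf <- size_factors(make_counts(m2))
  expect_equal(unname(sf[2] / sf[1]), 2)

  set.seed(5)
  true_sf <- c(0.6, 1, 1.4, 1.2)
  mu <- rlnorm(2000, log(100), 1)
  sim <- sapply(true_sf, function(s) rnbinom(2000, mu = s * mu, size = 20))
  colnames(sim) <- paste0("s", 1:4)
  sf_hat <- size_factors(make_counts(sim))
  rel <- sf_hat / (true_sf / exp(mean(log(true_sf))))
  expect_lt(max(abs(rel - 1)), 0.05)

  expect_error(size_factors(make_counts(cbind(a = c(0, 1), b = c(1, 0)))),
               "nonzero")
})

test_that("the NB Wald test is antisymmetric and recovers planted effects", {
  ids <- sprintf("g%04d", 1:2000)
  g <- structure(list(genes = tibble::tibble(gene_id = ids)),
                 class = "oomics_genome")
  base <- stats::setNames(rep(100, length(ids)), ids)
  truth <- tibble::tibble(gene_id = ids[1:100], log2fc = 2)
  sim <- simulate_rnaseq(g, baseline_means = base, de_truth = truth,
                         dispersion = 0.05, seed = 81)
  res <- nb_wald_test(sim$counts, sim$groups, reference = "control")

  # swapped labels negate the fold change and keep p
  swapped <- ifelse(sim$groups == "control", "cko", "control")
  names(swapped) <- names(sim$groups)
  res_sw <- nb_wald_test(sim$counts, swapped, reference = "control")
  expect_equal(res_sw$log2fc, -res$log2fc)
  expect_equal(res_sw$p, res$p)

  # planted log2FC 2 recovered with small mean bias
  expect_lt(abs(mean(res$log2fc[res$gene_id %in% truth$gene_id]) - 2), 0.15)

  # gene order invariance
  shuf <- sim$counts[sample(nrow(sim$counts)), ]
  res_shuf <- nb_wald_test(shuf, sim$groups, reference = "control")
  res_shuf <- res_shuf[match(res$gene_id, res_shuf$gene_id), ]
  expect_equal(res_shuf$p, res$p)

  # all-zero genes are excluded with a report
  counts0 <- sim$counts
  counts0[1, -1] <- 0
  expect_message(res0 <- nb_wald_test(counts0, sim$groups), "all-zero")
  expect_false(counts0$gene_id[1] %in% res0$gene_id)
})

test_that("DEG calls gate on both significance and fold change", {
  res <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        base_mean = 100,
                        log2fc = c(1.49, 3, 1.5, -1.5),
                        se = 1, stat = 1,
                        p = c(1e-12, 0.1, 1e-12, 1e-12),
                        padj = c(1e-10, 0.2, 1e-10, 1e-10),
                        dispersion = 0.05)
  class(res) <- c("oomics_de", class(res))
  called <- call_degs(res)
  expect_identical(called$call, c("none", "none", "up", "down"))
  # strict mode excludes the boundary
  expect_identical(call_degs(res, strict = TRUE)$call,
                   c("none", "none", "none", "none"))
  # up and down calls never intersect
  expect_equal(sum(called$call == "up" & called$call == "down"), 0)
})

test_that("down-sampling conserves totals exactly and halves expectations", {
  set.seed(6)
  m <- cbind(s1 = rmultinom(1, 3.8e6, prob = rgamma(800, 1))[, 1])
  counts <- make_counts(m, ids = sprintf("g%03d", 1:800))
  ds <- downsample_counts(counts, target = 1.9e6, seed = 3)
  expect_equal(sum(ds$s1), 1.9e6)
  ratio <- sum(ds$s1[1:400]) / sum(counts$s1[1:400])
  expect_lt(abs(ratio - 0.5), 0.01)

  # deterministic
  ds2 <- downsample_counts(counts, target = 1.9e6, seed = 3)
  expect_identical(ds, ds2)

  # at-target column passes through; short column warns
  at <- make_counts(cbind(s1 = c(1e6, 9e5)), ids = c("a", "b"))
  expect_identical(downsample_counts(at, target = 1.9e6, seed = 1), at)
  short <- make_counts(cbind(s1 = c(10, 20)), ids = c("a", "b"))
  expect_warning(downsample_counts(short, target = 1.9e6, seed = 1), "below")
})

test_that("ERV quantification applies the strict 2-kb exclusion", {
  genes <- tibble::tibble(chrom = "c", start = 10000, end = 20000)
  ervs <- tibble::tibble(chrom = "c",
                         start = c(20000, 22000, 21999, 50000),
                         end = c(21000, 23000, 22999, 51000),
                         erv_id = c("touch", "at2k", "inside2k", "far"),
                         family = c("ERVK", "ERVK", "ERVL", "ERVL"))
  counts <- make_counts(cbind(s1 = c(10, 10, 10, 10), s2 = c(20, 20, 20, 20)),
                        ids = ervs$erv_id)
  names(counts)[1] <- "erv_id"
  out <- quantify_ervs(counts, ervs, genes,
                       library_sizes = c(s1 = 1000, s2 = 1000))
  expect_setequal(out$retained, c("at2k", "far"))  # touching & <2k excluded
  expect_equal(out$percent$erv_percent, c(2, 4))

  # doubling one group's ERV counts doubles its percentage
  counts2 <- counts
  counts2$s2 <- counts2$s2  # s2 already 2x s1
  expect_equal(out$percent$erv_percent[2] / out$percent$erv_percent[1], 2)
  expect_true("by_family" %in% names(out))
})

test_that("DEG clustering recovers three planted expression patterns", {
  set.seed(31)
  block <- function(n, mu1, mu2) cbind(rnorm(n, mu1, 0.3), rnorm(n, mu2, 0.3))
  m <- rbind(block(40, -3, -3), block(40, 3, 3), block(40, 0, 3))
  planted <- rep(c("down_down", "up_up", "flat_up"), each = 40)
  x <- dplyr::bind_cols(tibble::tibble(id = sprintf("g%03d", 1:120)),
                        tibble::as_tibble(m, .name_repair = ~c("cko", "cdko")))
  cl <- cluster_degs(x, k = 3)
  expect_gte(mean(cl$pattern == planted), 0.95)

  # duplicated rows co-cluster
  x2 <- dplyr::bind_rows(x, x[1, ])
  cl2 <- cluster_degs(x2, k = 3)
  expect_equal(cl2$cluster[121], cl2$cluster[1])

  expect_error(cluster_degs(x[1:2, ], k = 3), "at least")
})
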