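test_that("CpG tiling groups exactly n CpGs and drops the remainder", {
  cpg <- tibble::tibble(chrom = "chr1", pos = sort(sample.int(1e6, 250)))
  tiles <- tile_by_cpg(cpg, n = 100)
  expect_equal(nrow(tiles), 2)
  expect_equal(tiles$start[1], cpg$pos[1])
  expect_equal(tiles$end[1], cpg$pos[100] + 1)
  expect_equal(tiles$end[2], cpg$pos[200] + 1)
  # tiles never overlap and jointly contain at most all CpGs
  expect_true(all(tiles$start[-1] >= tiles$end[-nrow(tiles)]))
  assigned <- assign <- sum(!is.na(oomics:::assign_cpg_tiles(cpg, tiles)))
  expect_equal(assigned, 200)

  one <- tile_by_cpg(tibble::tibble(chrom = "c", pos = 1:100), n = 100)
  expect_equal(nrow(one), 1)

  expect_error(tile_by_cpg(tibble::tibble(chrom = "c", pos = c(5, 1)), 2),
               "sorted")
})

test_that("coverage filter requires min_obs in every sample", {
  ts <- tidyr::crossing(tile_id = c("t1", "t2", "t3"),
                        sample = c("a", "b")) |>
    dplyr::mutate(chrom = "c", start = 0, end = 1,
                  meth = 5, unmeth = 5, pct = 50, n_cpg_covered = 2,
                  n_obs = c(10, 10, 9, 50, 10, 10))
  kept <- suppressMessages(coverage_filter(ts, min_obs = 10))
  expect_setequal(unique(kept$tile_id), c("t1", "t3"))
})

test_that("tile percentage modes differ exactly as coverage weighting implies", {
  tiles <- tibble::tibble(tile_id = "t1", chrom = "c", start = 0, end = 200)
  cov <- tibble::tibble(chrom = "c", pos = c(10, 20), sample = "s",
                        meth = c(10, 0), unmeth = c(0, 1000))
  per_base <- tile_percent(cov, tiles, mode = "per-base-mean")
  pooled <- tile_percent(cov, tiles, mode = "pooled")
  expect_equal(per_base$pct, 50)
  expect_equal(pooled$pct, 100 * 10 / 1010)

  # equal coverage -> both modes coincide
  cov_eq <- tibble::tibble(chrom = "c", pos = c(10, 20), sample = "s",
                           meth = c(7, 3), unmeth = c(3, 7))
  expect_equal(tile_percent(cov_eq, tiles)$pct,
               tile_percent(cov_eq, tiles, mode = "pooled")$pct)

  # all methylated -> 100 in both modes
  cov_full <- tibble::tibble(chrom = "c", pos = c(10, 20), sample = "s",
                             meth = c(5, 9), unmeth = 0)
  expect_equal(tile_percent(cov_full, tiles)$pct, 100)
  expect_equal(tile_percent(cov_full, tiles, mode = "pooled")$pct, 100)
})

test_that("the DMR test degenerates correctly and matches the exact oracle", {
  tiles <- tibble::tibble(tile_id = "t1", chrom = "c", start = 0, end = 100)
  # identical counts in both groups -> p = 1, difference 0
  cov_eq <- tidyr::crossing(pos = c(10, 50), sample = c("a1", "a2", "b1", "b2")) |>
    dplyr::mutate(chrom = "c", group = substr(sample, 1, 1),
                  meth = 7, unmeth = 3)
  res <- dmr_test(cov_eq, tiles)
  expect_equal(res$p, 1)
  expect_equal(res$diff, 0)

  # phi = 0 extreme: pooled (95/5) vs (5/95) against the Fisher oracle
  cov_x <- tibble::tibble(chrom = "c", pos = 50,
                          sample = c("a1", "a2", "b1", "b2"),
                          group = c("A", "A", "B", "B"),
                          meth = c(48, 47, 2, 3), unmeth = c(2, 3, 48, 47))
  res_x <- dmr_test(cov_x, tiles)
  p_oracle <- stats::fisher.test(matrix(c(95, 5, 5, 95), 2))$p.value
  expect_lt(res_x$p, 1e-30)
  # -log10 p agrees with the exact oracle within 10% relative
  expect_lt(abs(log10(res_x$p) - log10(p_oracle)) / abs(log10(p_oracle)), 0.1)

  # zero counts in one group -> NA with a report
  cov_z <- cov_x
  cov_z$meth[cov_z$group == "B"] <- 0
  cov_z$unmeth[cov_z$group == "B"] <- 0
  expect_message(res_z <- dmr_test(cov_z, tiles), "skipped")
  expect_true(is.na(res_z$p))
})

test_that("DMR calling gates on adjusted p and on the difference", {
  res <- tibble::tibble(tile_id = c("t1", "t2", "t3"), chrom = "c",
                        start = c(0, 100, 200), end = c(50, 150, 250),
                        mean_a = 40, mean_b = c(59.9, 70, 41),
                        diff = c(19.9, 30, 1), p = c(1e-10, 1e-10, 0.9))
  class(res) <- c("oomics_dmr_test", class(res))
  called <- call_dmrs(res, alpha = 0.05, min_diff = 20)
  expect_identical(called$call, c(FALSE, TRUE, FALSE))  # difference gate
  expect_identical(called$direction, c("hyper", "hyper", "hyper"))
  # hyper/hypo partition of calls is exhaustive and exclusive
  expect_true(all(called$direction[called$call] %in% c("hyper", "hypo")))
})

test_that("DMR-to-domain merging respects direction and is idempotent", {
  dmrs <- tibble::tibble(
    tile_id = paste0("t", 1:4), chrom = "c",
    start = c(0, 100, 300, 700), end = c(100, 200, 400, 800),
    diff = c(30, 35, -40, 30),
    direction = c("hyper", "hyper", "hypo", "hyper"),
    call = TRUE)
  dmd <- merge_dmrs(dmrs, max_gap = 100)
  expect_equal(nrow(dmd), 3)
  hyper1 <- dmd[dmd$start == 0, ]
  expect_equal(hyper1$end, 200)
  expect_equal(hyper1$n_dmrs, 2L)
  expect_equal(hyper1$mean_diff, 32.5)
  # adjacent hyper and hypo never merge
  expect_setequal(dmd$direction, c("hyper", "hypo", "hyper"))

  # idempotent: merging the domains again changes nothing
  again <- merge_dmrs(dplyr::mutate(dmd, diff = mean_diff), max_gap = 100)
  expect_equal(again[, c("chrom", "start", "end", "direction")],
               dmd[, c("chrom", "start", "end", "direction")])

  # order invariance
  dmd2 <- merge_dmrs(dmrs[sample(nrow(dmrs)), ], max_gap = 100)
  expect_equal(dmd2, dmd)
})

test_that("domain clustering recovers planted common/unique structure", {
  set.seed(9)
  n <- 120
  planted <- rep(c("common", "unique"), each = n / 2)
  doms <- tibble::tibble(
    domain_id = paste0("d", 1:n),
    direction = rep(c("hyper", "hypo"), n / 2),
    diff_cdko = c(rnorm(n / 2, 35, 3), rnorm(n / 2, 35, 3)),
    diff_cko = c(rnorm(n / 2, 33, 3), rnorm(n / 2, 0, 3)))
  out <- cluster_domains(doms, cols = c("diff_cko", "diff_cdko"))
  expect_gte(mean(out$cluster == planted), 0.95)

  # identical columns -> everything common
  same <- tibble::tibble(domain_id = paste0("s", 1:10), direction = "hyper",
                         diff_cko = 1:10, diff_cdko = 1:10)
  expect_true(all(cluster_domains(same)$cluster == "common"))

  # deterministic under fixed input order
  out2 <- cluster_domains(doms, cols = c("diff_cko", "diff_cdko"))
  expect_identical(out, out2)

  expect_warning(cluster_domains(same[1, ]), "fewer")
})

test_that("region methylation is consistent with tiles and recombines linearly", {
  tiles <- tibble::tibble(tile_id = "t1", chrom = "c", start = 0, end = 100)
  cov <- tibble::tibble(chrom = "c", pos = c(10, 40, 80), sample = "s",
                        meth = c(3, 6, 0), unmeth = c(7, 4, 10))
  # a region covering exactly the tile equals tile_percent
  r <- region_methylation(tibble::tibble(chrom = "c", start = 0, end = 100), cov)
  expect_equal(r$pct, tile_percent(cov, tiles)$pct)

  # fully methylated region
  cov_full <- dplyr::mutate(cov, meth = 5, unmeth = 0)
  expect_equal(region_methylation(
    tibble::tibble(chrom = "c", start = 0, end = 100), cov_full)$pct, 100)

  # disjoint partition recombines (CpG-count weighted) to the whole value
  parts <- tibble::tibble(chrom = "c", start = c(0, 50), end = c(50, 100))
  rp <- region_methylation(parts, cov)
  whole <- region_methylation(tibble::tibble(chrom = "c", start = 0, end = 100), cov)
  expect_equal(sum(rp$pct * rp$n_cpg) / sum(rp$n_cpg), whole$pct)

  # region without covered CpGs is flagged
  expect_message(
    r0 <- region_methylation(tibble::tibble(chrom = "c", start = 500, end = 600), cov),
    "without covered")
  expect_true(is.na(r0$pct))
})

test_that("DMR pipeline is invariant to chromosome processing order", {
  g <- make_genome(chrom_sizes = c(chr1 = 1e6, chr2 = 1e6), cpg_rate = 0.006,
                   n_cgis = 0, n_genes = 4, n_ervs = 0, seed = 71)
  tiles <- tile_by_cpg(g$cpg)
  bs <- simulate_bisulfite(g, group_means = c(a = 50, b = 60), seed = 72)
  res1 <- dmr_test(bs$cov, tiles)
  flip <- dplyr::arrange(bs$cov, dplyr::desc(chrom), pos)
  res2 <- dmr_test(flip, tiles)
  expect_equal(res1, res2)
})
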