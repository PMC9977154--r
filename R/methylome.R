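#' Tile the genome by CpG count
#'
#' Consecutive non-overlapping tiles of exactly `n` CpGs per chromosome
#' (equal CpG content, unequal bp span). Trailing CpGs that do not fill a
#' complete tile are dropped. A tile spans from its first CpG to one base
#' past its last CpG.
#'
#' @param cpg Tibble (chrom, pos) with positions sorted per chromosome.
#' @param n CpGs per tile (default 100).
#' @return Tibble (tile_id, chrom, start, end, cpg_count).
#' @export
tile_by_cpg <- function(cpg, n = 100) {
  if (n <= 0) abort("`n` must be positive")
  by_chr <- split(cpg$pos, cpg$chrom)
  if (any(vapply(by_chr, is.unsorted, logical(1)))) {
    abort("CpG positions must be sorted per chromosome")
  }
  out <- lapply(names(by_chr), function(ch) {
    p <- by_chr[[ch]]
    k <- length(p) %/% n
    if (k == 0) return(NULL)
    first <- p[seq.int(1, by = n, length.out = k)]
    last <- p[seq.int(n, by = n, length.out = k)]
    tibble::tibble(chrom = ch, start = first, end = last + 1,
                   cpg_count = n, tile_index = seq_len(k))
  })
  out <- dplyr::bind_rows(out)
  out$tile_id <- sprintf("%s_t%05d", out$chrom, out$tile_index)
  out[, c("tile_id", "chrom", "start", "end", "cpg_count")]
}

# Assign each CpG record to the tile whose span contains it (NA outside).
assign_cpg_tiles <- function(cpg, tiles) {
  res <- rep(NA_character_, nrow(cpg))
  for (ch in unique(cpg$chrom)) {
    ti <- tiles[tiles$chrom == ch, , drop = FALSE]
    if (!nrow(ti)) next
    sel <- which(cpg$chrom == ch)
    idx <- findInterval(cpg$pos[sel], ti$start)
    ok <- idx >= 1 & idx <= nrow(ti)
    ok[ok] <- cpg$pos[sel][ok] < ti$end[idx[ok]]
    res[sel[ok]] <- ti$tile_id[idx[ok]]
  }
  res
}

#' Aggregate per-CpG coverage into tile summaries
#'
#' @param cov Long tibble (chrom, pos, sample, meth, unmeth); a `group`
#'   column, if present, is carried through.
#' @param tiles Tiles from [tile_by_cpg()].
#' @return Tibble (tile_id, chrom, start, end, sample\[, group\], meth,
#'   unmeth, n_obs, n_cpg_covered, pct) where `n_obs` is the
#'   observed-cytosine total (sum of meth + unmeth) and `pct` the
#'   per-base-mean methylation percentage.
#' @export
aggregate_tiles <- function(cov, tiles) {
  key <- dplyr::distinct(cov, .data$chrom, .data$pos)
  key$tile_id <- assign_cpg_tiles(key, tiles)
  cov <- dplyr::left_join(cov, key, by = c("chrom", "pos"))
  cov <- cov[!is.na(cov$tile_id), , drop = FALSE]
  grouping <- c("tile_id", "sample", intersect("group", names(cov)))
  out <- cov %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) %>%
    dplyr::summarise(
      meth = sum(.data$meth), unmeth = sum(.data$unmeth),
      n_obs = sum(.data$meth + .data$unmeth),
      n_cpg_covered = sum(.data$meth + .data$unmeth > 0),
      pct = mean(100 * .data$meth[.data$meth + .data$unmeth > 0] /
                   (.data$meth + .data$unmeth)[.data$meth + .data$unmeth > 0]),
      .groups = "drop")
  dplyr::inner_join(tiles[, c("tile_id", "chrom", "start", "end")], out,
                    by = "tile_id")
}

#' Filter tiles by observed-cytosine coverage
#'
#' A tile is retained only when every sample reaches `min_obs` observed
#' cytosines (>=, so exactly `min_obs` passes). The number of dropped
#' tiles is reported.
#'
#' @param tile_summary Output of [aggregate_tiles()].
#' @param min_obs Minimum observed cytosines per tile and sample.
#' @return The retained rows of `tile_summary`.
#' @export
coverage_filter <- function(tile_summary, min_obs = 10) {
  n_samples <- length(unique(tile_summary$sample))
  keep <- tile_summary %>%
    dplyr::group_by(.data$tile_id) %>%
    dplyr::summarise(ok = dplyr::n() == n_samples & all(.data$n_obs >= min_obs),
                     .groups = "drop")
  dropped <- sum(!keep$ok)
  inform(sprintf("coverage_filter: retained %d/%d tiles (dropped %d)",
                 sum(keep$ok), nrow(keep), dropped))
  dplyr::semi_join(tile_summary, keep[keep$ok, ], by = "tile_id")
}

#' Per-tile methylation percentage
#'
#' Default mode `per-base-mean` averages the per-CpG methylation
#' percentages of covered CpGs (each CpG counts equally regardless of
#' depth); mode `pooled` divides summed methylated by summed total calls,
#' weighting CpGs by coverage. Samples with no covered CpG in a tile get
#' NA and are flagged.
#'
#' @param cov Long per-CpG tibble (chrom, pos, sample, meth, unmeth).
#' @param tiles Tiles from [tile_by_cpg()].
#' @param mode "per-base-mean" (default) or "pooled".
#' @return Tibble (tile_id, sample, pct, flagged).
#' @export
tile_percent <- function(cov, tiles, mode = c("per-base-mean", "pooled")) {
  mode <- match.arg(mode)
  key <- dplyr::distinct(cov, .data$chrom, .data$pos)
  key$tile_id <- assign_cpg_tiles(key, tiles)
  cov <- dplyr::left_join(cov, key, by = c("chrom", "pos"))
  cov <- cov[!is.na(cov$tile_id), , drop = FALSE]
  cov$total <- cov$meth + cov$unmeth
  out <- cov %>%
    dplyr::group_by(.data$tile_id, .data$sample) %>%
    dplyr::summarise(
      pct = if (sum(.data$total) == 0) NA_real_
            else if (mode == "pooled") 100 * sum(.data$meth) / sum(.data$total)
            else mean(100 * .data$meth[.data$total > 0] / .data$total[.data$total > 0]),
      .groups = "drop")
  out$flagged <- is.na(out$pct)
  if (any(out$flagged)) inform(sprintf(
    "tile_percent: %d tile/sample pairs with no covered CpG", sum(out$flagged)))
  out
}

# Beta-binomial log-likelihood with dispersion phi at mean p;
# phi = 0 degenerates to the binomial.
bb_loglik <- function(y, n, p, phi) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (phi <= 0) {
    sum(stats::dbinom(y, n, p, log = TRUE))
  } else {
    theta <- (1 - phi) / phi
    a <- p * theta
    b <- (1 - p) * theta
    sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
  }
}

bb_mle_p <- function(y, n, phi) {
  p0 <- sum(y) / sum(n)
  if (phi <= 0 || p0 <= 0 || p0 >= 1) return(p0)
  stats::optimize(function(p) -bb_loglik(y, n, p, phi),
                  interval = c(1e-9, 1 - 1e-9), tol = 1e-7)$minimum
}

# Method-of-moments beta dispersion phi from the scatter of per-CpG
# proportions around their group means: E[(p_hat - p_g)^2] =
# p_g(1-p_g)(phi + (1-phi)/n). Group-mean centring keeps a real group
# difference out of the dispersion estimate. Floored at 0 (binomial).
bb_mom_phi <- function(y, n, group) {
  keep <- n > 0
  y <- y[keep]; n <- n[keep]; group <- group[keep]
  if (length(y) < 2) return(0)
  num <- 0; den <- 0
  for (g in unique(group)) {
    sel <- group == g
    pg <- sum(y[sel]) / sum(n[sel])
    if (pg <= 0 || pg >= 1) next
    num <- num + sum((y[sel] / n[sel] - pg)^2 / (pg * (1 - pg)) - 1 / n[sel])
    den <- den + sum((n[sel] - 1) / n[sel])
  }
  if (den <= 0) return(0)
  max(0, min(0.99, num / den))
}

# Beta-binomial likelihood-ratio test of equal group means over the
# per-CpG x replicate observations of one tile, with a common per-tile
# dispersion estimated by method of moments; 1-df chi-square p-value.
bb_lrt <- function(y, n, group) {
  if (any(tapply(n, group, sum) == 0)) return(NA_real_)
  phi <- bb_mom_phi(y, n, group)
  keep <- n > 0
  y <- y[keep]; n <- n[keep]; group <- group[keep]
  l0 <- bb_loglik(y, n, bb_mle_p(y, n, phi), phi)
  l1 <- 0
  for (g in unique(group)) {
    sel <- group == g
    l1 <- l1 + bb_loglik(y[sel], n[sel], bb_mle_p(y[sel], n[sel], phi), phi)
  }
  stat <- max(0, 2 * (l1 - l0))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Differential methylation test per tile
#'
#' For each tile a beta-binomial likelihood-ratio test compares the two
#' groups on the per-CpG (methylated, unmethylated) observations of all
#' replicates. The common per-tile beta dispersion phi is a
#' method-of-moments estimate from the scatter of per-CpG proportions
#' around the pooled tile mean, floored at 0 (pure binomial); the
#' likelihood ratio is referred to a 1-df chi-square. Working at per-CpG
#' resolution gives the dispersion estimate hundreds of observations per
#' tile (100 CpGs x replicates), which is what makes the chi-square
#' reference calibrated at two replicates per group. The reported
#' difference is the group-B minus group-A mean of the per-sample
#' per-base-mean percentages.
#'
#' @param cov Long per-CpG tibble (chrom, pos, sample, meth, unmeth),
#'   with a `group` column or `groups` supplied.
#' @param tiles Tiles to test: [tile_by_cpg()] output, or the output of
#'   [coverage_filter()] (only its distinct tiles are used).
#' @param groups Named character vector sample -> group, or NULL to use
#'   the `group` column of `cov`.
#' @param group_a,group_b The reference and comparison group; difference
#'   is B - A. Default: first and second group encountered.
#' @return Tibble of class `oomics_dmr_test` (tile_id, chrom, start, end,
#'   mean_a, mean_b, diff, p). Tiles with zero total counts in a group
#'   get NA p and are reported.
#' @export
dmr_test <- function(cov, tiles, groups = NULL, group_a = NULL, group_b = NULL) {
  tiles <- dplyr::distinct(tiles[, c("tile_id", "chrom", "start", "end")])
  if (!is.null(groups)) cov$group <- groups[cov$sample]
  if (!"group" %in% names(cov)) abort("supply `groups` or a group column")
  lv <- sort(unique(cov$group))
  if (length(lv) != 2) abort("exactly two groups are required")
  group_a <- group_a %||% lv[1]
  group_b <- group_b %||% lv[2]

  key <- dplyr::distinct(cov, .data$chrom, .data$pos)
  key$tile_id <- assign_cpg_tiles(key, tiles)
  cov <- dplyr::left_join(cov, key, by = c("chrom", "pos"))
  cov <- cov[!is.na(cov$tile_id), , drop = FALSE]
  cov$total <- cov$meth + cov$unmeth

  per_sample <- cov %>%
    dplyr::group_by(.data$tile_id, .data$sample, .data$group) %>%
    dplyr::summarise(
      pct = if (sum(.data$total) == 0) NA_real_
            else mean(100 * .data$meth[.data$total > 0] /
                        .data$total[.data$total > 0]),
      .groups = "drop")
  means <- per_sample %>%
    dplyr::group_by(.data$tile_id) %>%
    dplyr::summarise(
      mean_a = mean(.data$pct[.data$group == group_a], na.rm = TRUE),
      mean_b = mean(.data$pct[.data$group == group_b], na.rm = TRUE),
      .groups = "drop")

  pvals <- vapply(split(cov[, c("meth", "total", "group")], cov$tile_id),
                  function(d) bb_lrt(d$meth, d$total, d$group),
                  numeric(1))
  res <- tiles %>%
    dplyr::inner_join(means, by = "tile_id") %>%
    dplyr::mutate(p = unname(pvals[.data$tile_id]),
                  diff = .data$mean_b - .data$mean_a) %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::select("tile_id", "chrom", "start", "end",
                  "mean_a", "mean_b", "diff", "p")
  n_skip <- sum(is.na(res$p))
  if (n_skip) inform(sprintf("dmr_test: %d tiles skipped (zero counts in a group)", n_skip))
  class(res) <- c("oomics_dmr_test", class(res))
  attr(res, "groups") <- c(a = group_a, b = group_b)
  res
}

#' Call differentially methylated regions
#'
#' A tile is a DMR when its Benjamini-Hochberg adjusted p-value is below
#' `alpha` and the absolute methylation difference reaches `min_diff`
#' percentage points. Direction follows the sign of the difference
#' (hyper = gained in group B).
#'
#' @param res Output of [dmr_test()].
#' @param alpha BH-adjusted significance level.
#' @param min_diff Minimum absolute difference in percentage points.
#' @return `res` with padj, direction and call columns; class
#'   `oomics_dmr`.
#' @export
call_dmrs <- function(res, alpha = 0.05, min_diff = 20) {
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res$direction <- ifelse(res$diff > 0, "hyper",
                          ifelse(res$diff < 0, "hypo", NA_character_))
  res$call <- !is.na(res$padj) & res$padj < alpha & abs(res$diff) >= min_diff
  class(res) <- unique(c("oomics_dmr", class(res)))
  attr(res, "alpha") <- alpha
  attr(res, "min_diff") <- min_diff
  res
}

#' Merge DMRs into differentially methylated domains
#'
#' Same-direction DMR tiles that are adjacent or separated by at most
#' `max_gap` bp are merged into one domain; hyper- and hypomethylated
#' DMRs never merge. The default gap of one tile-equivalent (the median
#' DMR tile span) bridges a single dropped or non-significant tile.
#'
#' @param dmrs Output of [call_dmrs()] (only rows with `call` TRUE are
#'   used), or any tibble with chrom, start, end, direction, diff.
#' @param max_gap Merge gap in bp; default the median tile span.
#' @return Tibble (domain_id, chrom, start, end, direction, n_dmrs,
#'   mean_diff).
#' @export
merge_dmrs <- function(dmrs, max_gap = NULL) {
  x <- dmrs
  if ("call" %in% names(x)) x <- x[x$call, , drop = FALSE]
  if (nrow(x) == 0) {
    return(tibble::tibble(domain_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          direction = character(), n_dmrs = integer(),
                          mean_diff = numeric()))
  }
  max_gap <- max_gap %||% stats::median(x$end - x$start)
  out <- lapply(split(x, x$direction), function(d) {
    d <- dplyr::arrange(d, .data$chrom, .data$start)
    m <- merge_interval_runs(d, max_gap = max_gap)
    gr_d <- as_granges0(m); gr_t <- as_granges0(d)
    hits <- GenomicRanges::findOverlaps(gr_t, gr_d)
    md <- tapply(d$diff[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), mean)
    m$direction <- d$direction[1]
    m$mean_diff <- as.numeric(md[as.character(seq_len(nrow(m)))])
    m
  })
  out <- dplyr::bind_rows(out) %>% dplyr::arrange(.data$chrom, .data$start)
  out$domain_id <- sprintf("dmd%05d", seq_len(nrow(out)))
  names(out)[names(out) == "n_members"] <- "n_dmrs"
  out[, c("domain_id", "chrom", "start", "end", "direction", "n_dmrs", "mean_diff")]
}

#' Cluster methylation domains into common and genotype-unique sets
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of the
#' per-genotype methylation-difference matrix, cut at k = 2 within each
#' direction. The cluster whose single-knockout mean difference is closer
#' to its double-knockout mean is labelled "common", the other "unique" —
#' reproducing the common/unique dichotomy of shared vs
#' double-knockout-specific domains.
#'
#' @param domains Tibble with a `direction` column and the numeric
#'   columns named in `cols`.
#' @param cols Length-2 character vector: the single-knockout and the
#'   double-knockout difference columns, in that order.
#' @return `domains` with a `cluster` label column.
#' @export
cluster_domains <- function(domains, cols = c("diff_cko", "diff_cdko")) {
  if (!all(cols %in% names(domains))) abort("difference columns missing")
  if (anyNA(domains[, cols])) abort("difference matrix must be complete")
  if (nrow(domains) < 2) {
    warn("fewer than 2 domains; all labelled common")
    domains$cluster <- rep("common", nrow(domains))
    return(domains)
  }
  domains$._row <- seq_len(nrow(domains))
  parts <- lapply(split(domains, domains$direction), function(d) {
    if (nrow(d) < 2) {
      d$cluster <- "common"
      return(d)
    }
    m <- as.matrix(d[, cols])
    hc <- stats::hclust(stats::dist(m), method = "ward.D2")
    grp <- stats::cutree(hc, k = 2)
    gap <- vapply(1:2, function(k)
      abs(mean(m[grp == k, 1]) - mean(m[grp == k, 2])), numeric(1))
    # ties (e.g. identical columns): every minimal-gap cluster is common
    common_k <- which(gap <= min(gap) + 1e-8)
    d$cluster <- ifelse(grp %in% common_k, "common", "unique")
    d
  })
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$._row), , drop = FALSE]
  out$._row <- NULL
  out
}

#' Mean methylation of arbitrary regions
#'
#' Per-base-mean methylation percentage over the CpGs falling inside each
#' region, per sample. Regions with no covered CpG are flagged with NA.
#'
#' @param regions Tibble (chrom, start, end) with optional `name`.
#' @param cov Long per-CpG tibble (chrom, pos, sample, meth, unmeth).
#' @return Tibble (region index/name, sample, pct, n_cpg).
#' @export
region_methylation <- function(regions, cov) {
  check_intervals(regions, what = "regions")
  regions$._r <- seq_len(nrow(regions))
  gr_c <- GenomicRanges::GRanges(cov$chrom, IRanges::IRanges(cov$pos + 1, cov$pos + 1))
  hits <- GenomicRanges::findOverlaps(gr_c, as_granges0(regions))
  sub <- cov[S4Vectors::queryHits(hits), , drop = FALSE]
  sub$._r <- regions$._r[S4Vectors::subjectHits(hits)]
  sub$total <- sub$meth + sub$unmeth
  agg <- sub %>%
    dplyr::group_by(.data$._r, .data$sample) %>%
    dplyr::summarise(
      pct = if (sum(.data$total) == 0) NA_real_
            else mean(100 * .data$meth[.data$total > 0] / .data$total[.data$total > 0]),
      n_cpg = sum(.data$total > 0), .groups = "drop")
  frame <- tidyr::crossing(._r = regions$._r, sample = unique(cov$sample))
  out <- dplyr::left_join(frame, agg, by = c("._r", "sample"))
  out$n_cpg[is.na(out$n_cpg)] <- 0L
  if (any(is.na(out$pct))) inform(sprintf(
    "region_methylation: %d region/sample pairs without covered CpGs",
    sum(is.na(out$pct))))
  out <- dplyr::rename(out, region = "._r")
  if ("name" %in% names(regions)) {
    out$name <- regions$name[out$region]
  }
  out
}
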