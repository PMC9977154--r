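# Helpers for the wide count layout (unit id in column 1, samples after).
count_matrix <- function(counts) {
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts[[1]]
  storage.mode(m) <- "double"
  m
}

#' Log counts per million
#'
#' log2(count / library_size x 1e6 + pseudocount).
#'
#' @param counts Wide tibble (gene_id first, one column per sample).
#' @param pseudocount Added to the CPM before the log (default 1).
#' @param library_sizes Named vector; default column sums.
#' @return Tibble of the same shape with log2-CPM values.
#' @export
log_cpm <- function(counts, pseudocount = 1, library_sizes = NULL) {
  m <- count_matrix(counts)
  lib <- library_sizes %||% colSums(m)
  if (any(lib <= 0)) abort("library sizes must be positive")
  out <- log2(sweep(m, 2, lib / 1e6, "/") + pseudocount)
  dplyr::bind_cols(counts[, 1], tibble::as_tibble(out))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median ratio of its counts to the per-gene
#' geometric mean, over genes with nonzero counts in every sample;
#' factors are rescaled to geometric mean 1.
#'
#' @param counts Wide count tibble.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    abort(paste("no gene has nonzero counts in all samples;",
                "filter genes or supply size factors computed elsewhere"))
  }
  logm <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(logm)
  sf <- apply(logm, 2, function(x) exp(stats::median(x - ref)))
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for differential expression
#'
#' Per gene, group means of size-factor-normalized counts give the log2
#' fold change (second group over first). The NB dispersion is a
#' method-of-moments estimate from the pooled within-group variance,
#' floored at 1e-8 and shrunk 50/50 toward a 1/mean trend fitted across
#' all genes. The Wald statistic is log2FC over its delta-method standard
#' error, referred to the standard normal, with Benjamini-Hochberg
#' adjustment. Genes with all-zero counts are excluded and reported.
#'
#' @param counts Wide count tibble (gene_id first column).
#' @param groups Named character vector sample -> group (two groups).
#'   The fold change is the non-reference group over the reference;
#'   swapping the labels between samples negates it exactly.
#' @param shrink_weight Weight of the gene-wise estimate in the shrinkage
#'   (default 0.5).
#' @param sf Optional size factors; default [size_factors()].
#' @param reference Group used as the denominator; default the
#'   alphabetically first label.
#' @return Tibble of class `oomics_de` (gene_id, base_mean, log2fc, se,
#'   stat, p, padj, dispersion).
#' @export
nb_wald_test <- function(counts, groups, shrink_weight = 0.5, sf = NULL,
                         reference = NULL) {
  m <- count_matrix(counts)
  samples <- colnames(m)
  if (!all(samples %in% names(groups))) abort("every sample needs a group label")
  g <- groups[samples]
  lv <- sort(unique(unname(g)))
  if (length(lv) != 2) abort("exactly two groups are required")
  if (!is.null(reference)) {
    if (!reference %in% lv) abort("`reference` is not a group label")
    lv <- c(reference, setdiff(lv, reference))
  }
  if (any(table(g) < 2)) abort("at least two samples per group are required")

  all_zero <- rowSums(m) == 0
  if (any(all_zero)) {
    inform(sprintf("nb_wald_test: excluding %d all-zero genes", sum(all_zero)))
    m <- m[!all_zero, , drop = FALSE]
  }
  sf <- sf %||% size_factors(dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m)))
  q <- sweep(m, 2, sf[samples], "/")

  idx_a <- which(g == lv[1]); idx_b <- which(g == lv[2])
  n_a <- length(idx_a); n_b <- length(idx_b)
  m_a <- rowMeans(q[, idx_a, drop = FALSE])
  m_b <- rowMeans(q[, idx_b, drop = FALSE])
  base_mean <- rowMeans(q)

  # pooled within-group variance of normalized counts
  v_a <- apply(q[, idx_a, drop = FALSE], 1, stats::var)
  v_b <- apply(q[, idx_b, drop = FALSE], 1, stats::var)
  s2_w <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
  m_w <- (n_a * m_a + n_b * m_b) / (n_a + n_b)
  disp_raw <- pmax((s2_w - m_w) / pmax(m_w, 1e-8)^2, 1e-8)

  # 1/mean dispersion trend across genes, then 50/50 shrinkage toward it
  pos <- base_mean > 0
  fit <- stats::lm(disp_raw[pos] ~ I(1 / base_mean[pos]))
  disp_trend <- pmax(as.numeric(fit$coefficients[1]) +
                       as.numeric(fit$coefficients[2]) / pmax(base_mean, 1e-8),
                     1e-8)
  dispersion <- shrink_weight * disp_raw + (1 - shrink_weight) * disp_trend

  # guard empty group means symmetrically so swapping groups negates lfc
  floor_a <- 0.5 / n_a; floor_b <- 0.5 / n_b
  ma <- pmax(m_a, floor_a); mb <- pmax(m_b, floor_b)
  log2fc <- log2(mb) - log2(ma)

  inv_sf_a <- mean(1 / sf[samples][idx_a]); inv_sf_b <- mean(1 / sf[samples][idx_b])
  var_ma <- (ma * inv_sf_a + dispersion * ma^2) / n_a
  var_mb <- (mb * inv_sf_b + dispersion * mb^2) / n_b
  se <- sqrt(var_ma / ma^2 + var_mb / mb^2) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))

  out <- tibble::tibble(
    gene_id = rownames(m), base_mean = base_mean, log2fc = log2fc,
    se = se, stat = stat, p = p, padj = stats::p.adjust(p, "BH"),
    dispersion = dispersion)
  class(out) <- c("oomics_de", class(out))
  attr(out, "groups") <- lv
  out
}

#' Call differentially expressed genes
#'
#' Up: adjusted p below `alpha` and log2FC at or above `lfc` (the
#' fold-change filter applied after the differential fit); down is
#' symmetric. With `strict = TRUE` the fold-change comparison is strict
#' (>).
#'
#' @param res Output of [nb_wald_test()].
#' @param lfc Log2 fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param strict Use strict inequality on the fold change.
#' @return `res` with a `call` column in {up, down, none}.
#' @export
call_degs <- function(res, lfc = 1.5, alpha = 0.05, strict = FALSE) {
  ge <- if (strict) `>` else `>=`
  sig <- !is.na(res$padj) & res$padj < alpha
  res$call <- dplyr::case_when(
    sig & ge(res$log2fc, lfc) ~ "up",
    sig & ge(-res$log2fc, lfc) ~ "down",
    TRUE ~ "none")
  res
}

#' Down-sample count libraries to a fixed depth
#'
#' Columns above the target are down-sampled by a multivariate
#' hypergeometric draw (reads without replacement), so realized totals
#' equal the target exactly; columns at or below the target pass through
#' unchanged with a warning.
#'
#' @param counts Wide count tibble.
#' @param target Target library size (default 1.9 million reads).
#' @param seed Integer seed.
#' @return Tibble of the same shape.
#' @export
downsample_counts <- function(counts, target = 1900000, seed) {
  if (missing(seed)) abort("`seed` is required")
  m <- count_matrix(counts)
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      tot <- sum(m[, j])
      if (tot <= target) {
        if (tot < target) warn(sprintf(
          "column %s (%d reads) is below the target %d; left unchanged",
          colnames(m)[j], as.integer(tot), as.integer(target)))
        next
      }
      remaining <- target
      left <- tot
      x <- m[, j]
      for (i in seq_along(x)) {
        left <- left - x[i]
        draw <- stats::rhyper(1, m = x[i], n = left, k = remaining)
        remaining <- remaining - draw
        x[i] <- draw
      }
      m[, j] <- x
    }
  })
  dplyr::bind_cols(counts[, 1], tibble::as_tibble(m))
}

#' Quantify ERV expression as a percentage of the library
#'
#' ERVs closer than `exclusion_bp` to any gene (interval gap, strict <;
#' touching or overlapping counts as distance 0) are removed to avoid
#' counting ordinary exonic transcription as ERV signal; remaining
#' per-ERV counts are summed per sample and expressed as a percentage of
#' total library counts.
#'
#' @param erv_counts Wide count tibble (erv_id first column).
#' @param ervs Tibble (chrom, start, end, erv_id\[, family\]).
#' @param genes Tibble of gene intervals.
#' @param exclusion_bp Exclusion distance in bp (default 2000).
#' @param library_sizes Named vector of total library counts per sample.
#' @return List with `percent` (tibble sample, erv_percent), `retained`
#'   (erv ids kept) and, when a family column is present, `by_family`.
#' @export
quantify_ervs <- function(erv_counts, ervs, genes, exclusion_bp = 2000,
                          library_sizes) {
  gr_e <- as_granges0(ervs)
  gr_g <- as_granges0(genes)
  d <- GenomicRanges::distanceToNearest(gr_e, gr_g)
  dist <- rep(Inf, nrow(ervs))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  keep_ids <- ervs$erv_id[dist >= exclusion_bp]

  m <- count_matrix(erv_counts)
  m <- m[rownames(m) %in% keep_ids, , drop = FALSE]
  if (!all(colnames(m) %in% names(library_sizes))) {
    abort("every sample needs a library size")
  }
  pct_tbl <- tibble::tibble(
    sample = colnames(m),
    erv_percent = unname(100 * colSums(m) / library_sizes[colnames(m)]))
  out <- list(percent = pct_tbl, retained = keep_ids)
  if ("family" %in% names(ervs)) {
    fam <- stats::setNames(ervs$family, ervs$erv_id)[rownames(m)]
    by_fam <- rowsum(m, fam)
    out$by_family <- dplyr::bind_cols(
      tibble::tibble(family = rownames(by_fam)),
      tibble::as_tibble(sweep(by_fam, 2, library_sizes[colnames(m)], "/") * 100))
  }
  out
}

#' Cluster differentially expressed genes by expression pattern
#'
#' Agglomerative clustering (Euclidean, Ward) of the supplied value
#' matrix, cut at k clusters (default 3, matching the down-in-both /
#' up-in-both / up-in-double-knockout-only trichotomy). Clusters are
#' labelled by the sign pattern of their column means.
#'
#' @param x Tibble: id column first, numeric value columns after (e.g.
#'   per-genotype log2 fold changes or mean log2 expression).
#' @param k Number of clusters.
#' @param flat_threshold Column means within this absolute value count as
#'   flat when building the pattern label.
#' @return Tibble (id, cluster, pattern).
#' @export
cluster_degs <- function(x, k = 3, flat_threshold = 0.5) {
  m <- as.matrix(x[, -1, drop = FALSE])
  if (nrow(m) < k) abort(sprintf("need at least %d rows to form %d clusters", k, k))
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  pat <- vapply(seq_len(k), function(ki) {
    mu <- colMeans(m[grp == ki, , drop = FALSE])
    paste(ifelse(mu > flat_threshold, "up",
                 ifelse(mu < -flat_threshold, "down", "flat")),
          collapse = "_")
  }, character(1))
  tibble::tibble(id = x[[1]], cluster = unname(grp), pattern = pat[grp])
}
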