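#' Fraction of query units overlapping a feature set
#'
#' Interval mode: fraction of query intervals with at least 1 bp
#' intersection with any feature interval. Set mode (plain vectors):
#' fraction of query ids that are members of the feature set.
#'
#' @param query Tibble (chrom, start, end) or character vector of ids.
#' @param features Tibble of intervals or character vector of ids.
#' @return A single fraction in \[0, 1\].
#' @export
overlap_fraction <- function(query, features) {
  if (is.data.frame(query)) {
    if (nrow(query) == 0) abort("empty query")
    if (!is.data.frame(features)) abort("features must be intervals too")
    mean(IRanges::overlapsAny(as_granges0(query), as_granges0(features)))
  } else {
    if (length(query) == 0) abort("empty query")
    mean(query %in% features)
  }
}

#' Overlap enrichment of a query against a background
#'
#' Builds the 2x2 table (query vs background) x (hit vs miss) and tests
#' it with a two-tailed Fisher's exact test (default) or a chi-square
#' test. A chi-square with any expected cell below 5 automatically falls
#' back to Fisher. The p-value is Bonferroni-multiplied by the supplied
#' family size and capped at 1.
#'
#' @param query_hits,query_n Hits and size of the query set.
#' @param bg_hits,bg_n Hits and size of the background set.
#' @param test "fisher" or "chisq".
#' @param family Number of tests in the Bonferroni family (default 1).
#' @return One-row tibble (query_hits, query_n, bg_hits, bg_n,
#'   frac_query, frac_bg, test_used, p, p_adj).
#' @export
enrichment_test <- function(query_hits, query_n, bg_hits, bg_n,
                            test = c("fisher", "chisq"), family = 1) {
  test <- match.arg(test)
  if (any(c(query_hits, query_n, bg_hits, bg_n) < 0)) abort("counts must be nonnegative")
  if (query_hits > query_n || bg_hits > bg_n) abort("hits exceed set size")
  tab <- matrix(c(query_hits, query_n - query_hits,
                  bg_hits, bg_n - bg_hits), nrow = 2,
                dimnames = list(c("hit", "miss"), c("query", "background")))
  used <- test
  if (test == "chisq") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      inform("expected cell below 5; falling back to Fisher's exact test")
      used <- "fisher"
    }
  }
  p <- if (used == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    stats::chisq.test(tab, correct = FALSE)$p.value
  }
  tibble::tibble(
    query_hits = query_hits, query_n = query_n,
    bg_hits = bg_hits, bg_n = bg_n,
    frac_query = query_hits / query_n, frac_bg = bg_hits / bg_n,
    test_used = used, p = p, p_adj = min(1, p * family))
}

# Spearman rho with average-rank ties and a two-sided t-approximation p.
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("paired vectors must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("at least 4 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant vector: rho undefined")
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Barcode-style rank enrichment of gene sets in a ranked list
#'
#' Genes are ranked by decreasing log2 fold change (rank 1 = most
#' up-regulated). For each set, the enrichment "worm" at every rank is
#' the set density inside a centred rectangular window of width
#' `span x N`, divided by the genome-wide set density, so a uniformly
#' spread set sits at 1. Each set is tested with a rank-sum test (normal
#' approximation with tie correction), one-sided in its nominal
#' direction. When a paired effect-size vector is supplied, the Spearman
#' correlation between the two effect sizes over all shared units is
#' reported.
#'
#' @param ranked Tibble (id, log2fc) or named numeric vector of ranking
#'   effect sizes.
#' @param up_set,down_set Character vectors of ids expected at the top /
#'   bottom of the ranking (subsets of the ranked ids).
#' @param span Window width as a fraction of N (0 < span <= 1).
#' @param paired Optional named numeric vector of matched effect sizes
#'   (e.g. protein log2FC) for the Spearman panel.
#' @return List of class `oomics_barcode`: `worm` (position, set,
#'   enrichment), `tests` (set, direction, n, p), `correlation`
#'   (tibble rho/p/n or NULL), `n_ranked`.
#' @export
barcode_enrichment <- function(ranked, up_set = NULL, down_set = NULL,
                               span = 0.25, paired = NULL) {
  if (span <= 0 || span > 1) abort("`span` must be in (0, 1]")
  if (is.data.frame(ranked)) ranked <- stats::setNames(ranked$log2fc, ranked$id)
  ord <- order(ranked, decreasing = TRUE)
  ids <- names(ranked)[ord]
  N <- length(ids)
  sets <- list(up = up_set, down = down_set)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (!length(sets)) abort("supply at least one of up_set/down_set")
  bad <- unlist(lapply(sets, setdiff, y = ids))
  if (length(bad)) abort("set members missing from the ranked list")

  h <- span * N / 2
  worm <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    member <- as.integer(ids %in% sets[[nm]])
    cs <- c(0, cumsum(member))
    pos <- seq_len(N)
    lo <- pmax(1, ceiling(pos - h))
    hi <- pmin(N, floor(pos + h))
    dens <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    tibble::tibble(position = pos, set = nm,
                   enrichment = dens / (sum(member) / N))
  }))

  tests <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    in_set <- ids %in% sets[[nm]]
    n_s <- sum(in_set)
    direction <- if (nm == "up") "less" else "greater"
    if (n_s < 3) {
      warn(sprintf("set '%s' has fewer than 3 members; test skipped", nm))
      return(tibble::tibble(set = nm, direction = direction,
                            n = n_s, p = NA_real_))
    }
    pos <- seq_len(N)
    p <- stats::wilcox.test(pos[in_set], pos[!in_set],
                            alternative = direction, exact = FALSE,
                            correct = TRUE)$p.value
    tibble::tibble(set = nm, direction = direction, n = n_s, p = p)
  }))

  correlation <- NULL
  if (!is.null(paired)) {
    shared <- intersect(names(ranked), names(paired))
    correlation <- spearman_cor(ranked[shared], paired[shared])
  }

  structure(list(worm = worm, tests = tests, correlation = correlation,
                 n_ranked = N, span = span),
            class = "oomics_barcode")
}

#' Rank correlation between methylation and expression changes
#'
#' Spearman's rank correlation (average-rank tie handling, two-sided p by
#' t approximation) between per-gene methylation differences and
#' expression log2 fold changes, optionally restricted to a subset of
#' genes.
#'
#' @param x Tibble with the two paired columns.
#' @param meth_col,lfc_col Column names (defaults "meth_diff", "log2fc").
#' @param subset Optional character vector of ids to keep; requires an
#'   id column named `gene_id`.
#' @return One-row tibble (rho, p, n).
#' @export
methylation_expression_correlation <- function(x, meth_col = "meth_diff",
                                               lfc_col = "log2fc",
                                               subset = NULL) {
  if (!is.null(subset)) x <- x[x$gene_id %in% subset, , drop = FALSE]
  spearman_cor(x[[meth_col]], x[[lfc_col]])
}

#' Partition two id sets
#'
#' @param a,b Character vectors (duplicates removed).
#' @return One-row tibble (only_a, shared, only_b).
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- length(intersect(a, b))
  tibble::tibble(only_a = length(a) - shared, shared = shared,
                 only_b = length(b) - shared)
}
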