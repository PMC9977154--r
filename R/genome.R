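#' Generate a synthetic genome annotation
#'
#' Builds the coordinate frame every other module works in: chromosome
#' sizes, CpG positions (clustered inside CpG islands, sparser elsewhere),
#' gene models with strand and an expression class, CpG islands, and ERV
#' intervals. Half of the ERVs are deliberately placed within 2 kb of a
#' gene so that the near-gene exclusion rule used in ERV quantification is
#' exercised by construction.
#'
#' All coordinates are 0-based, half-open.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#'   The default is a three-chromosome, 5-Mb-each desk-scale genome.
#' @param n_genes,n_cgis,n_ervs Number of genes, CpG islands and ERVs.
#' @param cpg_rate Per-bp CpG probability outside CpG islands.
#' @param cgi_cpg_rate Per-bp CpG probability inside CpG islands.
#' @param erv_near_fraction Fraction of ERVs placed within 2 kb of a gene.
#' @param seed Integer seed; the annotation is a pure function of the
#'   arguments and this seed.
#' @return An object of class `oomics_genome`: a list with tibbles
#'   `chrom_sizes` (chrom, length), `cpg` (chrom, pos), `genes`
#'   (gene_id, chrom, start, end, strand, expression_class), `cgis`
#'   (chrom, start, end) and `ervs` (chrom, start, end, erv_id, family,
#'   near_gene).
#' @export
make_genome <- function(chrom_sizes = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6),
                        n_genes = 300, n_cgis = 150, n_ervs = 100,
                        cpg_rate = 0.005, cgi_cpg_rate = 0.05,
                        erv_near_fraction = 0.5, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (any(chrom_sizes <= 0)) abort("chromosome sizes must be positive")
  if (is.null(names(chrom_sizes))) abort("`chrom_sizes` must be named")
  chrom_sizes <- round(chrom_sizes)

  with_seed(seed, {
    cgis <- place_intervals(chrom_sizes, round(stats::runif(n_cgis, 500, 2000)))
    cgis <- dplyr::arrange(cgis, .data$chrom, .data$start)

    genes <- place_intervals(chrom_sizes, round(stats::runif(n_genes, 5e3, 5e4)))
    genes <- dplyr::arrange(genes, .data$chrom, .data$start)
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$expression_class <- sample(c("not_expressed", "low", "high"),
      nrow(genes), replace = TRUE, prob = c(0.3, 0.3, 0.4))
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "expression_class")]

    cpg <- lapply(names(chrom_sizes), function(ch) {
      L <- chrom_sizes[[ch]]
      n_bg <- stats::rpois(1, cpg_rate * L)
      pos <- if (n_bg > 0) sample.int(L, min(n_bg, L)) - 1L else integer(0)
      ci <- cgis[cgis$chrom == ch, , drop = FALSE]
      if (nrow(ci)) {
        extra <- unlist(lapply(seq_len(nrow(ci)), function(i) {
          w <- ci$end[i] - ci$start[i]
          k <- stats::rpois(1, cgi_cpg_rate * w)
          if (k > 0) ci$start[i] + sample.int(w, min(k, w)) - 1L else integer(0)
        }))
        pos <- c(pos, extra)
      }
      tibble::tibble(chrom = ch, pos = sort(unique(as.integer(pos))))
    })
    cpg <- dplyr::bind_rows(cpg)

    ervs <- make_ervs(chrom_sizes, genes, n_ervs, erv_near_fraction)
  })

  genome <- structure(
    list(
      chrom_sizes = tibble::tibble(chrom = names(chrom_sizes),
                                   length = unname(chrom_sizes)),
      cpg = cpg, genes = genes, cgis = cgis, ervs = ervs,
      params = list(seed = seed, cpg_rate = cpg_rate,
                    cgi_cpg_rate = cgi_cpg_rate)
    ),
    class = "oomics_genome"
  )
  validate_genome(genome)
}

make_ervs <- function(chrom_sizes, genes, n_ervs, near_fraction) {
  if (n_ervs == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), erv_id = character(),
                          family = character(), near_gene = logical()))
  }
  n_near <- round(n_ervs * near_fraction)
  out <- vector("list", n_ervs)
  gr_genes <- as_granges0(genes)
  for (i in seq_len(n_ervs)) {
    len <- round(stats::runif(1, 500, 5000))
    if (i <= n_near && nrow(genes)) {
      # anchor within 2 kb of a random gene (gap in [0, 2000) bp)
      g <- genes[sample.int(nrow(genes), 1), ]
      gap <- sample.int(2000, 1) - 1L
      side <- sample(c("left", "right"), 1)
      s <- if (side == "right") g$end + gap else g$start - gap - len
      ch <- g$chrom
      if (s < 0 || s + len > chrom_sizes[[ch]]) {
        s <- g$end  # fall back to touching the gene
        if (s + len > chrom_sizes[[ch]]) s <- max(0, g$start - len)
      }
      out[[i]] <- tibble::tibble(chrom = ch, start = s, end = s + len,
                                 near_gene = TRUE)
    } else {
      # rejection-sample a placement at least 2 kb away from every gene
      for (try in 1:200) {
        ch <- sample(names(chrom_sizes), 1)
        s <- sample.int(chrom_sizes[[ch]] - len, 1) - 1L
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s + 1, s + len))
        d <- GenomicRanges::distanceToNearest(cand, gr_genes)
        dist <- if (length(d)) S4Vectors::mcols(d)$distance else Inf
        if (dist >= 2000) break
      }
      out[[i]] <- tibble::tibble(chrom = ch, start = s, end = s + len,
                                 near_gene = FALSE)
    }
  }
  ervs <- dplyr::bind_rows(out)
  ervs$erv_id <- sprintf("erv%04d", seq_len(nrow(ervs)))
  ervs$family <- sample(c("ERVK", "ERVL", "MaLR"), nrow(ervs), replace = TRUE)
  dplyr::arrange(
    ervs[, c("chrom", "start", "end", "erv_id", "family", "near_gene")],
    .data$chrom, .data$start)
}

validate_genome <- function(genome) {
  sizes <- stats::setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
  check_intervals(genome$genes, sizes, "genes")
  check_intervals(genome$cgis, sizes, "cgis")
  if (nrow(genome$ervs)) check_intervals(genome$ervs, sizes, "ervs")
  by_chr <- split(genome$cpg$pos, genome$cpg$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1)))) {
    abort("CpG positions must be strictly increasing per chromosome")
  }
  if (any(genome$cpg$pos < 0) ||
      any(genome$cpg$pos >= sizes[genome$cpg$chrom])) {
    abort("CpG positions out of chromosome bounds")
  }
  genome
}

#' @export
print.oomics_genome <- function(x, ...) {
  cat("<oomics_genome>\n")
  cat(sprintf("  %d chromosomes, %.1f Mb total\n",
              nrow(x$chrom_sizes), sum(x$chrom_sizes$length) / 1e6))
  cat(sprintf("  %d CpGs, %d genes, %d CGIs, %d ERVs\n",
              nrow(x$cpg), nrow(x$genes), nrow(x$cgis), nrow(x$ervs)))
  invisible(x)
}

#' Plant window-aligned enrichment domains
#'
#' Samples non-overlapping domains aligned to the 10-kb window grid; these
#' serve as planted truth for the ChIP simulator and give the domain
#' caller a recoverable target at exact window resolution.
#'
#' @param genome An `oomics_genome`.
#' @param n_domains Number of domains.
#' @param width Domain width in bp (rounded up to whole windows).
#' @param window_width Window grid the domains align to.
#' @param seed Integer seed.
#' @return Tibble (chrom, start, end) of planted domains.
#' @export
sample_truth_domains <- function(genome, n_domains = 30, width = 50000,
                                 window_width = 10000, seed) {
  if (missing(seed)) abort("`seed` is required")
  wins <- tile_windows(genome, width = window_width)
  k <- max(1L, ceiling(width / window_width))
  with_seed(seed, {
    picked <- list()
    occupied <- rep(FALSE, nrow(wins))
    tries <- 0
    while (length(picked) < n_domains && tries < 50 * n_domains) {
      tries <- tries + 1
      i <- sample.int(nrow(wins) - k + 1L, 1)
      idx <- i:(i + k - 1L)
      if (length(unique(wins$chrom[idx])) != 1 || any(occupied[idx])) next
      # keep a two-window buffer so planted domains never merge under the
      # one-window gap rule
      buf <- max(1L, i - 2L):min(nrow(wins), i + k + 1L)
      occupied[buf] <- TRUE
      picked[[length(picked) + 1L]] <-
        tibble::tibble(chrom = wins$chrom[i], start = wins$start[i],
                       end = wins$end[i + k - 1L])
    }
    dplyr::arrange(dplyr::bind_rows(picked), .data$chrom, .data$start)
  })
}
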