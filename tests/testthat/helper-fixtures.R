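# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; no data files are read.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Default desk-scale genome (3 x 5 Mb).
fix_genome <- function() memo("genome", function() make_genome(seed = 101))

# A sparse-CpG single-chromosome genome sized for ~500 methylation tiles.
fix_meth_genome <- function() memo("meth_genome", function() {
  make_genome(chrom_sizes = c(chr1 = 8e6), cpg_rate = 0.0065,
              n_cgis = 0, n_genes = 10, n_ervs = 0, seed = 202)
})

# Tiny deterministic window quantification for arithmetic checks.
fix_quant <- function(counts, width = 10000, lib = 1e6, sample = "s1") {
  n <- length(counts)
  quantify_rpkm(
    tibble::tibble(chrom = "chr1",
                   start = seq(0, by = width, length.out = n),
                   end = seq(width, by = width, length.out = n),
                   sample = sample, count = counts),
    library_size = stats::setNames(lib, sample))
}

# Brute-force gap-merge oracle on a bp bitmap: marks covered positions,
# then joins covered runs separated by at most `gap` uncovered bp.
merge_oracle <- function(intervals, gap) {
  out <- list()
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    lim <- max(iv$end) + 1
    covered <- rep(FALSE, lim)
    for (i in seq_len(nrow(iv))) covered[(iv$start[i] + 1):iv$end[i]] <- TRUE
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    segs <- data.frame(s = starts[runs$values] - 1, e = ends[runs$values])
    merged <- segs[1, , drop = FALSE]
    if (nrow(segs) > 1) {
      for (i in 2:nrow(segs)) {
        if (segs$s[i] - merged$e[nrow(merged)] <= gap) {
          merged$e[nrow(merged)] <- segs$e[i]
        } else {
          merged <- rbind(merged, segs[i, ])
        }
      }
    }
    out[[ch]] <- tibble::tibble(chrom = ch, start = merged$s, end = merged$e)
  }
  dplyr::bind_rows(out)
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration: sum of the
# probabilities of all tables (same margins) no more likely than observed.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b
  k <- a + c
  n_tot <- a + b + c + d
  lo <- max(0, k - (n_tot - m1))
  hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, n_tot - m1, k)
  p_obs <- stats::dhyper(a, m1, n_tot - m1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Windows whose midpoint falls inside a truth domain.
windows_in_domains <- function(windows, domains) {
  mid <- floor((windows$start + windows$end) / 2)
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(mid + 1, mid + 1))
  gr_d <- GenomicRanges::GRanges(domains$chrom,
                                 IRanges::IRanges(domains$start + 1, domains$end))
  IRanges::overlapsAny(gr, gr_d)
}
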