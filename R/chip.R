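#' Tile a genome into fixed-width windows
#'
#' Consecutive, non-overlapping windows per chromosome. A terminal partial
#' window is kept when it is at least half the nominal width and dropped
#' otherwise.
#'
#' @param genome An `oomics_genome` (or a tibble with chrom, length).
#' @param width Window width in bp (default 10 kb).
#' @return Tibble (chrom, start, end), 0-based half-open, sorted.
#' @export
tile_windows <- function(genome, width = 10000) {
  if (width <= 0) abort("`width` must be positive")
  sizes <- if (inherits(genome, "oomics_genome")) genome$chrom_sizes else genome
  out <- lapply(seq_len(nrow(sizes)), function(i) {
    L <- sizes$length[i]
    n_full <- L %/% width
    rem <- L - n_full * width
    starts <- seq.int(0, by = width, length.out = n_full)
    ends <- starts + width
    if (rem >= width / 2) {
      starts <- c(starts, n_full * width)
      ends <- c(ends, L)
    }
    tibble::tibble(chrom = sizes$chrom[i], start = starts, end = ends)
  })
  dplyr::bind_rows(out)
}

#' Quantify windowed counts as RPKM and log2 RPKM
#'
#' RPKM = count / ((width / 1000) x (library_size / 1e6)); the log2 value
#' uses a pseudocount (default 2^-4) so that zero-count windows map to a
#' finite value well below any realistic enrichment threshold.
#'
#' @param counts Long tibble with chrom, start, end, sample, count (extra
#'   columns such as role are preserved).
#' @param library_size Named vector of per-sample library sizes; by
#'   default the per-sample sum of counts.
#' @param pseudocount Added to RPKM before the log2.
#' @return The input with rpkm and log2_rpkm columns appended.
#' @export
quantify_rpkm <- function(counts, library_size = NULL, pseudocount = 2^-4) {
  if (any(counts$count < 0)) abort("negative counts")
  if (is.null(library_size)) {
    library_size <- tapply(counts$count, counts$sample, sum)
  }
  if (any(library_size <= 0)) abort("library sizes must be positive")
  lib <- unname(library_size[counts$sample])
  width_kb <- (counts$end - counts$start) / 1000
  counts$rpkm <- counts$count / (width_kb * (lib / 1e6))
  counts$log2_rpkm <- log2(counts$rpkm + pseudocount)
  counts
}

#' Mask mapping-artifact windows from input libraries
#'
#' A window is masked when the mean input RPKM of at least one replicate
#' set exceeds the threshold (strict >). Mirrors the filter that removes
#' windows with RPKM > 6 in 10% input libraries.
#'
#' The absolute default of 6 presumes full-genome scale, where uniform
#' input background sits far below it (about 0.37 RPKM on mouse).
#' `rpkm_threshold = NULL` switches to a depth-adaptive rule — three
#' times the median per-set mean input RPKM — suitable for small
#' synthetic genomes whose background RPKM is itself large.
#'
#' @param input_quant Output of [quantify_rpkm()] restricted to input
#'   samples.
#' @param sample_sets Named character vector sample -> replicate set; by
#'   default the `replicate_set` column if present, else one set.
#' @param rpkm_threshold Strict threshold on the per-set mean RPKM, or
#'   NULL for the adaptive rule.
#' @return Tibble (chrom, start, end, artifact).
#' @export
mask_artifacts <- function(input_quant, sample_sets = NULL, rpkm_threshold = 6) {
  if (nrow(input_quant) == 0) abort("no input samples supplied")
  if (is.null(sample_sets)) {
    if ("replicate_set" %in% names(input_quant)) {
      ss <- dplyr::distinct(input_quant, .data$sample, .data$replicate_set)
      sample_sets <- stats::setNames(ss$replicate_set, ss$sample)
    } else {
      sample_sets <- stats::setNames(
        rep("set1", length(unique(input_quant$sample))),
        unique(input_quant$sample))
    }
  }
  input_quant$._set <- sample_sets[input_quant$sample]
  if (is.null(rpkm_threshold)) {
    rpkm_threshold <- 3 * stats::median(input_quant$rpkm)
    inform(sprintf("mask_artifacts: adaptive RPKM threshold %.3f", rpkm_threshold))
  }
  input_quant %>%
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$._set) %>%
    dplyr::summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop") %>%
    dplyr::group_by(.data$chrom, .data$start, .data$end) %>%
    dplyr::summarise(artifact = any(.data$mean_rpkm > rpkm_threshold),
                     .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Call enriched windows by a log2 RPKM threshold
#'
#' A window is called when its log2 RPKM strictly exceeds the threshold
#' and it is not masked as an artifact. The default threshold 2.5 is the
#' value used for mature (d25) GV-oocyte H3K9me2 at full genome scale;
#' desk-scale synthetic data need a depth-appropriate threshold (see the
#' methods vignette).
#'
#' @param quant Output of [quantify_rpkm()] for the reference sample; if
#'   several samples are present, `sample` must name one.
#' @param log2_threshold Strict threshold on log2 RPKM.
#' @param mask Optional tibble from [mask_artifacts()].
#' @param sample Sample to call on when `quant` holds several.
#' @return Tibble (chrom, start, end, log2_rpkm, called).
#' @export
call_enriched_windows <- function(quant, log2_threshold = 2.5, mask = NULL,
                                  sample = NULL) {
  if (!is.null(sample)) quant <- quant[quant$sample == sample, , drop = FALSE]
  if (length(unique(quant$sample)) > 1) {
    abort("several samples present; use `sample` to pick the reference")
  }
  out <- quant[, c("chrom", "start", "end", "log2_rpkm")]
  out$called <- out$log2_rpkm > log2_threshold
  if (!is.null(mask)) {
    out <- dplyr::left_join(out, mask, by = c("chrom", "start", "end"))
    out$artifact[is.na(out$artifact)] <- FALSE
    out$called <- out$called & !out$artifact
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Merge called windows into domains
#'
#' Consecutive called windows whose gap is at most `max_gap` bp are joined
#' into one domain spanning from the first window start to the last
#' window end; the gap is absorbed into the domain. The operation is
#' idempotent.
#'
#' @param windows Tibble of called windows (chrom, start, end), sorted by
#'   (chrom, start); an unsorted input is an error. A `log2_rpkm` column,
#'   if present, is averaged into a domain `score`.
#' @param max_gap Largest gap (bp) bridged between neighbouring windows.
#' @return Tibble (chrom, start, end, n_windows\[, score\]).
#' @export
merge_windows <- function(windows, max_gap = 10000) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer()))
  }
  if (!is_sorted_intervals(windows)) abort("windows must be sorted by (chrom, start)")
  merged <- merge_interval_runs(windows, max_gap = max_gap)
  names(merged)[names(merged) == "n_members"] <- "n_windows"
  if ("log2_rpkm" %in% names(windows)) {
    gr_d <- as_granges0(merged)
    gr_w <- as_granges0(windows)
    hits <- GenomicRanges::findOverlaps(gr_w, gr_d)
    sc <- tapply(windows$log2_rpkm[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), mean)
    merged$score <- NA_real_
    merged$score[as.integer(names(sc))] <- as.numeric(sc)
  }
  merged
}

#' Sample random domains as an empirical null
#'
#' Uniformly samples `n` windows without replacement from the supplied
#' (unmasked) windows and merges them with the same gap rule as the real
#' domains, yielding a size-matched random-domain background.
#'
#' @param windows Tibble of candidate windows (chrom, start, end).
#' @param n Number of windows to sample (<= rows of `windows`).
#' @param max_gap Merge gap in bp.
#' @param seed Integer seed, recorded in the result attributes.
#' @return Tibble of merged random domains.
#' @export
sample_random_domains <- function(windows, n, max_gap = 10000, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n > nrow(windows)) abort("`n` exceeds the number of available windows")
  picked <- with_seed(seed, sort(sample.int(nrow(windows), n)))
  out <- merge_windows(dplyr::arrange(windows[picked, , drop = FALSE],
                                      .data$chrom, .data$start),
                       max_gap = max_gap)
  attr(out, "seed") <- seed
  out
}

#' Composite signal profile across a region set (probe trend)
#'
#' Each region is rescaled to `interior_bins` bins, flanked on both sides
#' by fixed-width bins (`flank` bp in `flank_bin` steps). The per-bin
#' value is the mean signal of quantified windows overlapping the bin,
#' weighted by overlap length, averaged over regions. Regions shorter
#' than one bin per interior bin contribute their single mean to every
#' interior bin.
#'
#' @param regions Tibble (chrom, start, end); must be non-empty.
#' @param quant Output of [quantify_rpkm()] (any number of samples).
#' @param flank Flank size in bp on each side.
#' @param interior_bins Number of bins the region body is rescaled to.
#' @param flank_bin Width of each flank bin in bp.
#' @param value Column of `quant` to average (default "log2_rpkm").
#' @return Tibble of class `oomics_profile` (bin, zone, sample, signal);
#'   bins run left flank -> interior -> right flank.
#' @export
composite_profile <- function(regions, quant, flank = 5000, interior_bins = 20,
                              flank_bin = 1000, value = "log2_rpkm") {
  if (nrow(regions) == 0) abort("`regions` must be non-empty")
  n_flank <- as.integer(flank / flank_bin)
  n_bins <- interior_bins + 2L * n_flank

  bins <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    left <- seq(s - flank, s, by = flank_bin)
    right <- seq(e, e + flank, by = flank_bin)
    interior <- s + round((0:interior_bins) * (e - s) / interior_bins)
    starts <- c(left[-length(left)], interior[-length(interior)],
                right[-length(right)])
    ends <- c(left[-1], interior[-1], right[-1])
    tibble::tibble(region = i, bin = seq_len(n_bins),
                   chrom = regions$chrom[i],
                   start = starts, end = ends,
                   degenerate = ends <= starts)
  })
  bins <- dplyr::bind_rows(bins)
  ok <- bins[!bins$degenerate & bins$start >= 0, , drop = FALSE]

  win <- dplyr::distinct(quant, .data$chrom, .data$start, .data$end)
  win$._w <- seq_len(nrow(win))
  hits <- GenomicRanges::findOverlaps(as_granges0(ok), as_granges0(win))
  ov <- tibble::tibble(
    region = ok$region[S4Vectors::queryHits(hits)],
    bin = ok$bin[S4Vectors::queryHits(hits)],
    bs = ok$start[S4Vectors::queryHits(hits)],
    be = ok$end[S4Vectors::queryHits(hits)],
    ._w = win$._w[S4Vectors::subjectHits(hits)],
    ws = win$start[S4Vectors::subjectHits(hits)],
    we = win$end[S4Vectors::subjectHits(hits)]
  )
  ov$weight <- pmin(ov$be, ov$we) - pmax(ov$bs, ov$ws)

  qu <- quant
  qu <- dplyr::left_join(qu, win, by = c("chrom", "start", "end"))
  vals <- qu[, c("._w", "sample", value)]
  names(vals)[3] <- "signal"

  prof <- dplyr::inner_join(ov, vals, by = "._w",
                            relationship = "many-to-many") %>%
    dplyr::group_by(.data$region, .data$bin, .data$sample) %>%
    dplyr::summarise(signal = sum(.data$signal * .data$weight) /
                       sum(.data$weight), .groups = "drop")

  # degenerate regions: spread the region mean over all interior bins
  degen <- unique(bins$region[bins$degenerate])
  if (length(degen)) {
    reg_mean <- prof %>%
      dplyr::filter(.data$region %in% degen,
                    .data$bin > n_flank, .data$bin <= n_flank + interior_bins) %>%
      dplyr::group_by(.data$region, .data$sample) %>%
      dplyr::summarise(signal = mean(.data$signal), .groups = "drop")
    fill <- tidyr::crossing(reg_mean,
                            bin = (n_flank + 1L):(n_flank + interior_bins))
    prof <- dplyr::bind_rows(
      dplyr::anti_join(prof,
                       dplyr::distinct(fill, .data$region, .data$bin),
                       by = c("region", "bin")),
      fill[, names(prof)])
  }

  out <- prof %>%
    dplyr::group_by(.data$bin, .data$sample) %>%
    dplyr::summarise(signal = mean(.data$signal), .groups = "drop") %>%
    dplyr::mutate(zone = dplyr::case_when(
      .data$bin <= n_flank ~ "left_flank",
      .data$bin > n_flank + interior_bins ~ "right_flank",
      TRUE ~ "interior")) %>%
    dplyr::select("bin", "zone", "sample", "signal") %>%
    dplyr::arrange(.data$sample, .data$bin)
  class(out) <- c("oomics_profile", class(out))
  attr(out, "n_flank") <- n_flank
  attr(out, "interior_bins") <- interior_bins
  out
}

#' Classify promoters by expression level and CGI status
#'
#' Promoters are the 1-kb interval centred on the transcription start site
#' ([TSS - 500, TSS + 500)), strand-aware. Expression classes follow the
#' FPKM cuts used for oocyte transcripts: below 0.1 not expressed, 0.1 up
#' to (but excluding) 1 low, 1 and above high — boundaries assigned
#' upward.
#'
#' @param genes Tibble (gene_id, chrom, start, end, strand).
#' @param fpkm Named numeric vector of FPKM per gene, or tibble
#'   (gene_id, fpkm).
#' @param cgis Tibble of CGI intervals, or NULL to skip CGI status.
#' @return Tibble (gene_id, chrom, start, end, strand, fpkm,
#'   expression_class, cgi_promoter).
#' @export
classify_promoters <- function(genes, fpkm, cgis = NULL) {
  if (!"strand" %in% names(genes) || anyNA(genes$strand)) {
    abort("gene strand is required")
  }
  if (is.data.frame(fpkm)) fpkm <- stats::setNames(fpkm$fpkm, fpkm$gene_id)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  out <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = tss - 500, end = tss + 500, strand = genes$strand,
    fpkm = unname(fpkm[genes$gene_id]))
  out$expression_class <- dplyr::case_when(
    out$fpkm < 0.1 ~ "not_expressed",
    out$fpkm < 1 ~ "low",
    TRUE ~ "high")
  if (!is.null(cgis) && nrow(cgis)) {
    clip <- out
    clip$start <- pmax(clip$start, 0)
    out$cgi_promoter <- IRanges::overlapsAny(as_granges0(clip), as_granges0(cgis))
  } else {
    out$cgi_promoter <- FALSE
  }
  out
}
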