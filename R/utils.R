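#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr %>%
NULL

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# All coordinates in the package are 0-based half-open [start, end).
# GRanges is 1-based closed, so conversion adds 1 to start.
as_granges0 <- function(x, seqlengths = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    seqlengths = seqlengths
  )
}

check_intervals <- function(x, chrom_sizes = NULL, what = "intervals") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("%s must have columns chrom, start, end", what))
  }
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("%s: start >= end at row %d", what, bad[1]))
  }
  if (any(x$start < 0)) abort(sprintf("%s: negative start", what))
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[x$chrom]
    if (anyNA(lim)) abort(sprintf("%s: unknown chromosome", what))
    if (any(x$end > lim)) abort(sprintf("%s: interval exceeds chromosome bounds", what))
  }
  invisible(x)
}

is_sorted_intervals <- function(x) {
  all(unlist(lapply(split(x$start, x$chrom), function(s) !is.unsorted(s))))
}

# Merge sorted 0-based half-open intervals, joining neighbours whose gap
# (next start - previous end) is <= max_gap. Returns one row per merged run.
merge_interval_runs <- function(x, max_gap = 0) {
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  grp <- unlist(lapply(split(seq_len(nrow(x)), x$chrom)[unique(x$chrom)], function(idx) {
    s <- x$start[idx]
    e <- cummax(x$end[idx])
    new_run <- c(TRUE, s[-1] - e[-length(e)] > max_gap)
    cumsum(new_run)
  }), use.names = FALSE)
  x$._run <- paste(x$chrom, grp, sep = ".")
  out <- x %>%
    dplyr::group_by(.data$chrom, .data$._run) %>%
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_members = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::select("chrom", "start", "end", "n_members")
  out
}

# Sample n non-overlapping intervals of the given lengths on a genome,
# by rejection; used by the annotation generator.
place_intervals <- function(chrom_sizes, lengths, max_tries = 50L) {
  n <- length(lengths)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  chroms <- names(chrom_sizes)
  probs <- chrom_sizes / sum(chrom_sizes)
  placed <- vector("list", n)
  occupied <- lapply(chroms, function(.) cbind(numeric(0), numeric(0)))
  names(occupied) <- chroms
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = probs)
      len <- lengths[i]
      if (chrom_sizes[[ch]] <= len) next
      s <- sample.int(chrom_sizes[[ch]] - len, 1) - 1L
      e <- s + len
      occ <- occupied[[ch]]
      if (nrow(occ) == 0 || all(e <= occ[, 1] | s >= occ[, 2])) {
        occupied[[ch]] <- rbind(occ, c(s, e))
        placed[[i]] <- tibble::tibble(chrom = ch, start = s, end = e)
        break
      }
    }
  }
  dplyr::bind_rows(placed)
}

pct <- function(x) 100 * x
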