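#' Read a BED region file
#'
#' Three or more tab-separated columns, 0-based half-open; name and score
#' columns are preserved when present. Malformed rows are reported with
#' their line number.
#'
#' @param path File path.
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   bounds checking.
#' @return Sorted tibble (chrom, start, end\[, name, score\]).
#' @export
read_regions <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 columns",
                  which(n_col < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]))
  bad <- which(start >= end)
  if (length(bad)) abort(sprintf("malformed BED line %d: start >= end", bad[1]))
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (all(n_col >= 4)) out$name <- vapply(fields, `[[`, character(1), 4)
  if (all(n_col >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5)))
  }
  check_intervals(out, chrom_sizes, what = basename(path))
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write intervals as BED
#'
#' @param x Tibble (chrom, start, end\[, name, score\]); a `domain_id` or
#'   `direction` column is used as the BED name, a `score`/`mean_diff`
#'   column as the BED score.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name
          else if ("domain_id" %in% names(x)) x$domain_id
          else sprintf("region%05d", seq_len(nrow(x)))
  score <- if ("score" %in% names(x)) x$score
           else if ("mean_diff" %in% names(x)) x$mean_diff
           else rep(0, nrow(x))
  bed <- tibble::tibble(chrom = x$chrom,
                        start = format(x$start, scientific = FALSE, trim = TRUE),
                        end = format(x$end, scientific = FALSE, trim = TRUE),
                        name = name, score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-CpG coverage records
#'
#' Two dialects: `coverage6` is the 6-column bisulfite coverage format
#' (chrom, start \[1-based\], end, percent, meth_count, unmeth_count) whose
#' percent column, when inconsistent with the counts by more than 0.5
#' points, triggers a warning with the number of discrepant rows;
#' `synthetic4` is the package's own 4-column format (chrom, pos
#' \[0-based\], meth, unmeth).
#'
#' @param path File path.
#' @param dialect "coverage6" or "synthetic4".
#' @return Tibble (chrom, pos, meth, unmeth), pos 0-based.
#' @export
read_cpg_coverage <- function(path, dialect = c("coverage6", "synthetic4")) {
  dialect <- match.arg(dialect)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (dialect == "coverage6") {
    if (ncol(x) < 6) abort("coverage6 dialect needs 6 columns")
    out <- tibble::tibble(chrom = as.character(x[[1]]), pos = x[[2]] - 1,
                          meth = x[[5]], unmeth = x[[6]])
    expected <- 100 * out$meth / pmax(out$meth + out$unmeth, 1)
    n_bad <- sum(abs(x[[4]] - expected) > 0.5 & (out$meth + out$unmeth) > 0)
    if (n_bad > 0) {
      warn(sprintf("%d rows with percent inconsistent with counts (> 0.5 points)", n_bad))
    }
  } else {
    if (ncol(x) < 4) abort("synthetic4 dialect needs 4 columns")
    out <- tibble::tibble(chrom = as.character(x[[1]]), pos = x[[2]],
                          meth = x[[3]], unmeth = x[[4]])
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Write per-CpG coverage records
#'
#' @param x Tibble (chrom, pos, meth, unmeth), pos 0-based.
#' @param path Output path.
#' @param dialect Output dialect; see [read_cpg_coverage()].
#' @return `path`, invisibly.
#' @export
write_cpg_coverage <- function(x, path, dialect = c("synthetic4", "coverage6")) {
  dialect <- match.arg(dialect)
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  out <- if (dialect == "synthetic4") {
    data.frame(x$chrom, x$pos, x$meth, x$unmeth)
  } else {
    tot <- pmax(x$meth + x$unmeth, 1)
    data.frame(x$chrom, x$pos + 1, x$pos + 1,
               round(100 * x$meth / tot, 6), x$meth, x$unmeth)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a unit-by-sample count or value matrix
#'
#' TSV with the unit id in column 1 and one column per sample, with
#' header. Lines starting with '#' are treated as provenance comments.
#'
#' @param path File path.
#' @return Wide tibble.
#' @export
read_matrix_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname read_matrix_tsv
#' @param x Wide tibble (unit id first column).
#' @param header Optional provenance lines written as '#' comments.
#' @export
write_matrix_tsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Columns: sample, assay (chip / input / igg / bsseq / rnaseq /
#' proteome), group, and optionally file and replicate_set. Sample ids
#' must be unique; referenced files must exist.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample", "assay", "group")
  if (!all(required %in% names(x))) {
    abort(sprintf("sample sheet needs columns: %s", paste(required, collapse = ", ")))
  }
  if (anyDuplicated(x$sample)) abort("sample ids must be unique")
  valid <- c("chip", "input", "igg", "bsseq", "rnaseq", "proteome")
  if (!all(x$assay %in% valid)) abort("unknown assay in sample sheet")
  if ("file" %in% names(x)) {
    missing_files <- x$file[!is.na(x$file) & !file.exists(x$file)]
    if (length(missing_files)) {
      abort(sprintf("sample sheet references missing file: %s", missing_files[1]))
    }
  }
  x
}
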