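#' Simulate windowed ChIP-seq counts with planted broad domains
#'
#' Draws per-window read counts for ChIP and input libraries from a
#' multinomial over 10-kb windows. ChIP windows inside planted truth
#' domains carry `enrichment_fold` times the background weight; input
#' libraries are uniform except for an optional set of artifact windows
#' whose input weight is inflated, so the input-RPKM artifact mask has
#' something to find. Column sums equal the requested library sizes
#' exactly (reads are conserved).
#'
#' @param genome An `oomics_genome`.
#' @param truth_domains Tibble (chrom, start, end) of enriched domains,
#'   e.g. from [sample_truth_domains()].
#' @param enrichment_fold Fold enrichment of in-domain windows (>= 1).
#' @param n_reads_chip,n_reads_input Library sizes per replicate.
#' @param n_replicates Replicates per role.
#' @param window_width Window size in bp.
#' @param n_artifact_windows Number of windows given `artifact_fold` times
#'   the background weight in the input libraries.
#' @param artifact_fold Input-weight inflation of artifact windows.
#' @param seed Integer seed.
#' @return List of class `oomics_chip_sim` with `counts` (long tibble:
#'   chrom, start, end, sample, role, replicate_set, count), `windows`,
#'   and `truth` (`domains`, `artifact_windows`).
#' @export
simulate_chip <- function(genome, truth_domains, enrichment_fold = 6,
                          n_reads_chip = 1e6, n_reads_input = 1e6,
                          n_replicates = 2, window_width = 10000,
                          n_artifact_windows = 0, artifact_fold = 10,
                          seed) {
  if (missing(seed)) abort("`seed` is required")
  if (enrichment_fold < 1) abort("`enrichment_fold` must be >= 1")
  if (n_reads_chip <= 0 || n_reads_input <= 0) abort("read numbers must be positive")
  sizes <- stats::setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
  check_intervals(truth_domains, sizes, "truth_domains")

  windows <- tile_windows(genome, width = window_width)
  mid <- (windows$start + windows$end) / 2
  gr_mid <- GenomicRanges::GRanges(windows$chrom,
                                   IRanges::IRanges(floor(mid) + 1, floor(mid) + 1))
  in_domain <- IRanges::overlapsAny(gr_mid, as_granges0(truth_domains))

  with_seed(seed, {
    artifact_idx <- if (n_artifact_windows > 0) {
      sort(sample(which(!in_domain), n_artifact_windows))
    } else integer(0)

    w_chip <- ifelse(in_domain, enrichment_fold, 1)
    w_input <- rep(1, nrow(windows))
    w_input[artifact_idx] <- artifact_fold

    draw <- function(n_reads, w, label, role) {
      cnt <- as.integer(stats::rmultinom(1, size = n_reads, prob = w / sum(w)))
      tibble::tibble(windows, sample = label, role = role,
                     replicate_set = paste0(role, "_set1"), count = cnt)
    }
    counts <- dplyr::bind_rows(
      lapply(seq_len(n_replicates), function(r)
        draw(n_reads_chip, w_chip, sprintf("chip_rep%d", r), "chip")),
      lapply(seq_len(n_replicates), function(r)
        draw(n_reads_input, w_input, sprintf("input_rep%d", r), "input"))
    )
  })

  structure(list(
    counts = counts,
    windows = windows,
    truth = list(domains = truth_domains,
                 artifact_windows = windows[artifact_idx, , drop = FALSE]),
    params = list(enrichment_fold = enrichment_fold,
                  n_reads_chip = n_reads_chip, n_reads_input = n_reads_input,
                  n_replicates = n_replicates, window_width = window_width,
                  artifact_fold = artifact_fold, seed = seed)
  ), class = "oomics_chip_sim")
}

#' Pick tiles to carry a planted methylation shift
#'
#' @param tiles Tiles from [tile_by_cpg()].
#' @param n Number of effect tiles.
#' @param delta Shift in percentage points applied to the second group
#'   (recycled; positive = hypermethylated in group B).
#' @param seed Integer seed.
#' @return Tibble (tile_id, delta, direction).
#' @export
sample_effect_tiles <- function(tiles, n, delta = 30, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n > nrow(tiles)) abort("more effect tiles requested than tiles available")
  with_seed(seed, {
    idx <- sort(sample.int(nrow(tiles), n))
    tibble::tibble(tile_id = tiles$tile_id[idx],
                   delta = rep_len(delta, n),
                   direction = ifelse(rep_len(delta, n) > 0, "hyper", "hypo"))
  })
}

#' Simulate replicate bisulfite coverage with group-level shifts
#'
#' Per replicate and CpG, coverage is Poisson(`coverage_mean`) and the
#' methylated count is binomial with a per-CpG success probability drawn
#' from a beta distribution parameterized by the group mean m and
#' dispersion phi (a = m(1-phi)/phi, b = (1-m)(1-phi)/phi); phi = 0
#' degenerates to a pure binomial. Effect tiles shift the second group's
#' mean by `delta` percentage points, clipped to \[0, 100\] (a warning is
#' raised when clipping occurs).
#'
#' @param genome An `oomics_genome`.
#' @param group_means Named length-2 vector of % methylation per group.
#' @param effect_tiles Tibble from [sample_effect_tiles()], or NULL.
#' @param coverage_mean Mean per-CpG read coverage.
#' @param beta_dispersion Beta dispersion phi in \[0, 1).
#' @param n_replicates Replicates per group.
#' @param tile_cpg CpGs per tile used to lay out effect tiles.
#' @param seed Integer seed.
#' @return List of class `oomics_bs_sim`: `cov` (long tibble chrom, pos,
#'   sample, group, meth, unmeth), `tiles`, `truth`.
#' @export
simulate_bisulfite <- function(genome, group_means = c(control = 70, cko = 70),
                               effect_tiles = NULL, coverage_mean = 30,
                               beta_dispersion = 0.02, n_replicates = 2,
                               tile_cpg = 100, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (any(group_means < 0 | group_means > 100)) abort("group means must be in [0, 100]")
  if (beta_dispersion < 0 || beta_dispersion >= 1) abort("`beta_dispersion` must be in [0, 1)")
  if (length(group_means) != 2 || is.null(names(group_means))) {
    abort("`group_means` must be a named vector of two groups")
  }

  tiles <- tile_by_cpg(genome$cpg, n = tile_cpg)
  cpg <- genome$cpg
  # map CpGs onto tiles (trailing CpGs beyond the last full tile get NA)
  cpg$tile_id <- assign_cpg_tiles(cpg, tiles)

  g_names <- names(group_means)
  base_mean <- stats::setNames(group_means / 100, g_names)

  m_mat <- matrix(rep(base_mean, each = nrow(cpg)), ncol = 2,
                  dimnames = list(NULL, g_names))
  if (!is.null(effect_tiles) && nrow(effect_tiles)) {
    missing_tiles <- setdiff(effect_tiles$tile_id, tiles$tile_id)
    if (length(missing_tiles)) abort("effect tile not present in tiling")
    shift <- stats::setNames(effect_tiles$delta, effect_tiles$tile_id)
    hit <- !is.na(cpg$tile_id) & cpg$tile_id %in% names(shift)
    target <- m_mat[, 2] ; target[hit] <- target[hit] + shift[cpg$tile_id[hit]] / 100
    if (any(target < 0 | target > 1)) {
      warn("planted effect pushes group mean outside [0, 100]; clipping")
      target <- pmin(pmax(target, 0), 1)
    }
    m_mat[, 2] <- target
  }

  with_seed(seed, {
    out <- vector("list", 2 * n_replicates)
    k <- 0
    for (g in 1:2) {
      for (r in seq_len(n_replicates)) {
        k <- k + 1
        m <- m_mat[, g]
        cov <- stats::rpois(nrow(cpg), coverage_mean)
        if (beta_dispersion > 0) {
          a <- m * (1 - beta_dispersion) / beta_dispersion
          b <- (1 - m) * (1 - beta_dispersion) / beta_dispersion
          p <- ifelse(m <= 0, 0, ifelse(m >= 1, 1, stats::rbeta(nrow(cpg), pmax(a, 1e-12), pmax(b, 1e-12))))
        } else {
          p <- m
        }
        meth <- stats::rbinom(nrow(cpg), cov, p)
        out[[k]] <- tibble::tibble(
          chrom = cpg$chrom, pos = cpg$pos,
          sample = sprintf("%s_rep%d", g_names[g], r),
          group = g_names[g], meth = meth, unmeth = cov - meth)
      }
    }
    cov_tbl <- dplyr::bind_rows(out)
  })

  structure(list(
    cov = cov_tbl, tiles = tiles,
    truth = list(effect_tiles = effect_tiles, group_means = group_means),
    params = list(coverage_mean = coverage_mean,
                  beta_dispersion = beta_dispersion,
                  n_replicates = n_replicates, seed = seed)
  ), class = "oomics_bs_sim")
}

#' Draw a differential-expression truth set
#'
#' Default up:down ratio is 90:10, mirroring the strong up-regulation bias
#' seen when a transcriptional repressor is lost.
#'
#' @param genome An `oomics_genome`.
#' @param n_de Number of differential genes.
#' @param prop_up Fraction of differential genes that are up-regulated.
#' @param lfc Absolute log2 fold change planted (recycled).
#' @param seed Integer seed.
#' @return Tibble (gene_id, log2fc).
#' @export
sample_de_truth <- function(genome, n_de = 50, prop_up = 0.9, lfc = 2, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_de > nrow(genome$genes)) abort("more DE genes requested than genes present")
  with_seed(seed, {
    ids <- sample(genome$genes$gene_id, n_de)
    n_up <- round(n_de * prop_up)
    sign <- c(rep(1, n_up), rep(-1, n_de - n_up))
    tibble::tibble(gene_id = ids, log2fc = sign * rep_len(abs(lfc), n_de))
  })
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Counts are NB with mean `size_factor x baseline x 2^log2FC(group)` and
#' the given dispersion; dispersion 0 degenerates to Poisson. Size factors
#' are the library sizes centred to geometric mean 1.
#'
#' @param genome An `oomics_genome`.
#' @param baseline_means Named per-gene baseline means; defaults to
#'   log-normal draws (meanlog log(100), sdlog 1) for every gene.
#' @param de_truth Tibble (gene_id, log2fc) of planted effects
#'   (e.g. [sample_de_truth()]); applied to the second group.
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2).
#' @param library_sizes Named numeric vector, one entry per sample.
#' @param groups Named character vector sample -> group (two groups); by
#'   default inferred from sample names of `library_sizes` as
#'   `<group>_rep<k>`.
#' @param seed Integer seed.
#' @return List of class `oomics_rna_sim`: `counts` (wide tibble, gene_id
#'   first column), `groups`, `truth`.
#' @export
simulate_rnaseq <- function(genome, baseline_means = NULL, de_truth = NULL,
                            dispersion = 0.05,
                            library_sizes = stats::setNames(
                              rep(2e6, 8),
                              c(sprintf("control_rep%d", 1:4),
                                sprintf("cko_rep%d", 1:4))),
                            groups = NULL, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  gene_ids <- genome$genes$gene_id
  if (is.null(groups)) {
    groups <- sub("_rep[0-9]+$", "", names(library_sizes))
    names(groups) <- names(library_sizes)
  }
  if (length(unique(groups)) != 2) abort("exactly two groups are required")
  if (!is.null(de_truth) && !all(de_truth$gene_id %in% gene_ids)) {
    abort("de_truth refers to genes absent from the genome")
  }

  with_seed(seed, {
    if (is.null(baseline_means)) {
      baseline_means <- stats::setNames(
        stats::rlnorm(length(gene_ids), log(100), 1), gene_ids)
    }
    lfc <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
    if (!is.null(de_truth)) lfc[de_truth$gene_id] <- de_truth$log2fc

    sf <- library_sizes / exp(mean(log(library_sizes)))
    grp_levels <- unique(unname(groups))
    mat <- vapply(names(library_sizes), function(s) {
      mult <- if (groups[[s]] == grp_levels[2]) 2^lfc else rep(1, length(lfc))
      mu <- sf[[s]] * baseline_means[gene_ids] * mult
      if (dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
    }, numeric(length(gene_ids)))
    counts <- tibble::tibble(gene_id = gene_ids,
                             tibble::as_tibble(mat))
  })

  structure(list(
    counts = counts, groups = groups,
    truth = list(de = de_truth, baseline_means = baseline_means),
    params = list(dispersion = dispersion, library_sizes = library_sizes,
                  seed = seed)
  ), class = "oomics_rna_sim")
}

#' Simulate a TMT-style protein log2-intensity matrix coupled to transcripts
#'
#' Protein log2 fold changes are generated so that their expected Spearman
#' correlation with the matched transcript log2 fold changes equals
#' `coupling_rho`: both margins are mapped to normal scores and combined
#' with Pearson correlation r = 2 sin(pi * rho / 6), the exact
#' bivariate-normal relation between Pearson and Spearman correlation.
#' Replicate intensities are the group mean plus Gaussian noise.
#'
#' @param transcript_log2fc Named numeric vector of transcript log2 fold
#'   changes (names are gene ids).
#' @param coupling_rho Target Spearman correlation in \[0, 1\].
#' @param n_proteins Number of proteins (must not exceed the number of
#'   transcripts supplied).
#' @param noise_sd Replicate-level Gaussian noise SD (log2 units).
#' @param n_replicates Replicates per group.
#' @param lfc_sd SD of the protein log2FC marginal.
#' @param seed Integer seed.
#' @return List of class `oomics_prot_sim`: `matrix` (wide tibble,
#'   protein_id first column), `groups`, `truth` (protein_id, gene_id,
#'   log2fc).
#' @export
simulate_proteome <- function(transcript_log2fc, coupling_rho = 0.43,
                              n_proteins = length(transcript_log2fc),
                              noise_sd = 0.1, n_replicates = 5,
                              lfc_sd = 0.3, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (coupling_rho < 0 || coupling_rho > 1) abort("`coupling_rho` must be in [0, 1]")
  if (n_proteins > length(transcript_log2fc)) {
    abort("`n_proteins` exceeds the number of matched transcripts")
  }

  with_seed(seed, {
    genes <- sample(names(transcript_log2fc), n_proteins)
    t_lfc <- transcript_log2fc[genes]
    n <- length(t_lfc)
    z_t <- stats::qnorm(rank(t_lfc, ties.method = "average") / (n + 1))
    r <- 2 * sin(pi * coupling_rho / 6)
    z_p <- r * z_t + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
    p_lfc <- lfc_sd * z_p

    base <- stats::rnorm(n, 10, 1.5)
    g_names <- c("control", "cko")
    samples <- c(sprintf("control_rep%d", seq_len(n_replicates)),
                 sprintf("cko_rep%d", seq_len(n_replicates)))
    grp <- stats::setNames(rep(g_names, each = n_replicates), samples)
    mat <- vapply(samples, function(s) {
      mu <- base + (if (grp[[s]] == "cko") p_lfc / 2 else -p_lfc / 2)
      mu + stats::rnorm(n, 0, noise_sd)
    }, numeric(n))
    protein_ids <- sprintf("prot%05d", seq_len(n))
    out_mat <- tibble::tibble(protein_id = protein_ids, tibble::as_tibble(mat))
    truth <- tibble::tibble(protein_id = protein_ids, gene_id = genes,
                            log2fc = unname(p_lfc))
  })

  structure(list(
    matrix = out_mat, groups = grp, truth = truth,
    params = list(coupling_rho = coupling_rho, noise_sd = noise_sd,
                  n_replicates = n_replicates, lfc_sd = lfc_sd, seed = seed)
  ), class = "oomics_prot_sim")
}
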