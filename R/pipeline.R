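#' Default end-to-end configuration
#'
#' Desk-scale study conditions: a 3 x 5 Mb genome, fold-6 H3K9me2 domains
#' at 1e6 reads, 30x bisulfite coverage with 2 replicates per genotype,
#' negative-binomial RNA counts with a 90:10 up:down truth, and a
#' proteome coupled to the transcriptome at Spearman rho 0.43.
#'
#' @param scale Multiplier applied to chromosome lengths.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_config <- function(scale = 1) {
  list(
    genome = list(chrom_sizes = list(chr1 = 5e6 * scale, chr2 = 5e6 * scale,
                                     chr3 = 5e6 * scale),
                  n_genes = 300, n_cgis = 150, n_ervs = 100),
    chip = list(n_domains = 30, domain_width = 50000, enrichment_fold = 6,
                n_reads = 1e6, n_replicates = 2, n_artifact_windows = 20,
                artifact_fold = 10, window_width = 10000,
                log2_threshold = NULL, max_gap = 10000,
                random_fraction = 0.128, rpkm_mask_threshold = NULL),
    bsseq = list(group_means = list(control = 70, cko = 70),
                 n_effect_tiles = 40, delta = 30, coverage_mean = 30,
                 beta_dispersion = 0.02, n_replicates = 2,
                 alpha = 0.05, min_diff = 20),
    rnaseq = list(n_de = 50, prop_up = 0.9, lfc = 2, dispersion = 0.05,
                  library_size = 2e6, n_per_group = 4,
                  lfc_threshold = 1.5, alpha = 0.05),
    proteome = list(coupling_rho = 0.43, noise_sd = 0.1, n_replicates = 5,
                    p_threshold = 0.05, lfc_threshold = 0.3),
    integrate = TRUE
  )
}

#' Run the full synthetic multi-omics pipeline
#'
#' Generates a genome and all requested omic layers, runs every analysis
#' stage in dependency order, and writes the artifacts (BED domains, TSV
#' tables, JSON truth manifest and provenance) under `outdir`. Removing a
#' block (e.g. `config$bsseq <- NULL`) skips that stage and everything
#' that needs it. The run is a pure function of (config, seed): a rerun
#' with the same inputs reproduces every output byte for byte.
#'
#' @param config Nested list as from [default_config()], or the path of
#'   a YAML file with the same structure.
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (missing(outdir)) abort("`outdir` is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)
  version <- as.character(utils::packageVersion("oomics"))
  prov <- sprintf("oomics %s; config_hash=%s; seed=%d", version, cfg_hash, seed)
  stage_seed <- function(k) as.integer((seed + 7919L * k) %% .Machine$integer.max)
  artifacts <- list()
  logs <- character()
  log_line <- function(...) {
    msg <- sprintf(...)
    inform(msg)
    logs <<- c(logs, msg)
  }
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    artifacts[[name]] <<- path
    path
  }

  gcfg <- config$genome
  genome <- make_genome(
    chrom_sizes = unlist(gcfg$chrom_sizes),
    n_genes = gcfg$n_genes, n_cgis = gcfg$n_cgis, n_ervs = gcfg$n_ervs,
    seed = stage_seed(1))
  emit("genes.bed", function(p) write_regions(
    dplyr::mutate(genome$genes, name = .data$gene_id), p))
  emit("cgis.bed", function(p) write_regions(genome$cgis, p))
  emit("ervs.bed", function(p) write_regions(
    dplyr::mutate(genome$ervs, name = .data$erv_id), p))
  truth <- list()
  rna <- NULL; de_res <- NULL; domains <- NULL; random_domains <- NULL
  dmrs <- NULL; prot_res <- NULL; prot_sim <- NULL

  if (!is.null(config$chip)) {
    cc <- config$chip
    truth_domains <- sample_truth_domains(
      genome, n_domains = cc$n_domains, width = cc$domain_width,
      window_width = cc$window_width, seed = stage_seed(2))
    sim <- simulate_chip(
      genome, truth_domains, enrichment_fold = cc$enrichment_fold,
      n_reads_chip = cc$n_reads, n_reads_input = cc$n_reads,
      n_replicates = cc$n_replicates,
      n_artifact_windows = cc$n_artifact_windows,
      artifact_fold = cc$artifact_fold,
      window_width = cc$window_width, seed = stage_seed(3))
    quant <- quantify_rpkm(sim$counts)
    mask <- mask_artifacts(quant[quant$role == "input", ],
                           rpkm_threshold = cc$rpkm_mask_threshold)
    log_line("chip: %d windows masked as artifacts", sum(mask$artifact))
    thr <- cc$log2_threshold %||%
      (stats::median(quant$log2_rpkm[quant$sample == "chip_rep1"]) +
         log2(cc$enrichment_fold) / 2)
    called <- call_enriched_windows(quant, log2_threshold = thr,
                                    mask = mask, sample = "chip_rep1")
    log_line("chip: %d/%d windows enriched at log2RPKM > %.3f",
             sum(called$called), nrow(called), thr)
    domains <- merge_windows(called[called$called, ], max_gap = cc$max_gap)
    unmasked <- called[!called$artifact, c("chrom", "start", "end")]
    random_domains <- sample_random_domains(
      unmasked, n = round(cc$random_fraction * nrow(unmasked)),
      max_gap = cc$max_gap, seed = stage_seed(4))
    profile <- composite_profile(domains, quant)
    emit("chip_windows.tsv", function(p) write_matrix_tsv(quant, p, prov))
    emit("h3k9me2_domains.bed", function(p) write_regions(domains, p))
    emit("random_domains.bed", function(p) write_regions(random_domains, p))
    emit("chip_profile.tsv", function(p) write_matrix_tsv(profile, p, prov))
    truth$chip_domains <- truth_domains
    truth$artifact_windows <- sim$truth$artifact_windows
  }

  if (!is.null(config$bsseq)) {
    bc <- config$bsseq
    tiles <- tile_by_cpg(genome$cpg)
    effect <- sample_effect_tiles(tiles, n = bc$n_effect_tiles,
                                  delta = bc$delta, seed = stage_seed(5))
    bs <- simulate_bisulfite(
      genome, group_means = unlist(bc$group_means), effect_tiles = effect,
      coverage_mean = bc$coverage_mean,
      beta_dispersion = bc$beta_dispersion,
      n_replicates = bc$n_replicates, seed = stage_seed(6))
    for (s in unique(bs$cov$sample)) {
      emit(sprintf("cov_%s.tsv", s), function(p)
        write_cpg_coverage(bs$cov[bs$cov$sample == s, ], p))
    }
    agg <- aggregate_tiles(bs$cov, tiles)
    kept <- coverage_filter(agg, min_obs = 10)
    log_line("bsseq: %d/%d tiles pass coverage",
             length(unique(kept$tile_id)), length(unique(agg$tile_id)))
    res <- dmr_test(bs$cov, kept, group_a = names(bc$group_means)[1],
                    group_b = names(bc$group_means)[2])
    dmrs <- call_dmrs(res, alpha = bc$alpha, min_diff = bc$min_diff)
    log_line("bsseq: %d DMRs called", sum(dmrs$call))
    dmds <- merge_dmrs(dmrs)
    emit("dmr_results.tsv", function(p) write_matrix_tsv(
      tibble::as_tibble(dmrs), p, prov))
    if (sum(dmrs$call)) {
      emit("dmrs.bed", function(p) write_regions(
        dplyr::mutate(dmrs[dmrs$call, ],
                      name = .data$tile_id, score = .data$diff), p))
    }
    if (nrow(dmds)) emit("dmds.bed", function(p) write_regions(dmds, p))
    truth$effect_tiles <- effect
  }

  if (!is.null(config$rnaseq)) {
    rc <- config$rnaseq
    de_truth <- sample_de_truth(genome, n_de = rc$n_de, prop_up = rc$prop_up,
                                lfc = rc$lfc, seed = stage_seed(7))
    lib <- stats::setNames(
      rep(rc$library_size, 2 * rc$n_per_group),
      c(sprintf("control_rep%d", seq_len(rc$n_per_group)),
        sprintf("cko_rep%d", seq_len(rc$n_per_group))))
    rna <- simulate_rnaseq(genome, de_truth = de_truth,
                           dispersion = rc$dispersion,
                           library_sizes = lib, seed = stage_seed(8))
    de_res <- nb_wald_test(rna$counts, rna$groups, reference = "control")
    de_res <- call_degs(de_res, lfc = rc$lfc_threshold, alpha = rc$alpha)
    log_line("rnaseq: %d up, %d down of %d genes",
             sum(de_res$call == "up"), sum(de_res$call == "down"), nrow(de_res))
    emit("rna_counts.tsv", function(p) write_matrix_tsv(rna$counts, p, prov))
    emit("de_results.tsv", function(p) write_matrix_tsv(
      tibble::as_tibble(de_res), p, prov))
    truth$de_genes <- de_truth
  }

  if (!is.null(config$proteome) && !is.null(de_res)) {
    pc <- config$proteome
    t_lfc <- stats::setNames(de_res$log2fc, de_res$gene_id)
    prot_sim <- simulate_proteome(t_lfc, coupling_rho = pc$coupling_rho,
                                  noise_sd = pc$noise_sd,
                                  n_replicates = pc$n_replicates,
                                  seed = stage_seed(9))
    norm <- normalize_median(prot_sim$matrix)
    prot_res <- moderated_t(norm, prot_sim$groups, reference = "control")
    prot_res <- call_diff_proteins(prot_res, p = pc$p_threshold,
                                   lfc = pc$lfc_threshold)
    log_line("proteome: %d up, %d down of %d proteins",
             sum(prot_res$call == "up"), sum(prot_res$call == "down"),
             nrow(prot_res))
    emit("protein_matrix.tsv", function(p) write_matrix_tsv(prot_sim$matrix, p, prov))
    emit("protein_de.tsv", function(p) write_matrix_tsv(
      tibble::as_tibble(prot_res), p, prov))
    truth$protein_coupling <- pc$coupling_rho
  }

  if (isTRUE(config$integrate)) {
    integ <- list()
    if (!is.null(dmrs) && !is.null(domains) && sum(dmrs$call) > 0 &&
        nrow(random_domains) > 0) {
      q <- dmrs[dmrs$call, c("chrom", "start", "end")]
      integ$dmr_vs_h3k9me2 <- enrichment_test(
        query_hits = round(overlap_fraction(q, domains) * nrow(q)),
        query_n = nrow(q),
        bg_hits = round(overlap_fraction(
          random_domains[, c("chrom", "start", "end")], domains) *
            nrow(random_domains)),
        bg_n = nrow(random_domains))
    }
    if (!is.null(prot_res) && !is.null(de_res)) {
      gene_of <- stats::setNames(prot_sim$truth$gene_id,
                                 prot_sim$truth$protein_id)
      up <- unname(gene_of[prot_res$protein_id[prot_res$call == "up"]])
      down <- unname(gene_of[prot_res$protein_id[prot_res$call == "down"]])
      ranked <- stats::setNames(de_res$log2fc, de_res$gene_id)
      ranked <- ranked[unname(gene_of)]
      paired <- stats::setNames(prot_res$log2fc, unname(gene_of[prot_res$protein_id]))
      bc_res <- barcode_enrichment(ranked,
                                   up_set = intersect(up, names(ranked)),
                                   down_set = intersect(down, names(ranked)),
                                   paired = paired)
      integ$barcode_tests <- bc_res$tests
      integ$transcript_protein_rho <- bc_res$correlation
      emit("barcode_worm.tsv", function(p) write_matrix_tsv(bc_res$worm, p, prov))
    }
    if (length(integ)) {
      emit("integration.json", function(p) jsonlite::write_json(
        integ, p, auto_unbox = TRUE, digits = 10, pretty = TRUE))
    }
  }

  emit("truth.json", function(p) jsonlite::write_json(
    truth, p, auto_unbox = TRUE, digits = 10, pretty = TRUE))
  emit("manifest.json", function(p) jsonlite::write_json(
    list(version = version, config_hash = cfg_hash, seed = seed,
         artifacts = sort(names(artifacts))),
    p, auto_unbox = TRUE, pretty = TRUE))
  emit("pipeline.log", function(p) writeLines(c(prov, logs), p))

  invisible(artifacts)
}
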