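#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one place, named, with
#' the study defaults: the 2-CPM (mRNA) / 1-CPM (miRNA) in >= 5 samples
#' expression filters; |r| > 0.98 with BH FDR < 0.02 for the all-sample
#' network; rewiring thresholds 0.99 / 0.1 band / 1.95 gap with 5000
#' outcome-label randomizations; |r| > 0.85 cross-layer selection with 5000
#' identity shuffles; consensus p <= 0.03 with 10,000 reshuffles and
#' leave-one-out retention; enrichment FDR < 0.10; panel FDR < 0.03 and a
#' 2000-seed random-forest sweep.
#'
#' @param input list of input paths (`mrna`, `mirna`, `samples`,
#'   `annotation`, optional `interactions`, `gene_sets`), or `NULL` when
#'   `simulate` is given.
#' @param simulate optional [simulation_spec()] used instead of file input.
#' @param min_cpm_mrna,min_cpm_mirna,min_samples expression filter.
#' @param coexpr_min_abs_r,coexpr_max_fdr all-sample edge selection.
#' @param rewire_inverted_gap,rewire_present_abs_r,rewire_absent_band
#'   rewiring thresholds.
#' @param n_perm_rewire,n_perm_cross,n_perm_de permutation counts.
#' @param cross_min_abs_r cross-layer |r| selection threshold.
#' @param de_p_cut consensus nominal p cut-off.
#' @param enrich_fdr enrichment significance threshold (reporting only).
#' @param enrich_n_samplings null draws per term.
#' @param panel_fdr year-adjusted panel BH FDR threshold.
#' @param n_runs_sweep seeds in the prediction sweep.
#' @param seed master seed; stage streams are derived from it.
#' @param stages character vector of stages to run, in order, from
#'   `filter`, `coexpr`, `rewire`, `mirna`, `de`, `enrich`, `predict`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            min_cpm_mrna = 2, min_cpm_mirna = 1, min_samples = 5,
                            coexpr_min_abs_r = 0.98, coexpr_max_fdr = 0.02,
                            rewire_inverted_gap = 1.95,
                            rewire_present_abs_r = 0.99,
                            rewire_absent_band = 0.1,
                            n_perm_rewire = 5000, n_perm_cross = 5000,
                            n_perm_de = 10000,
                            cross_min_abs_r = 0.85,
                            de_p_cut = 0.03,
                            enrich_fdr = 0.10, enrich_n_samplings = 10000,
                            panel_fdr = 0.03, n_runs_sweep = 2000,
                            seed = 1,
                            stages = c("filter", "coexpr", "rewire", "mirna",
                                       "de", "enrich", "predict")) {
  cfg <- as.list(environment())
  stopifnot(de_p_cut > 0, de_p_cut < 1, coexpr_min_abs_r > 0,
            coexpr_min_abs_r <= 1, cross_min_abs_r > 0, cross_min_abs_r <= 1)
  rewire_thresholds(rewire_inverted_gap, rewire_present_abs_r,
                    rewire_absent_band)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- simulate_dataset(cfg$simulate)
    return(list(counts_mrna = sim$counts_mrna, counts_mirna = sim$counts_mirna,
                samples = sim$samples, annotation = sim$annotation,
                interactions = NULL, gene_sets = NULL, truth = sim$truth))
  }
  inp <- cfg$input
  if (is.null(inp)) stop("config needs either input paths or a simulation spec")
  list(counts_mrna = read_counts(inp$mrna, layer = "mRNA"),
       counts_mirna = if (!is.null(inp$mirna)) read_counts(inp$mirna, "miRNA"),
       samples = read_sample_table(inp$samples),
       annotation = read_annotation(inp$annotation),
       interactions = if (!is.null(inp$interactions)) read_interactions(inp$interactions),
       gene_sets = if (!is.null(inp$gene_sets)) read_gene_sets(inp$gene_sets),
       truth = NULL)
}

write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Run the full pipeline
#'
#' Executes the toggled stages in order — expression filtering, all-sample
#' coexpression, differential-coexpression rewiring with eFDR, miRNA:mRNA
#' integration, consensus differential expression, enrichment, cross-year
#' prediction — writing each stage's tables under `out_dir` together with a
#' run manifest (configuration, derived stage seeds, package version). A
#' rerun with the same configuration and seed reproduces the outputs
#' byte-identically.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @return named list of stage results, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- setNames(derive_seeds(cfg$seed, 5),
                    c("rewire", "cross", "de", "enrich", "sweep"))
  dat <- load_inputs(cfg)
  res <- list()
  filter_report <- list()
  year2 <- dat$samples$sample_id[dat$samples$year == max(dat$samples$year)]
  focal_samples <- dat$samples[dat$samples$sample_id %in% year2, , drop = FALSE]

  run_stage <- function(name) name %in% cfg$stages

  ## --- filter ------------------------------------------------------------
  if (run_stage("filter")) {
    filt <- function(counts, min_cpm, biotype) {
      cpm_raw <- compute_cpm(counts)
      kept <- filter_expressed(counts, cpm_raw, min_cpm, cfg$min_samples)
      filter_report[[biotype]] <<- attr(kept, "filter_report")
      sub <- subset_biotype(kept, dat$annotation, biotype)
      filter_report[[paste0(biotype, "_biotype")]] <<- attr(sub, "filter_report")
      sub
    }
    res$mrna <- filt(dat$counts_mrna, cfg$min_cpm_mrna, "protein_coding")
    res$mirna <- if (!is.null(dat$counts_mirna))
      filt(dat$counts_mirna, cfg$min_cpm_mirna, "miRNA")
    write_matrix_tsv(res$mrna, file.path(out_dir, "filtered_mrna.tsv"))
    if (!is.null(res$mirna))
      write_matrix_tsv(res$mirna, file.path(out_dir, "filtered_mirna.tsv"))
    write_json(filter_report, file.path(out_dir, "filter_report.json"))
  } else stop("the filter stage is required by all downstream stages")

  ## log2(CPM + 1) on the focal cohort, full-library scaling
  lib_mrna <- library_sizes(dat$counts_mrna)
  em_mrna <- compute_cpm(res$mrna[, year2, drop = FALSE], log = TRUE,
                         lib_sizes = lib_mrna)
  em_mirna <- NULL
  if (!is.null(res$mirna) && nrow(res$mirna))
    em_mirna <- compute_cpm(res$mirna[, year2, drop = FALSE], log = TRUE,
                            lib_sizes = library_sizes(dat$counts_mirna))
  th <- rewire_thresholds(cfg$rewire_inverted_gap, cfg$rewire_present_abs_r,
                          cfg$rewire_absent_band)

  ## --- coexpr ------------------------------------------------------------
  if (run_stage("coexpr")) {
    net <- coexpression_network(res$mrna[, year2, drop = FALSE],
                                cfg$coexpr_min_abs_r, cfg$coexpr_max_fdr,
                                lib_sizes = lib_mrna)
    res$coexpr <- net
    write.table(net$selected, file.path(out_dir, "coexpression_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- rewire ------------------------------------------------------------
  if (run_stage("rewire")) {
    gct <- groupwise_correlation(em_mrna, focal_samples)
    rew <- consensus_rewired_edges(gct, th)
    ef <- efdr_rewiring(em_mrna, focal_samples, th,
                        n_randomizations = cfg$n_perm_rewire,
                        seed = seeds[["rewire"]])
    res$rewire <- list(edges = rew$edges, discordant = rew$discordant, efdr = ef)
    write.table(rew$edges, file.path(out_dir, "rewired_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_json(list(pooled = ef$pooled, per_class = ef$per_class),
               file.path(out_dir, "rewire_efdr.json"))
  }

  ## --- mirna -------------------------------------------------------------
  if (run_stage("mirna") && !is.null(em_mirna) && nrow(em_mirna)) {
    cc <- cross_correlation(em_mirna, em_mrna)
    sel <- select_cross_layer(cc, cfg$cross_min_abs_r)
    ef <- efdr_cross_layer(em_mirna, em_mrna, cfg$cross_min_abs_r,
                           n_randomizations = cfg$n_perm_cross,
                           seed = seeds[["cross"]])
    rewx <- cross_layer_rewiring(em_mirna, em_mrna, focal_samples, th)
    if (!is.null(dat$interactions))
      sel <- overlay_interactions(sel, dat$interactions)
    res$mirna_integration <- list(selected = sel, efdr = ef,
                                  rewired = rewx$edges)
    write.table(sel, file.path(out_dir, "cross_layer_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rewx$edges, file.path(out_dir, "cross_layer_rewired.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_json(ef[c("threshold", "observed_exceedances",
                    "mean_scrambled_exceedances", "n_randomizations", "efdr")],
               file.path(out_dir, "cross_layer_efdr.json"))
  }

  ## --- de ----------------------------------------------------------------
  if (run_stage("de")) {
    contrasts <- list(c("AI_PREG", "NON_PREG"), c("NB_PREG", "NON_PREG"))
    res$de <- list()
    for (ct in contrasts) {
      if (!all(ct %in% focal_samples$outcome)) next
      nm <- paste(ct, collapse = "_vs_")
      de <- de_analysis(res$mrna[, year2, drop = FALSE], focal_samples,
                        focal = ct[1], reference = ct[2],
                        p_cut = cfg$de_p_cut,
                        n_randomizations = cfg$n_perm_de,
                        seed = seeds[["de"]])
      res$de[[nm]] <- de
      write.table(de$table, file.path(out_dir, paste0("de_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## --- enrich ------------------------------------------------------------
  if (run_stage("enrich") && !is.null(dat$gene_sets)) {
    if (is.null(res$de) || !length(res$de))
      stop("enrich stage needs the de stage")
    de1 <- res$de[[1]]$table
    selected <- de1$gene_id[de1$consensus & !is.na(de1$loo_pass) & de1$loo_pass]
    background <- rownames(res$mrna)
    lens <- dat$annotation$length_bp[match(background, dat$annotation$feature_id)]
    enr <- enrichment_analysis(dat$gene_sets, selected, background, lens,
                               n_samplings = cfg$enrich_n_samplings,
                               seed = seeds[["enrich"]])
    enr$significant <- enr$fdr_by < cfg$enrich_fdr
    res$enrichment <- enr
    write.table(enr, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- predict -----------------------------------------------------------
  if (run_stage("predict") && length(unique(dat$samples$year)) == 2) {
    panel <- select_panel(res$mrna, dat$samples, fdr_threshold = cfg$panel_fdr)
    years <- sort(unique(dat$samples$year))
    keep <- dat$samples$outcome %in% c("AI_PREG", "NON_PREG")
    sm <- dat$samples[keep, , drop = FALSE]
    tr_ids <- sm$sample_id[sm$year == years[1]]
    te_ids <- sm$sample_id[sm$year == years[2]]
    vt_tr <- vst_transform(res$mrna[, tr_ids, drop = FALSE], panel$genes)
    vt_te <- vst_transform(res$mrna[, te_ids, drop = FALSE], panel$genes,
                           params = vt_tr$params)
    y_tr <- droplevels(sm$outcome[match(tr_ids, sm$sample_id)])
    y_te <- droplevels(sm$outcome[match(te_ids, sm$sample_id)])
    screen <- screen_algorithms(vt_tr$x, y_tr, seed = seeds[["sweep"]])
    sweep_res <- seed_sweep(vt_tr$x, y_tr, vt_te$x, y_te,
                            algorithm = "rf", n_runs = cfg$n_runs_sweep,
                            base_seed = seeds[["sweep"]])
    res$prediction <- list(panel = panel, screen = screen, sweep = sweep_res)
    write.table(sweep_res$runs, file.path(out_dir, "prediction_runs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sweep_res$histogram, file.path(out_dir, "prediction_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sweep_res$importance, file.path(out_dir, "prediction_importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(screen, file.path(out_dir, "algorithm_screen.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(packageVersion("rewirenet")),
    seed = cfg$seed, stage_seeds = as.list(seeds),
    stages = cfg$stages,
    config = cfg[setdiff(names(cfg), c("input", "simulate", "stages"))])
  write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(res)
}
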