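#' Specification for a synthetic two-layer cohort
#'
#' Describes a negative-binomial two-layer (mRNA + miRNA) count data set
#' mirroring the study design: 17 samples in outcome groups of 6 (AI
#' pregnant), 6 (NB pregnant) and 5 (non-pregnant), optionally preceded by a
#' second cohort year of 6 AI-pregnant and 6 non-pregnant animals, ~290
#' miRNAs, and a reduced gene count (default 2000) for tractability. Planted
#' structure — rewired coexpression edges, differential genes, miRNA-target
#' couplings — is declared here and reported back as truth tables.
#'
#' Within-group correlations are planted through latent factors on the
#' log-mean scale: each planted pair receives fixed, exactly-orthogonalized
#' design vectors whose empirical correlation equals the target r within
#' each group cell, so that the realized count-scale correlation is the
#' target attenuated only by NB noise. Planted features get a high baseline
#' (`planted_meanlog`) and a low dispersion (`planted_dispersion`) so the
#' attenuation stays small; the methods vignette quantifies it.
#'
#' @param n_genes,n_mirna layer sizes (defaults 2000 and 290).
#' @param group_sizes named sizes for the focal cohort
#'   (default `c(AI_PREG = 6, NB_PREG = 6, NON_PREG = 5)`).
#' @param n_years 1 or 2; with 2, the first year holds
#'   `year1_group_sizes` (default 6 AI-pregnant / 6 non-pregnant).
#' @param year1_group_sizes sizes for the first cohort when `n_years = 2`.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean counts of
#'   genes (default log(500), 1.2).
#' @param mirna_meanlog,mirna_sdlog log-normal baseline for miRNAs.
#' @param dispersion NB dispersion for unplanted features (default 0.2).
#' @param planted_meanlog,planted_dispersion baseline log-mean and
#'   dispersion of features carrying planted correlation structure.
#' @param factor_sigma per-sample SD (natural-log scale) of the planted
#'   latent design vectors.
#' @param depth_sdlog log-normal SD of per-sample sequencing depth factors.
#' @param year_shift_sd SD of per-gene additive year effects (natural log).
#' @param rewired data.frame with `class` (a rewiring class) and `target_r`
#'   per planted edge; see [plant_rewired()].
#' @param coexpressed data.frame with `target_r` per planted all-sample
#'   coexpressed gene pair; see [plant_coexpressed()].
#' @param de data.frame with `log2_fc` and `group` per planted differential
#'   gene; see [plant_de()].
#' @param mirna_targets data.frame with `sign`, `target_r`, `scope`
#'   (`"all"` or `"gained"`) per planted coupling; see [plant_targets()].
#' @param seed integer seed; the data set is a deterministic function of
#'   (spec, seed).
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000, n_mirna = 290,
                            group_sizes = c(AI_PREG = 6, NB_PREG = 6, NON_PREG = 5),
                            n_years = 1,
                            year1_group_sizes = c(AI_PREG = 6, NB_PREG = 0, NON_PREG = 6),
                            baseline_meanlog = log(500), baseline_sdlog = 1.2,
                            mirna_meanlog = log(800), mirna_sdlog = 1,
                            dispersion = 0.2,
                            planted_meanlog = log(2500), planted_dispersion = 0.001,
                            factor_sigma = 1.5, depth_sdlog = 0.15,
                            year_shift_sd = 0.2,
                            rewired = NULL, de = NULL, mirna_targets = NULL,
                            coexpressed = NULL, seed = 1) {
  stopifnot(n_genes > 0, n_mirna > 0, n_years %in% 1:2, dispersion >= 0,
            all(group_sizes >= 0), sum(group_sizes) > 0)
  if (!is.null(rewired)) {
    stopifnot(all(rewired$class %in% setdiff(REWIRE_CLASSES, "NONE")),
              all(abs(rewired$target_r) < 1), all(rewired$target_r > 0))
  }
  if (!is.null(mirna_targets))
    stopifnot(all(mirna_targets$sign %in% c(-1, 1)),
              all(mirna_targets$scope %in% c("all", "gained")),
              all(mirna_targets$target_r > 0), all(mirna_targets$target_r < 1))
  if (!is.null(coexpressed))
    stopifnot(all(abs(coexpressed$target_r) < 1))
  n_planted <- 2 * NROW(rewired) + NROW(de) + NROW(mirna_targets) +
    2 * NROW(coexpressed)
  if (n_planted > n_genes)
    stop("planted structure requires more genes than n_genes provides")
  if (NROW(mirna_targets) > n_mirna)
    stop("more planted miRNA couplings than miRNAs")
  structure(as.list(environment()), class = "simulation_spec")
}

#' Helpers declaring planted structure
#'
#' `plant_rewired()` declares `n` rewired edges of one class with a target
#' within-group correlation; `plant_de()` declares `n` differential genes
#' with a common log2 fold change applied to one outcome group (all years);
#' `plant_targets()` declares `n` miRNA:gene couplings, either across all
#' samples (`scope = "all"`) or gained in the non-pregnant group only
#' (`scope = "gained"`).
#'
#' @param n number of planted items.
#' @param class rewiring class for the edges.
#' @param target_r target within-group correlation magnitude.
#' @param log2_fc planted log2 fold change.
#' @param group outcome group receiving the expression shift.
#' @param sign coupling sign (+1 or -1).
#' @param scope `"all"` or `"gained"`.
#' @return data.frame fragment for [simulation_spec()].
#' @export
plant_rewired <- function(n, class = "GAINED_POSITIVE", target_r = 0.995) {
  data.frame(class = rep(class, length.out = n),
             target_r = rep(target_r, length.out = n),
             stringsAsFactors = FALSE)
}

#' @rdname plant_rewired
#' @export
plant_coexpressed <- function(n, target_r = 0.999) {
  data.frame(target_r = rep(target_r, length.out = n),
             stringsAsFactors = FALSE)
}

#' @rdname plant_rewired
#' @export
plant_de <- function(n, log2_fc = 2, group = "NON_PREG") {
  data.frame(log2_fc = rep(log2_fc, length.out = n),
             group = rep(group, length.out = n), stringsAsFactors = FALSE)
}

#' @rdname plant_rewired
#' @export
plant_targets <- function(n, sign = -1, target_r = 0.95, scope = "all") {
  data.frame(sign = rep(sign, length.out = n),
             target_r = rep(target_r, length.out = n),
             scope = rep(scope, length.out = n), stringsAsFactors = FALSE)
}

# A pair of centered design vectors of length n with per-sample SD `sigma`
# and empirical correlation exactly `r`. Uniform base draws keep the vectors
# bounded (|u| <= ~sqrt(3) * sigma after scaling), so planted log-means do
# not produce the extreme count excursions Gaussian tails would.
latent_pair <- function(n, r, sigma) {
  if (n < 3) stop("need at least 3 samples per group cell for planted vectors")
  repeat {
    u <- runif(n, -1, 1)
    u <- u - mean(u)
    if (sd(u) > 1e-6) break
  }
  u <- u / sd(u)
  repeat {
    w <- runif(n, -1, 1)
    w <- w - mean(w)
    w <- w - u * sum(u * w) / sum(u * u)
    if (sum(w^2) > 1e-8) break
  }
  w <- w / sd(w)
  rbind(a = sigma * u, b = sigma * (r * u + sqrt(1 - r^2) * w))
}

#' Simulate a two-layer cohort data set
#'
#' Draws counts as `NB(mean, dispersion)` where the log-mean is baseline +
#' planted group effects + year effects + planted latent design vectors,
#' multiplied by a per-sample depth factor. Planted feature ids are
#' allocated deterministically from the front of each layer and reported in
#' the truth tables.
#'
#' @param spec a [simulation_spec()].
#' @return list with `counts_mrna`, `counts_mirna` (count matrices),
#'   `samples` (sample table), `annotation` (both layers), and `truth`
#'   (`rewired`, `de`, `mirna_targets` data.frames with assigned ids).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  ## sample table
  year_sizes <- if (spec$n_years == 2)
    list(`1` = spec$year1_group_sizes, `2` = spec$group_sizes)
  else list(`1` = spec$group_sizes)
  rows <- list()
  for (y in names(year_sizes)) {
    gs <- year_sizes[[y]]
    for (g in OUTCOME_LEVELS) {
      ng <- if (g %in% names(gs)) gs[[g]] else 0
      if (ng > 0)
        rows[[length(rows) + 1]] <- data.frame(
          outcome = g, year = as.integer(y), n = ng, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(sum(meta$n))),
    outcome = check_outcome(rep(meta$outcome, meta$n)),
    year = rep(meta$year, meta$n), stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  gene_ids <- sprintf("gene%05d", seq_len(spec$n_genes))
  mirna_ids <- sprintf("mir%04d", seq_len(spec$n_mirna))

  ## allocate planted feature ids from the front of each layer
  nxt <- 1
  take_genes <- function(k) {
    ids <- gene_ids[nxt:(nxt + k - 1)]; nxt <<- nxt + k; ids
  }
  truth <- list(rewired = spec$rewired, de = spec$de,
                mirna_targets = spec$mirna_targets,
                coexpressed = spec$coexpressed)
  if (NROW(spec$rewired)) {
    truth$rewired$feature_a <- take_genes(NROW(spec$rewired))
    truth$rewired$feature_b <- take_genes(NROW(spec$rewired))
    ## canonical order within each pair
    swap <- truth$rewired$feature_a > truth$rewired$feature_b
    tmp <- truth$rewired$feature_a[swap]
    truth$rewired$feature_a[swap] <- truth$rewired$feature_b[swap]
    truth$rewired$feature_b[swap] <- tmp
  }
  if (NROW(spec$coexpressed)) {
    truth$coexpressed$feature_a <- take_genes(NROW(spec$coexpressed))
    truth$coexpressed$feature_b <- take_genes(NROW(spec$coexpressed))
    swap <- truth$coexpressed$feature_a > truth$coexpressed$feature_b
    tmp <- truth$coexpressed$feature_a[swap]
    truth$coexpressed$feature_a[swap] <- truth$coexpressed$feature_b[swap]
    truth$coexpressed$feature_b[swap] <- tmp
  }
  if (NROW(spec$de)) truth$de$gene_id <- take_genes(NROW(spec$de))
  if (NROW(spec$mirna_targets)) {
    truth$mirna_targets$gene_id <- take_genes(NROW(spec$mirna_targets))
    truth$mirna_targets$mirna_id <- mirna_ids[seq_len(NROW(spec$mirna_targets))]
  }
  planted_genes <- unique(c(truth$rewired$feature_a, truth$rewired$feature_b,
                            truth$coexpressed$feature_a,
                            truth$coexpressed$feature_b,
                            truth$mirna_targets$gene_id))
  planted_mirnas <- unique(truth$mirna_targets$mirna_id)

  ## baselines and dispersions
  base_g <- rnorm(spec$n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
  base_m <- rnorm(spec$n_mirna, spec$mirna_meanlog, spec$mirna_sdlog)
  names(base_g) <- gene_ids; names(base_m) <- mirna_ids
  base_g[planted_genes] <- spec$planted_meanlog
  base_m[planted_mirnas] <- spec$planted_meanlog
  ## differential genes emulate moderately expressed transcripts: above the
  ## 2-CPM filter, below the extreme tail where mean-dispersion trends are
  ## data-poor
  if (NROW(truth$de))
    base_g[truth$de$gene_id] <- pmin(pmax(base_g[truth$de$gene_id], log(100)),
                                     log(1000))
  phi_g <- setNames(rep(spec$dispersion, spec$n_genes), gene_ids)
  phi_m <- setNames(rep(spec$dispersion, spec$n_mirna), mirna_ids)
  phi_g[planted_genes] <- spec$planted_dispersion
  phi_m[planted_mirnas] <- spec$planted_dispersion

  ## log-mean matrices
  lmu_g <- matrix(base_g, nrow = spec$n_genes, ncol = n_s,
                  dimnames = list(gene_ids, samples$sample_id))
  lmu_m <- matrix(base_m, nrow = spec$n_mirna, ncol = n_s,
                  dimnames = list(mirna_ids, samples$sample_id))
  ## year effects (genes only; miRNA profiles are near-invariant in plasma)
  if (spec$n_years == 2) {
    shift <- rnorm(spec$n_genes, 0, spec$year_shift_sd)
    lmu_g[, samples$year == 2] <- lmu_g[, samples$year == 2] + shift
  }
  ## planted DE group effects (all years)
  if (NROW(truth$de)) {
    for (i in seq_len(nrow(truth$de))) {
      cols <- samples$outcome == truth$de$group[i]
      lmu_g[truth$de$gene_id[i], cols] <-
        lmu_g[truth$de$gene_id[i], cols] + truth$de$log2_fc[i] * log(2)
    }
  }
  ## planted rewired edges: exact-correlation design vectors per group cell
  cells <- split(seq_len(n_s), list(samples$outcome, samples$year), drop = TRUE)
  cell_group <- vapply(strsplit(names(cells), "\\."), `[`, character(1), 1)
  if (NROW(truth$rewired)) {
    for (i in seq_len(nrow(truth$rewired))) {
      cls <- truth$rewired$class[i]; t_r <- truth$rewired$target_r[i]
      a <- truth$rewired$feature_a[i]; b <- truth$rewired$feature_b[i]
      for (ci in seq_along(cells)) {
        focal <- cell_group[ci] == "NON_PREG"
        r <- switch(cls,
          GAINED_POSITIVE = if (focal) t_r else 0,
          GAINED_NEGATIVE = if (focal) -t_r else 0,
          LOST_POSITIVE = if (focal) 0 else t_r,
          LOST_NEGATIVE = if (focal) 0 else -t_r,
          INVERTED = if (focal) t_r else -t_r)
        cols <- cells[[ci]]
        lp <- latent_pair(length(cols), r, spec$factor_sigma)
        lmu_g[a, cols] <- lmu_g[a, cols] + lp["a", ]
        lmu_g[b, cols] <- lmu_g[b, cols] + lp["b", ]
      }
    }
  }
  ## planted all-sample coexpressed gene pairs (one shared factor, all samples)
  if (NROW(truth$coexpressed)) {
    for (i in seq_len(nrow(truth$coexpressed))) {
      lp <- latent_pair(n_s, truth$coexpressed$target_r[i], spec$factor_sigma)
      a <- truth$coexpressed$feature_a[i]; b <- truth$coexpressed$feature_b[i]
      lmu_g[a, ] <- lmu_g[a, ] + lp["a", ]
      lmu_g[b, ] <- lmu_g[b, ] + lp["b", ]
    }
  }

  ## planted miRNA:gene couplings
  if (NROW(truth$mirna_targets)) {
    for (i in seq_len(nrow(truth$mirna_targets))) {
      tg <- truth$mirna_targets[i, ]
      cell_list <- if (tg$scope == "all") list(seq_len(n_s)) else cells
      for (ci in seq_along(cell_list)) {
        r <- if (tg$scope == "all") tg$sign * tg$target_r
             else if (cell_group[ci] == "NON_PREG") tg$sign * tg$target_r else 0
        cols <- cell_list[[ci]]
        lp <- latent_pair(length(cols), r, spec$factor_sigma)
        lmu_m[tg$mirna_id, cols] <- lmu_m[tg$mirna_id, cols] + lp["a", ]
        lmu_g[tg$gene_id, cols] <- lmu_g[tg$gene_id, cols] + lp["b", ]
      }
    }
  }
  ## depth factors and NB draws
  depth <- exp(rnorm(n_s, 0, spec$depth_sdlog))
  draw <- function(lmu, phi) {
    mu <- sweep(exp(lmu), 2, depth, "*")
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / pmax(phi, 1e-8)),
                  nrow = nrow(mu), dimnames = dimnames(mu))
    cnt
  }
  counts_g <- draw(lmu_g, phi_g)
  counts_m <- draw(lmu_m, phi_m)
  annotation <- data.frame(
    feature_id = c(gene_ids, mirna_ids),
    biotype = c(rep("protein_coding", spec$n_genes), rep("miRNA", spec$n_mirna)),
    length_bp = c(round(exp(rnorm(spec$n_genes, log(2000), 0.7))),
                  rep(80, spec$n_mirna)),
    symbol = c(gene_ids, mirna_ids), stringsAsFactors = FALSE)
  list(counts_mrna = validate_counts(counts_g, layer = "mRNA"),
       counts_mirna = validate_counts(counts_m, layer = "miRNA"),
       samples = samples, annotation = annotation, truth = truth, spec = spec)
}

#' Export a simulated data set as pipeline input files
#'
#' Writes exactly the formats [read_counts()], [read_sample_table()] and
#' [read_annotation()] consume, plus truth tables.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
export_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mrna = file.path(dir, "counts_mrna.tsv"),
    mirna = file.path(dir, "counts_mirna.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.tsv"))
  write_matrix_tsv(sim$counts_mrna, paths["mrna"])
  write_matrix_tsv(sim$counts_mirna, paths["mirna"])
  write.table(sim$samples, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$annotation, paths["annotation"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(sim$truth)) {
    if (NROW(sim$truth[[nm]])) {
      p <- file.path(dir, paste0("truth_", nm, ".tsv"))
      write.table(sim$truth[[nm]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths[paste0("truth_", nm)] <- p
    }
  }
  invisible(paths)
}
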