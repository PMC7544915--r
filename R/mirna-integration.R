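#' Cross-layer miRNA:mRNA correlation
#'
#' Pearson's r between every circulating miRNA and every PWBC mRNA across
#' all samples. The two layers must cover the same samples, matched by
#' sample id; columns are aligned before correlating. Zero-variance features
#' in either layer are excluded with a logged count.
#'
#' @param em_mirna miRNA expression matrix (miRNAs x samples).
#' @param em_mrna mRNA expression matrix (genes x samples).
#' @return data.frame with `mirna_id`, `gene_id`, `r`.
#' @export
cross_correlation <- function(em_mirna, em_mrna) {
  miss <- c(setdiff(colnames(em_mirna), colnames(em_mrna)),
            setdiff(colnames(em_mrna), colnames(em_mirna)))
  if (length(miss))
    stop("sample mismatch between layers: ", paste(unique(miss), collapse = ", "))
  em_mrna <- em_mrna[, colnames(em_mirna), drop = FALSE]
  v1 <- apply(em_mirna, 1, var); v2 <- apply(em_mrna, 1, var)
  if (any(v1 == 0) || any(v2 == 0))
    rw_msg(sum(v1 == 0) + sum(v2 == 0),
           " zero-variance feature(s) excluded from cross-layer correlation")
  em_mirna <- em_mirna[v1 > 0, , drop = FALSE]
  em_mrna <- em_mrna[v2 > 0, , drop = FALSE]
  cm <- cor(t(em_mirna), t(em_mrna))
  data.frame(mirna_id = rep(rownames(cm), times = ncol(cm)),
             gene_id = rep(colnames(cm), each = nrow(cm)),
             r = as.vector(cm), stringsAsFactors = FALSE)
}

#' Select cross-layer pairs by absolute correlation
#'
#' @param edges data.frame from [cross_correlation()].
#' @param r_threshold absolute-r selection threshold (default 0.85, the
#'   study's all-sample miRNA:mRNA cutoff).
#' @return the selected subset.
#' @export
select_cross_layer <- function(edges, r_threshold = 0.85) {
  edges[abs(edges$r) > r_threshold, , drop = FALSE]
}

#' Empirical FDR for cross-layer correlation by identity shuffling
#'
#' Permutes the sample identities of the mRNA matrix (the miRNA matrix is
#' left fixed), breaking the common animal source of the two RNA layers
#' while preserving each layer's within-layer structure, then counts
#' cross-layer pairs exceeding the |r| threshold in each scrambled data set.
#'
#' @param em_mirna,em_mrna aligned expression matrices.
#' @param r_threshold |r| threshold whose exceedances are counted.
#' @param n_randomizations number of shuffles (study default 5000).
#' @param seed integer seed.
#' @return eFDR record as in [efdr_rewiring()] plus the scrambled counts.
#' @export
efdr_cross_layer <- function(em_mirna, em_mrna, r_threshold = 0.85,
                             n_randomizations = 5000, seed = 1) {
  stopifnot(n_randomizations >= 1)
  em_mrna <- em_mrna[, colnames(em_mirna), drop = FALSE]
  em_mirna <- em_mirna[apply(em_mirna, 1, var) > 0, , drop = FALSE]
  em_mrna <- em_mrna[apply(em_mrna, 1, var) > 0, , drop = FALSE]
  tm <- t(em_mirna); tg <- t(em_mrna)
  observed <- sum(abs(cor(tm, tg)) > r_threshold)
  set.seed(seed)
  scrambled <- integer(n_randomizations)
  n <- nrow(tg)
  for (i in seq_len(n_randomizations)) {
    scrambled[i] <- sum(abs(cor(tm, tg[sample.int(n), , drop = FALSE])) > r_threshold)
  }
  res <- efdr_result(observed, scrambled, n_randomizations, r_threshold)
  res$scrambled_counts <- scrambled
  res
}

#' Differential (rewired) miRNA:mRNA coexpression
#'
#' Applies the same rewiring rules as the within-layer analysis to every
#' (miRNA, gene) pair: within-group cross correlations are computed for
#' `AI_PREG`, `NB_PREG` and `NON_PREG`, and a pair is reported when
#' [classify_edge()] gives the same non-`NONE` class for `NON_PREG` against
#' both pregnant reference groups.
#'
#' @param em_mirna,em_mrna aligned expression matrices.
#' @param samples sample table covering the shared samples.
#' @param thresholds a [rewire_thresholds()] object.
#' @return list with `edges` (`mirna_id`, `gene_id`, group correlations,
#'   `rewire_class`), `discordant`, and `table` (all pairs with group r).
#' @export
cross_layer_rewiring <- function(em_mirna, em_mrna, samples,
                                 thresholds = rewire_thresholds()) {
  em_mrna <- em_mrna[, colnames(em_mirna), drop = FALSE]
  samples <- samples[match(colnames(em_mirna), samples$sample_id), , drop = FALSE]
  outcome <- check_outcome(samples$outcome)
  rmats <- lapply(setNames(nm = OUTCOME_LEVELS), function(g) {
    cols <- which(outcome == g)
    if (length(cols) < 3) stop("group ", g, " has fewer than 3 samples")
    suppressWarnings(cor(t(em_mirna[, cols, drop = FALSE]),
                         t(em_mrna[, cols, drop = FALSE])))
  })
  tab <- data.frame(
    mirna_id = rep(rownames(rmats[[1]]), times = ncol(rmats[[1]])),
    gene_id = rep(colnames(rmats[[1]]), each = nrow(rmats[[1]])),
    r_ai = as.vector(rmats$AI_PREG), r_nb = as.vector(rmats$NB_PREG),
    r_np = as.vector(rmats$NON_PREG), stringsAsFactors = FALSE)
  defined <- !(is.na(tab$r_ai) | is.na(tab$r_nb) | is.na(tab$r_np))
  if (any(!defined))
    rw_msg(sum(!defined), " cross-layer pair(s) with undefined within-group r excluded")
  tab <- tab[defined, , drop = FALSE]
  cc <- consensus_class(tab$r_np, tab$r_ai, tab$r_nb, thresholds)
  keep <- cc$class != "NONE"
  edges <- tab[keep, , drop = FALSE]
  edges$rewire_class <- cc$class[keep]
  rownames(edges) <- NULL
  disc <- tab[cc$discordant, , drop = FALSE]
  if (nrow(disc)) {
    disc$class_vs_ai <- cc$class_1[cc$discordant]
    disc$class_vs_nb <- cc$class_2[cc$discordant]
  }
  rownames(disc) <- NULL
  list(edges = edges, discordant = disc, table = tab)
}

#' Overlay known miRNA-target interactions on cross-layer edges
#'
#' Marks each (miRNA, gene) edge that appears in a user-supplied interaction
#' table (e.g. experimentally validated pairs exported from a target
#' database). Duplicated table rows have no effect beyond the first.
#'
#' @param edges data.frame with `mirna_id` and `gene_id` columns.
#' @param interactions data.frame with columns `mirna_id`, `gene_id`.
#' @return `edges` with a logical `known_interaction` column; summary counts
#'   by correlation sign in attribute `overlay_summary` when `edges` has an
#'   `r` column.
#' @export
overlay_interactions <- function(edges, interactions) {
  if (!all(c("mirna_id", "gene_id") %in% names(interactions)))
    stop("interaction table needs columns mirna_id, gene_id")
  key <- function(d) paste(d$mirna_id, d$gene_id, sep = "\r")
  edges$known_interaction <- key(edges) %in% key(interactions)
  if ("r" %in% names(edges)) {
    attr(edges, "overlay_summary") <- c(
      known_negative = sum(edges$known_interaction & edges$r < 0),
      known_positive = sum(edges$known_interaction & edges$r > 0))
  }
  edges
}

#' Read a two-column miRNA-target interaction table
#'
#' @param path TSV with columns `mirna_id`, `gene_id` (one pair per row).
#' @return deduplicated data.frame.
#' @export
read_interactions <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(df)))
    stop("interaction table needs columns mirna_id, gene_id")
  unique(df[c("mirna_id", "gene_id")])
}
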