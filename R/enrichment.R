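#' Length-bias probability weighting function
#'
#' Longer transcripts accumulate more reads and are therefore more likely to
#' be selected by count-based tests at equal expression; gene-set enrichment
#' must sample its null accordingly. Genes are binned into `n_bins` quantile
#' bins of transcript length, the per-bin selection fraction is computed and
#' made monotone non-decreasing in length by weighted isotonic pooling
#' (pool-adjacent-violators with bin sizes as weights), and each gene
#' receives its bin's pooled fraction, floored at `eps`.
#'
#' @param lengths transcript length (bp) per background gene.
#' @param selected logical selection flag per background gene.
#' @param n_bins number of length-quantile bins (default 20).
#' @param eps floor for the weights.
#' @return numeric vector of per-gene selection weights.
#' @export
fit_pwf <- function(lengths, selected, n_bins = 20, eps = 1e-4) {
  stopifnot(length(lengths) == length(selected))
  if (length(lengths) < 20) stop("need at least 20 background genes")
  if (all(selected) || !any(selected)) {
    warning("degenerate selection (all or none); using flat weights")
    return(rep(1, length(lengths)))
  }
  n_bins <- max(1L, as.integer(n_bins))
  br <- unique(quantile(lengths, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(lengths, breaks = br, include.lowest = TRUE)
  frac <- tapply(selected, bin, mean)
  w <- tapply(selected, bin, length)
  keep <- !is.na(frac)
  pooled <- pava_nondecreasing(as.numeric(frac[keep]), as.numeric(w[keep]))
  vals <- setNames(rep(NA_real_, nlevels(bin)), levels(bin))
  vals[names(frac)[keep]] <- pooled
  pmax(vals[as.character(bin)], eps)
}

# Weighted pool-adjacent-violators, non-decreasing.
pava_nondecreasing <- function(y, w) {
  n <- length(y)
  if (n <= 1) return(y)
  val <- y; wt <- w; idx <- rep(1L, n)  # blocks
  vals <- y[1]; wts <- w[1]; sizes <- 1L
  for (i in 2:n) {
    vals <- c(vals, y[i]); wts <- c(wts, w[i]); sizes <- c(sizes, 1L)
    while (length(vals) > 1 &&
           vals[length(vals) - 1] > vals[length(vals)]) {
      k <- length(vals)
      merged_w <- wts[k - 1] + wts[k]
      merged_v <- (vals[k - 1] * wts[k - 1] + vals[k] * wts[k]) / merged_w
      merged_s <- sizes[k - 1] + sizes[k]
      vals <- c(vals[seq_len(k - 2)], merged_v)
      wts <- c(wts[seq_len(k - 2)], merged_w)
      sizes <- c(sizes[seq_len(k - 2)], merged_s)
    }
  }
  rep(vals, sizes)
}

#' Weighted-sampling enrichment p-value for one gene set
#'
#' Repeatedly draws `|selected|` genes from the background without
#' replacement with probability proportional to the PWF weights and compares
#' the in-term count with the observed one. The over-representation p-value
#' uses the add-one estimator
#' `(1 + #draws with count >= observed) / (n_samplings + 1)`, so it is
#' bounded below by `1 / (n_samplings + 1)`.
#'
#' @param term_genes gene ids of the set.
#' @param selected gene ids of the selected list.
#' @param background all background gene ids.
#' @param weights per-gene weights aligned with `background` (default flat).
#' @param n_samplings number of null draws (default 10,000).
#' @param seed integer seed.
#' @return list with `observed`, `expected` (mean null in-term count) and
#'   `p_over`.
#' @export
sampling_enrichment_test <- function(term_genes, selected, background,
                                     weights = NULL, n_samplings = 10000,
                                     seed = 1) {
  stopifnot(n_samplings >= 1)
  if (is.null(weights)) weights <- rep(1, length(background))
  stopifnot(length(weights) == length(background))
  term_genes <- intersect(term_genes, background)
  if (!length(term_genes)) stop("term has no genes in the background")
  selected <- intersect(selected, background)
  k <- length(selected)
  in_term <- background %in% term_genes
  observed <- sum(selected %in% term_genes)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_samplings), function(i)
    sum(in_term[sample.int(length(background), k, prob = weights)]),
    numeric(1))
  list(observed = as.integer(observed), expected = mean(null_counts),
       p_over = (1 + sum(null_counts >= observed)) / (n_samplings + 1))
}

#' Benjamini-Yekutieli adjustment (FDR under dependency)
#'
#' @param p p-values.
#' @return BY-adjusted values via [stats::p.adjust()].
#' @export
fdr_by <- function(p) p.adjust(p, method = "BY")

#' Length-aware gene-set enrichment of a selected gene list
#'
#' For each term: PWF-weighted sampling p-value for over-representation,
#' then Benjamini-Yekutieli adjustment across terms. Terms with fewer than
#' 2 background members are dropped. The background is intended to be all
#' genes detected as expressed after filtering.
#'
#' @param gene_sets data.frame with columns `term_id`, `gene_id` and
#'   optionally `term_name`.
#' @param selected selected gene ids.
#' @param background background gene ids.
#' @param lengths transcript lengths aligned with `background`; when `NULL`
#'   flat weights are used.
#' @param n_samplings null draws per term.
#' @param seed integer seed.
#' @param n_bins PWF bins.
#' @return data.frame with `term_id`, `n_term`, `n_selected_in_term`,
#'   `expected`, `p_over`, `fdr_by`, sorted by `p_over`.
#' @export
enrichment_analysis <- function(gene_sets, selected, background,
                                lengths = NULL, n_samplings = 10000,
                                seed = 1, n_bins = 20) {
  stopifnot(all(c("term_id", "gene_id") %in% names(gene_sets)))
  gene_sets <- gene_sets[gene_sets$gene_id %in% background, , drop = FALSE]
  sizes <- table(gene_sets$term_id)
  keep_terms <- names(sizes)[sizes >= 2]
  gene_sets <- gene_sets[gene_sets$term_id %in% keep_terms, , drop = FALSE]
  if (!nrow(gene_sets))
    return(data.frame(term_id = character(), n_term = integer(),
                      n_selected_in_term = integer(), expected = numeric(),
                      p_over = numeric(), fdr_by = numeric()))
  weights <- if (is.null(lengths)) rep(1, length(background)) else
    fit_pwf(lengths, background %in% selected, n_bins = n_bins)
  terms <- split(gene_sets$gene_id, gene_sets$term_id)
  seeds <- derive_seeds(seed, length(terms))
  rows <- lapply(seq_along(terms), function(i) {
    res <- sampling_enrichment_test(terms[[i]], selected, background,
                                    weights, n_samplings, seeds[i])
    data.frame(term_id = names(terms)[i], n_term = length(unique(terms[[i]])),
               n_selected_in_term = res$observed, expected = res$expected,
               p_over = res$p_over, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_by <- fdr_by(out$p_over)
  if ("term_name" %in% names(gene_sets)) {
    nm <- gene_sets[!duplicated(gene_sets$term_id), c("term_id", "term_name")]
    out$term_name <- nm$term_name[match(out$term_id, nm$term_id)]
  }
  out[order(out$p_over), , drop = FALSE]
}

#' Read gene sets from a two-column TSV or a GMT file
#'
#' @param path file path; `.gmt` is detected by extension, otherwise a TSV
#'   with columns `term_id`, `gene_id` (optional `term_name`) is expected.
#' @return data.frame with `term_id`, `gene_id` (and `term_name` for GMT).
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    rows <- lapply(strsplit(lines[nzchar(lines)], "\t"), function(f) {
      if (length(f) < 3) return(NULL)
      data.frame(term_id = f[1], term_name = f[2], gene_id = f[-(1:2)],
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(df)))
    stop("gene set table needs columns term_id, gene_id")
  df
}
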