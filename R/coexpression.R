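#' All-sample pairwise coexpression
#'
#' Computes Pearson's r for every unordered pair of features across all
#' samples. Features with zero variance across the samples are excluded with
#' a logged count (their correlation is undefined). Pairs are canonicalized
#' so `feature_a < feature_b` lexicographically and each pair appears once.
#'
#' @param em expression matrix (features x samples); the pipeline uses
#'   log2(CPM + 1) values.
#' @param features optional subset of feature ids to correlate.
#' @return data.frame with `feature_a`, `feature_b`, `r`.
#' @export
pairwise_correlation <- function(em, features = NULL) {
  if (!is.null(features)) em <- em[intersect(features, rownames(em)), , drop = FALSE]
  if (ncol(em) < 3) stop("at least 3 samples required for correlation")
  v <- apply(em, 1, var)
  if (any(v == 0)) {
    rw_msg(sum(v == 0), " zero-variance feature(s) excluded from correlation")
    em <- em[v > 0, , drop = FALSE]
  }
  em <- em[order(rownames(em)), , drop = FALSE]
  if (nrow(em) < 2)
    return(data.frame(feature_a = character(), feature_b = character(),
                      r = numeric()))
  cm <- cor(t(em))
  ut <- upper.tri(cm)
  pairs <- canonical_pairs(rownames(em))
  pairs$r <- cm[ut]
  pairs
}

#' Correlation p-value by the Fisher z normal approximation
#'
#' Two-sided p-value for the null r = 0: `z = atanh(r) * sqrt(n - 3)`,
#' `p = 2 * (1 - pnorm(|z|))`, clipped below at the smallest representable
#' positive double. `|r| = 1` (infinite z) returns that minimum.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @param n number of samples (>= 4).
#' @return p-value(s) in `(0, 1]`.
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 4) stop("n >= 4 required")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  z <- suppressWarnings(atanh(r)) * sqrt(n - 3)
  p <- 2 * pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

#' Select significant coexpression edges
#'
#' Attaches nominal p-values (Fisher z approximation) and Benjamini-Hochberg
#' FDR over all tested pairs, then retains edges with `|r| > r_threshold` and
#' `fdr < fdr_threshold` (both strict, matching the selection rule
#' |r| > 0.98, FDR < 0.02).
#'
#' @param edges data.frame from [pairwise_correlation()].
#' @param n number of samples the correlations were computed on.
#' @param r_threshold absolute-correlation threshold (default 0.98).
#' @param fdr_threshold BH FDR threshold (default 0.02).
#' @return list with `edges` (all pairs with `p`, `fdr`, `selected`),
#'   `selected` (the retained subset) and `counts` (positive/negative
#'   retained edges).
#' @export
significant_edges <- function(edges, n, r_threshold = 0.98, fdr_threshold = 0.02) {
  if (nrow(edges) == 0) {
    edges$p <- numeric(); edges$fdr <- numeric(); edges$selected <- logical()
    return(list(edges = edges, selected = edges,
                counts = c(positive = 0L, negative = 0L)))
  }
  edges$p <- correlation_pvalue(edges$r, n)
  edges$fdr <- p.adjust(edges$p, method = "BH")
  edges$selected <- abs(edges$r) > r_threshold & edges$fdr < fdr_threshold
  sel <- edges[edges$selected, , drop = FALSE]
  list(edges = edges, selected = sel,
       counts = c(positive = sum(sel$r > 0), negative = sum(sel$r < 0)))
}

#' All-sample coexpression network
#'
#' Convenience wrapper: correlations on `log2(CPM + 1)` of the supplied
#' counts, p-values, BH FDR and edge selection in one call.
#'
#' @param counts filtered count matrix.
#' @param r_threshold,fdr_threshold selection thresholds (defaults 0.98, 0.02).
#' @param lib_sizes optional library sizes for the CPM step.
#' @return as [significant_edges()].
#' @export
coexpression_network <- function(counts, r_threshold = 0.98,
                                 fdr_threshold = 0.02, lib_sizes = NULL) {
  em <- compute_cpm(counts, log = TRUE, lib_sizes = lib_sizes)
  edges <- pairwise_correlation(em)
  significant_edges(edges, n = ncol(counts),
                    r_threshold = r_threshold, fdr_threshold = fdr_threshold)
}
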