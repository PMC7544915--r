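#' Rewiring classification thresholds
#'
#' The three constants of the rewiring rules: an edge is *inverted* between
#' two groups when the within-group correlations differ by more than
#' `inverted_gap`; it is *gained* in the focal group (or *lost*, by symmetry)
#' when the focal correlation exceeds `present_abs_r` in absolute value while
#' the reference correlation lies strictly inside the `absent_band` around
#' zero. Defaults are the study's rules: |r1 - r2| > 1.95 for inversion,
#' |r1| > 0.99 with -0.1 < r2 < 0.1 for gain/loss.
#'
#' @param inverted_gap gap threshold in (0, 2].
#' @param present_abs_r absolute-correlation threshold for a present edge.
#' @param absent_band half-width of the absent band around zero.
#' @return list of class `rewire_thresholds`.
#' @export
rewire_thresholds <- function(inverted_gap = 1.95, present_abs_r = 0.99,
                              absent_band = 0.1) {
  if (!(inverted_gap > 0 && inverted_gap <= 2)) stop("inverted_gap must be in (0, 2]")
  if (!(absent_band > 0 && absent_band < present_abs_r && present_abs_r <= 1))
    stop("need 0 < absent_band < present_abs_r <= 1")
  structure(list(inverted_gap = inverted_gap, present_abs_r = present_abs_r,
                 absent_band = absent_band), class = "rewire_thresholds")
}

#' Classify a coexpression edge between two groups
#'
#' Pure, vectorized function of the two within-group correlations. All
#' inequalities are strict:
#' * `INVERTED` if `|r_focal - r_reference| > inverted_gap`;
#' * `GAINED_POSITIVE` / `GAINED_NEGATIVE` (sign of `r_focal`) if
#'   `|r_focal| > present_abs_r` and `-absent_band < r_reference < absent_band`;
#' * `LOST_POSITIVE` / `LOST_NEGATIVE` if the mirrored condition holds for
#'   `r_reference`;
#' * `NONE` otherwise.
#'
#' Under the default thresholds the gained/lost and inverted regions are
#' disjoint (|r1| > 0.99 with |r2| < 0.1 forces |r1 - r2| < 1.09 < 1.95).
#'
#' @param r_focal,r_reference within-group correlations.
#' @param thresholds a [rewire_thresholds()] object.
#' @return character vector over `GAINED_POSITIVE`, `GAINED_NEGATIVE`,
#'   `LOST_POSITIVE`, `LOST_NEGATIVE`, `INVERTED`, `NONE`.
#' @export
classify_edge <- function(r_focal, r_reference, thresholds = rewire_thresholds()) {
  th <- thresholds
  out <- rep("NONE", length(r_focal))
  gained <- abs(r_focal) > th$present_abs_r &
    r_reference > -th$absent_band & r_reference < th$absent_band
  lost <- abs(r_reference) > th$present_abs_r &
    r_focal > -th$absent_band & r_focal < th$absent_band
  inv <- abs(r_focal - r_reference) > th$inverted_gap
  out[lost] <- ifelse(r_reference[lost] > 0, "LOST_POSITIVE", "LOST_NEGATIVE")
  out[gained] <- ifelse(r_focal[gained] > 0, "GAINED_POSITIVE", "GAINED_NEGATIVE")
  out[inv] <- "INVERTED"
  out
}

# Within-group correlation matrices for an expression matrix.
group_cor_matrices <- function(em, outcome) {
  outcome <- check_outcome(outcome)
  lapply(setNames(nm = OUTCOME_LEVELS), function(g) {
    cols <- which(outcome == g)
    if (length(cols) < 3)
      stop("group ", g, " has fewer than 3 samples; correlation undefined")
    suppressWarnings(cor(t(em[, cols, drop = FALSE])))
  })
}

#' Within-group pairwise correlations
#'
#' Pearson's r for every feature pair inside each outcome group. Pairs
#' involving a feature with zero variance within any group (undefined r)
#' are flagged `defined = FALSE` and excluded from downstream rewiring calls.
#'
#' @param em expression matrix (features x samples), log2(CPM + 1) in the
#'   pipeline.
#' @param samples sample table aligned with `colnames(em)`.
#' @return data.frame with `feature_a`, `feature_b`, `r_ai`, `r_nb`, `r_np`,
#'   `defined`; group sizes in attribute `group_sizes`.
#' @export
groupwise_correlation <- function(em, samples) {
  samples <- samples[match(colnames(em), samples$sample_id), , drop = FALSE]
  em <- em[order(rownames(em)), , drop = FALSE]
  mats <- group_cor_matrices(em, samples$outcome)
  ut <- upper.tri(mats[[1]])
  gct <- canonical_pairs(rownames(em))
  gct$r_ai <- mats$AI_PREG[ut]
  gct$r_nb <- mats$NB_PREG[ut]
  gct$r_np <- mats$NON_PREG[ut]
  gct$defined <- !(is.na(gct$r_ai) | is.na(gct$r_nb) | is.na(gct$r_np))
  if (any(!gct$defined))
    rw_msg(sum(!gct$defined), " pair(s) with undefined within-group r flagged")
  attr(gct, "group_sizes") <- table(check_outcome(samples$outcome))
  gct
}

# Consensus class of each pair: same non-NONE class versus both references.
consensus_class <- function(r_focal, r_ref1, r_ref2, thresholds) {
  c1 <- classify_edge(r_focal, r_ref1, thresholds)
  c2 <- classify_edge(r_focal, r_ref2, thresholds)
  cls <- ifelse(c1 == c2, c1, "NONE")
  discordant <- c1 != c2 & c1 != "NONE" & c2 != "NONE"
  list(class = cls, discordant = discordant, class_1 = c1, class_2 = c2)
}

#' Consensus rewired edges (focal group versus both references)
#'
#' An edge is reported as rewired when [classify_edge()] returns the *same*
#' non-`NONE` class for the focal group against each of the two reference
#' groups — the focal group is `NON_PREG`, the references `AI_PREG` and
#' `NB_PREG`, matching a change "relative to both" pregnant groups. Pairs
#' whose two contrasts give different non-`NONE` classes are returned
#' separately as discordant and excluded from the headline set.
#'
#' @param gct table from [groupwise_correlation()] (or any data.frame with
#'   `feature_a`, `feature_b`, `r_ai`, `r_nb`, `r_np`).
#' @param thresholds a [rewire_thresholds()] object.
#' @return list with `edges` (consensus rewired pairs and their class) and
#'   `discordant`.
#' @export
consensus_rewired_edges <- function(gct, thresholds = rewire_thresholds()) {
  if ("defined" %in% names(gct)) gct <- gct[gct$defined, , drop = FALSE]
  cc <- consensus_class(gct$r_np, gct$r_ai, gct$r_nb, thresholds)
  keep <- cc$class != "NONE"
  edges <- gct[keep, c("feature_a", "feature_b", "r_np", "r_ai", "r_nb")]
  edges$rewire_class <- cc$class[keep]
  rownames(edges) <- NULL
  disc <- gct[cc$discordant, c("feature_a", "feature_b", "r_np", "r_ai", "r_nb")]
  if (nrow(disc)) {
    disc$class_vs_ai <- cc$class_1[cc$discordant]
    disc$class_vs_nb <- cc$class_2[cc$discordant]
  }
  rownames(disc) <- NULL
  list(edges = edges, discordant = disc)
}

# Count consensus classes for one outcome labelling (fast path used by the
# permutation null as well as the observed data). Pure logical arithmetic on
# the upper triangle; agreement with classify_edge() is property-tested.
consensus_counts <- function(em, outcome, thresholds) {
  th <- thresholds
  mats <- group_cor_matrices(em, outcome)
  ut <- upper.tri(mats[[1]])
  r_np <- mats$NON_PREG[ut]; r_ai <- mats$AI_PREG[ut]; r_nb <- mats$NB_PREG[ut]
  ok <- !(is.na(r_np) | is.na(r_ai) | is.na(r_nb))
  r_np <- r_np[ok]; r_ai <- r_ai[ok]; r_nb <- r_nb[ok]
  band <- function(r) r > -th$absent_band & r < th$absent_band
  pres <- function(r) abs(r) > th$present_abs_r
  inv <- function(r1, r2) abs(r1 - r2) > th$inverted_gap
  # per-contrast class indicators, inverted taking precedence
  inv1 <- inv(r_np, r_ai); inv2 <- inv(r_np, r_nb)
  g1 <- pres(r_np) & band(r_ai) & !inv1; g2 <- pres(r_np) & band(r_nb) & !inv2
  l1 <- pres(r_ai) & band(r_np) & !inv1; l2 <- pres(r_nb) & band(r_np) & !inv2
  pos_np <- r_np > 0
  c(GAINED_POSITIVE = sum(g1 & g2 & pos_np),
    GAINED_NEGATIVE = sum(g1 & g2 & !pos_np),
    LOST_POSITIVE = sum(l1 & l2 & r_ai > 0 & r_nb > 0),
    LOST_NEGATIVE = sum(l1 & l2 & r_ai < 0 & r_nb < 0),
    INVERTED = sum(inv1 & inv2))
}

# Shared empirical-FDR bookkeeping: mean scrambled exceedances over observed.
efdr_result <- function(observed, scrambled, n_randomizations, threshold) {
  mean_scrambled <- mean(scrambled)
  if (observed == 0) {
    warning("no observed exceedances; eFDR undefined, reported as 1")
    efdr <- 1
  } else efdr <- min(1, mean_scrambled / observed)
  list(threshold = threshold, observed_exceedances = as.integer(observed),
       mean_scrambled_exceedances = mean_scrambled,
       n_randomizations = as.integer(n_randomizations), efdr = efdr)
}

#' Empirical FDR for consensus rewiring by outcome-label permutation
#'
#' Resamples the outcome labels across all samples (group sizes preserved),
#' recomputes the within-group correlations, and counts the pairs satisfying
#' the same consensus rewiring rule in each scrambled data set. The empirical
#' FDR is the mean scrambled count divided by the observed count, clipped to
#' `[0, 1]`; it is reported pooled over rewiring classes and per class.
#'
#' @param em expression matrix (log2 CPM + 1).
#' @param samples sample table aligned to `em` columns.
#' @param thresholds a [rewire_thresholds()] object.
#' @param n_randomizations number of label permutations (study default 5000).
#' @param seed integer seed for the permutation stream.
#' @return list with `pooled` (an eFDR record: threshold, observed and mean
#'   scrambled exceedances, n_randomizations, efdr), `per_class`, and the
#'   matrix of scrambled per-class counts.
#' @export
efdr_rewiring <- function(em, samples, thresholds = rewire_thresholds(),
                          n_randomizations = 5000, seed = 1) {
  stopifnot(n_randomizations >= 1)
  samples <- samples[match(colnames(em), samples$sample_id), , drop = FALSE]
  outcome <- check_outcome(samples$outcome)
  em <- em[apply(em, 1, var) > 0, , drop = FALSE]
  obs <- consensus_counts(em, outcome, thresholds)
  set.seed(seed)
  scram <- matrix(0L, nrow = n_randomizations, ncol = length(obs),
                  dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_randomizations)) {
    perm <- sample(outcome)
    scram[i, ] <- consensus_counts(em, perm, thresholds)
  }
  pooled <- efdr_result(sum(obs), rowSums(scram), n_randomizations,
                        threshold = thresholds$present_abs_r)
  per_class <- lapply(setNames(nm = names(obs)), function(k) {
    suppressWarnings(efdr_result(obs[[k]], scram[, k], n_randomizations,
                                 thresholds$present_abs_r))
  })
  list(pooled = pooled, per_class = per_class,
       observed_counts = obs, scrambled_counts = scram)
}
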