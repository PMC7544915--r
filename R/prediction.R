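#' Select a year-adjusted differential-expression feature panel
#'
#' Combines both cohorts (years) of `AI_PREG` and `NON_PREG` samples and
#' tests each gene with the NB Wald model including year as a fixed effect;
#' genes with Benjamini-Hochberg FDR below `fdr_threshold` (default 0.03)
#' form the panel. Selection is deterministic. Note: selecting on the
#' combined cohorts before train/test splitting follows the original
#' protocol and is itself a mild information leak; see the methods vignette.
#'
#' @param counts count matrix covering both years.
#' @param samples sample table with `year`.
#' @param fdr_threshold BH FDR threshold (default 0.03).
#' @param focal,reference outcome groups contrasted (defaults `AI_PREG` vs
#'   `NON_PREG`).
#' @return list of class `feature_panel`: `genes`, per-gene `table`, and
#'   the contrast.
#' @export
select_panel <- function(counts, samples, fdr_threshold = 0.03,
                         focal = "AI_PREG", reference = "NON_PREG") {
  samples <- match_samples(counts, samples)
  keep <- samples$outcome %in% c(focal, reference)
  cm <- counts[, keep, drop = FALSE]
  sm <- samples[keep, , drop = FALSE]
  if (length(unique(sm$year)) < 2) stop("select_panel needs two cohorts (years)")
  for (y in unique(sm$year))
    if (length(unique(sm$outcome[sm$year == y])) < 2)
      stop("year ", y, " lacks one of the outcome groups")
  groups <- factor(as.character(sm$outcome), levels = c(reference, focal))
  nf <- normalization_factors(cm)
  phi <- nb_dispersion(cm, interaction(groups, sm$year), nf)
  wald <- nb_wald_test(cm, groups, phi, nf, year = sm$year)
  tab <- data.frame(gene_id = rownames(cm),
                    log2_fold_change = wald$log2_fold_change,
                    p = wald$p, fdr = p.adjust(wald$p, method = "BH"),
                    stringsAsFactors = FALSE)
  genes <- tab$gene_id[tab$fdr < fdr_threshold]
  if (!length(genes))
    stop("empty panel at FDR < ", fdr_threshold, "; consider relaxing the threshold")
  structure(list(genes = genes, table = tab,
                 contrast = c(focal = focal, reference = reference),
                 fdr_threshold = fdr_threshold),
            class = "feature_panel")
}

#' Variance-stabilizing transform of panel counts
#'
#' `log2(normalized count + 0.5)` per gene (TMM effective libraries),
#' followed by per-gene centering and scaling. Transform parameters (mean,
#' SD) are estimated on the training cohort only and reused unchanged on
#' test data; a gene with zero training variance gets scale 1 and is
#' flagged.
#'
#' @param counts count matrix (all samples to transform).
#' @param genes panel gene ids.
#' @param params optional parameter list from a previous call (training
#'   fit); when `NULL`, parameters are estimated from `counts`.
#' @return list: `x` (samples x genes transformed matrix) and `params`
#'   (`mean`, `sd`, `zero_var` per gene).
#' @export
vst_transform <- function(counts, genes, params = NULL) {
  miss <- setdiff(genes, rownames(counts))
  if (length(miss)) stop("panel genes absent from matrix: ",
                         paste(miss, collapse = ", "))
  nf <- normalization_factors(counts)
  z <- log2(normalized_counts(counts, nf)[genes, , drop = FALSE] + 0.5)
  if (is.null(params)) {
    mu <- rowMeans(z)
    sdv <- apply(z, 1, sd)
    zero <- sdv == 0
    if (any(zero)) rw_msg(sum(zero), " zero-variance panel gene(s); scale set to 1")
    sdv[zero] <- 1
    params <- list(mean = mu, sd = sdv, zero_var = zero)
  }
  x <- t((z - params$mean[genes]) / params$sd[genes])
  list(x = x, params = params)
}

#' Classifier registry
#'
#' A small registry of classifier families standing in for a wide
#' algorithm screen: random forest (`ranger`), diagonal linear discriminant
#' (in-package, suited to p >> n), ridge-regularized logistic regression
#' (`glmnet`), linear support-vector machine (`e1071`), and k-nearest
#' neighbours (`class`). Each entry is a list with `fit(x, y, seed)`
#' returning a model and `predict(model, x)` returning class labels.
#'
#' @return named list of classifier entries.
#' @export
classifier_registry <- function() {
  list(
    rf = list(
      fit = function(x, y, seed) {
        ranger::ranger(x = x, y = y, num.trees = 500,
                       mtry = max(1, floor(sqrt(ncol(x)))),
                       importance = "impurity", seed = seed)
      },
      predict = function(model, x) predict(model, data = x)$predictions),
    dlda = list(
      fit = function(x, y, seed) dlda_fit(x, y),
      predict = function(model, x) dlda_predict(model, x)),
    glmnet_ridge = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 1)
      },
      predict = function(model, x) {
        lv <- model$classnames
        factor(lv[1 + (predict(model, x, type = "response")[, 1] > 0.5)],
               levels = lv)
      }),
    svm_linear = list(
      fit = function(x, y, seed) e1071::svm(x, y, kernel = "linear"),
      predict = function(model, x) predict(model, x)),
    knn = list(
      fit = function(x, y, seed) list(x = x, y = y, k = 3),
      predict = function(model, x)
        class::knn(model$x, x, model$y, k = model$k))
  )
}

# Diagonal linear discriminant: Gaussian class centroids with pooled
# per-feature variances; the standard p >> n genomics baseline.
dlda_fit <- function(x, y) {
  y <- droplevels(as.factor(y))
  mu <- t(vapply(levels(y), function(l) colMeans(x[y == l, , drop = FALSE]),
                 numeric(ncol(x))))
  v <- colSums((x - mu[as.integer(y), , drop = FALSE])^2) / (nrow(x) - nlevels(y))
  list(levels = levels(y), mu = mu, v = pmax(v, 1e-8))
}

dlda_predict <- function(model, x) {
  d <- vapply(seq_along(model$levels), function(i)
    rowSums(sweep(x, 2, model$mu[i, ])^2 / rep(model$v, each = nrow(x))),
    numeric(nrow(x)))
  factor(model$levels[apply(matrix(d, nrow = nrow(x)), 1, which.min)],
         levels = model$levels)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated accuracy screen over the classifier registry
#'
#' Stratified k-fold cross-validation on the training cohort; algorithms
#' reaching `flag_threshold` accuracy are flagged for the seed sweep.
#'
#' @param x training matrix (samples x features).
#' @param y training labels (two-level factor).
#' @param registry classifier registry (default [classifier_registry()]).
#' @param k_folds number of stratified folds (default 4).
#' @param seed integer seed (folds and fits).
#' @param flag_threshold accuracy flag level (default 0.9, the study's
#'   screen cut).
#' @return data.frame with `algorithm`, `accuracy`, `flagged`.
#' @export
screen_algorithms <- function(x, y, registry = classifier_registry(),
                              k_folds = 4, seed = 1, flag_threshold = 0.9) {
  y <- droplevels(as.factor(y))
  k_folds <- min(k_folds, min(table(y)))
  fold <- stratified_folds(y, k_folds, seed)
  acc <- vapply(names(registry), function(name) {
    alg <- registry[[name]]
    correct <- 0L
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      model <- suppressWarnings(alg$fit(x[tr, , drop = FALSE], y[tr], seed + f))
      pred <- alg$predict(model, x[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    correct / length(y)
  }, numeric(1))
  data.frame(algorithm = names(registry), accuracy = acc,
             flagged = acc >= flag_threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classification accuracy
#'
#' Fraction of samples correctly classified.
#'
#' @param pred predicted labels.
#' @param truth true labels (same length).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(as.character(pred) == as.character(truth))
}

#' Exact accuracy p-value against the no-information rate
#'
#' One-sided exact binomial test of `n_correct` successes in `n` trials
#' against the majority-class fraction of the test set.
#'
#' @param n_correct correctly classified samples.
#' @param n number of test samples.
#' @param p0 no-information (majority-class) success probability.
#' @return p-value.
#' @export
accuracy_pvalue <- function(n_correct, n, p0) {
  binom.test(n_correct, n, p = p0, alternative = "greater")$p.value
}

#' Repeated-seed prediction sweep
#'
#' Trains the chosen algorithm once per seed (`base_seed + i`) on the
#' training cohort, blind-predicts the test cohort, and summarizes the
#' distribution of correct classifications (the study runs 2000 seeds of a
#' random forest), along with mean impurity importance per gene when the
#' algorithm provides it.
#'
#' @param x_train,y_train training matrix and labels.
#' @param x_test test matrix.
#' @param y_test optional true test labels; enables accuracy summaries.
#' @param algorithm registry entry name (default `"rf"`).
#' @param n_runs number of seeds (study default 2000).
#' @param base_seed run i uses seed `base_seed + i`.
#' @param registry classifier registry.
#' @return list: `runs` (per-seed `seed`, `n_correct`, `accuracy`),
#'   `histogram` (count of runs per `n_correct`), `importance` (mean score
#'   and rank per gene, or `NULL`), `predictions` (runs x test samples).
#' @export
seed_sweep <- function(x_train, y_train, x_test, y_test = NULL,
                       algorithm = "rf", n_runs = 2000, base_seed = 1,
                       registry = classifier_registry()) {
  stopifnot(n_runs >= 1)
  alg <- registry[[algorithm]]
  if (is.null(alg)) stop("unknown algorithm: ", algorithm)
  y_train <- droplevels(as.factor(y_train))
  preds <- matrix(NA_character_, nrow = n_runs, ncol = nrow(x_test),
                  dimnames = list(NULL, rownames(x_test)))
  imp <- NULL
  for (i in seq_len(n_runs)) {
    seed <- base_seed + i
    set.seed(seed)
    model <- suppressWarnings(alg$fit(x_train, y_train, seed))
    preds[i, ] <- as.character(alg$predict(model, x_test))
    if (algorithm == "rf") {
      vi <- ranger::importance(model)
      imp <- if (is.null(imp)) vi else imp + vi
    }
  }
  runs <- data.frame(seed = base_seed + seq_len(n_runs))
  histogram <- NULL
  if (!is.null(y_test)) {
    runs$n_correct <- apply(preds, 1, function(p)
      sum(p == as.character(y_test)))
    runs$accuracy <- runs$n_correct / nrow(x_test)
    histogram <- as.data.frame(table(
      n_correct = factor(runs$n_correct, levels = 0:nrow(x_test))),
      stringsAsFactors = FALSE)
    names(histogram) <- c("n_correct", "n_runs")
    histogram$n_correct <- as.integer(as.character(histogram$n_correct))
  }
  importance <- NULL
  if (!is.null(imp)) {
    importance <- data.frame(gene_id = names(imp), importance = imp / n_runs,
                             row.names = NULL, stringsAsFactors = FALSE)
    importance <- importance[order(-importance$importance), ]
    importance$rank <- seq_len(nrow(importance))
  }
  list(runs = runs, histogram = histogram, importance = importance,
       predictions = preds)
}
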