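#' @keywords internal
"_PACKAGE"

OUTCOME_LEVELS <- c("AI_PREG", "NB_PREG", "NON_PREG")

REWIRE_CLASSES <- c("GAINED_POSITIVE", "GAINED_NEGATIVE",
                    "LOST_POSITIVE", "LOST_NEGATIVE",
                    "INVERTED", "NONE")

#' @importFrom utils read.delim write.table packageVersion
#' @importFrom stats cor pnorm p.adjust quantile median var sd rnbinom rnorm
#'   runif setNames aggregate lowess approx glm poisson coef dbinom phyper
#'   binom.test predict ks.test rbinom
NULL

rw_msg <- function(...) message("[rewirenet] ", ...)

#' Validate a counts matrix
#'
#' Checks the invariants of a count matrix: a numeric matrix of non-negative
#' integral values with unique, non-empty feature (row) and sample (column)
#' names and at least two samples.
#'
#' @param counts numeric matrix, features in rows, samples in columns.
#' @param layer optional layer tag, `"mRNA"` or `"miRNA"`, stored as an
#'   attribute.
#' @return the validated matrix (in storage mode double, integral values),
#'   invisibly unchanged apart from the `layer` attribute.
#' @export
validate_counts <- function(counts, layer = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (ncol(counts) < 2) stop("at least 2 samples required")
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("non-integral counts are not allowed")
  storage.mode(counts) <- "double"
  if (!is.null(layer)) {
    layer <- match.arg(layer, c("mRNA", "miRNA"))
    attr(counts, "layer") <- layer
  }
  counts
}

# canonical unordered pair ordering: a < b lexicographically
canonical_pairs <- function(ids) {
  ids <- sort(ids)
  n <- length(ids)
  if (n < 2) return(data.frame(feature_a = character(), feature_b = character()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(feature_a = ids[idx[, "row"]], feature_b = ids[idx[, "col"]],
             stringsAsFactors = FALSE)
}

check_outcome <- function(x) {
  bad <- setdiff(unique(as.character(x)), OUTCOME_LEVELS)
  if (length(bad))
    stop("unknown outcome label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(OUTCOME_LEVELS, collapse = "/"), ")")
  factor(as.character(x), levels = OUTCOME_LEVELS)
}

# Draw independent sub-seeds (< 2^31) from one user seed, so stages that run
# in sequence do not share permutation streams.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
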