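#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV input has one feature per row: the first column holds feature ids, the
#' header row holds sample ids, and values are raw read counts. Lines starting
#' with `#` are ignored. MTX input is a MatrixMarket triplet file with sidecar
#' `features.tsv` and `samples.tsv` id files (one id per line) in the same
#' directory.
#'
#' @param path path to the counts TSV or `.mtx` file.
#' @param layer `"mRNA"` or `"miRNA"`; recorded as an attribute on the result.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtx"`.
#' @return a validated numeric matrix of counts (features x samples) with a
#'   `layer` attribute.
#' @export
read_counts <- function(path, layer = c("mRNA", "miRNA"),
                        format = c("auto", "tsv", "mtx")) {
  layer <- match.arg(layer)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    fpath <- file.path(dir, "features.tsv")
    spath <- file.path(dir, "samples.tsv")
    if (!file.exists(fpath) || !file.exists(spath))
      stop("MTX input needs sidecar features.tsv and samples.tsv next to ", path)
    rn <- readLines(fpath); cn <- readLines(spath)
    rn <- rn[nzchar(rn)]; cn <- cn[nzchar(cn)]
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- tryCatch(
      read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                 check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = NA),
      error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
    if (ncol(df) < 2) stop("parse error in ", path, ": need id column plus samples")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!apply(df[, -1, drop = FALSE], 1,
                          function(r) all(grepl("^\\s*-?[0-9.eE+-]+\\s*$", r))))[1]
      stop("parse error in ", path, ": non-numeric count at data line ",
           if (is.na(bad)) "?" else bad)
    }
    rownames(m) <- ids
  }
  validate_counts(m, layer = layer)
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `outcome` (one of `AI_PREG`,
#' `NB_PREG`, `NON_PREG`) and `year` (integer cohort label).
#'
#' @param path TSV path.
#' @return data.frame with `sample_id`, factor `outcome`, integer `year`.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "outcome", "year")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample table")
  df$outcome <- check_outcome(df$outcome)
  df$year <- as.integer(df$year)
  df[need]
}

#' Read a feature annotation table
#'
#' Expects a TSV with columns `feature_id`, `biotype`, `length_bp` and
#' optionally `symbol`.
#'
#' @param path TSV path.
#' @return data.frame with validated `length_bp > 0` and non-empty `biotype`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("feature_id", "biotype", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (!"symbol" %in% names(df)) df$symbol <- NA_character_
  df$length_bp <- as.numeric(df$length_bp)
  if (any(!is.finite(df$length_bp)) || any(df$length_bp <= 0))
    stop("annotation length_bp must be positive")
  if (any(!nzchar(df$biotype))) stop("annotation biotype must be non-empty")
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id in annotation")
  df[c("feature_id", "biotype", "length_bp", "symbol")]
}

#' Align a sample table to a count matrix
#'
#' @param counts count matrix.
#' @param samples sample table (`read_sample_table()` format).
#' @return the sample table reordered to match `colnames(counts)`.
#' @export
match_samples <- function(counts, samples) {
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss))
    stop("samples absent from metadata: ", paste(miss, collapse = ", "))
  samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
}

library_sizes <- function(counts) {
  ls <- colSums(counts)
  if (any(ls <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[ls <= 0], collapse = ", "))
  ls
}

#' Counts per million
#'
#' CPM of feature f in sample s is `counts[f, s] / library_size(s) * 1e6`,
#' with the library size taken as the column sum over all features present in
#' `counts`. Library sizes may be supplied to keep the scaling of a subsetted
#' matrix anchored to the full library (the pipeline computes CPM on the raw
#' matrix before any subsetting).
#'
#' @param counts count matrix.
#' @param log if `TRUE`, return `log2(CPM + prior)`.
#' @param prior pseudocount used when `log = TRUE`.
#' @param lib_sizes optional named library sizes; defaults to `colSums(counts)`.
#' @return numeric matrix with attribute `unit` set to `"CPM"` or `"LOG2_CPM"`.
#' @export
compute_cpm <- function(counts, log = FALSE, prior = 1, lib_sizes = NULL) {
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  } else if (!is.null(colnames(counts)) && !is.null(names(lib_sizes))) {
    lib_sizes <- lib_sizes[colnames(counts)]
  }
  if (length(lib_sizes) != ncol(counts) || anyNA(lib_sizes))
    stop("lib_sizes missing for some samples")
  if (any(lib_sizes <= 0))
    stop("zero library size for sample(s): ",
         paste(if (!is.null(colnames(counts))) colnames(counts)[lib_sizes <= 0]
               else which(lib_sizes <= 0), collapse = ", "))
  m <- sweep(counts, 2, lib_sizes, "/") * 1e6
  if (log) {
    m <- log2(m + prior)
    attr(m, "unit") <- "LOG2_CPM"
  } else attr(m, "unit") <- "CPM"
  m
}

#' Fragments per kilobase per million
#'
#' FPKM of feature f in sample s is
#' `counts[f, s] / (length_bp(f) / 1e3) / (library_size(s) / 1e6)`.
#'
#' @inheritParams compute_cpm
#' @param annotation feature annotation with `feature_id` and `length_bp`.
#' @return numeric matrix with attribute `unit = "FPKM"`.
#' @export
compute_fpkm <- function(counts, annotation, lib_sizes = NULL) {
  len <- annotation$length_bp[match(rownames(counts), annotation$feature_id)]
  if (anyNA(len))
    stop("missing transcript length for feature(s): ",
         paste(rownames(counts)[is.na(len)], collapse = ", "))
  if (is.null(lib_sizes)) lib_sizes <- library_sizes(counts)
  lib_sizes <- lib_sizes[colnames(counts)]
  m <- sweep(counts, 1, len / 1e3, "/")
  m <- sweep(m, 2, lib_sizes / 1e6, "/")
  attr(m, "unit") <- "FPKM"
  m
}

#' Filter lowly expressed features
#'
#' Retains features with CPM at or above `min_cpm` in at least `min_samples`
#' samples (inclusive thresholds). The defaults reproduce the study design:
#' 2 CPM for the PWBC mRNA layer, 1 CPM for the plasma miRNA layer, in five or
#' more of the samples.
#'
#' @param counts count matrix to filter.
#' @param cpm optional CPM matrix aligned with `counts`; computed from
#'   `counts` when omitted. Pass a CPM matrix computed on the *raw* matrix to
#'   filter against full library sizes.
#' @param min_cpm CPM threshold (default 2; use 1 for miRNA).
#' @param min_samples minimum number of samples meeting the threshold.
#' @return filtered count matrix; attribute `filter_report` records counts
#'   before/after.
#' @export
filter_expressed <- function(counts, cpm = NULL, min_cpm = 2, min_samples = 5) {
  if (min_samples > ncol(counts))
    stop("min_samples (", min_samples, ") exceeds number of samples (",
         ncol(counts), ")")
  if (is.null(cpm)) cpm <- compute_cpm(counts)
  cpm <- cpm[rownames(counts), colnames(counts), drop = FALSE]
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "layer") <- attr(counts, "layer")
  attr(out, "filter_report") <- list(step = "filter_expressed",
                                     n_in = nrow(counts), n_out = sum(keep),
                                     min_cpm = min_cpm, min_samples = min_samples)
  out
}

#' Subset a count matrix by biotype
#'
#' Features without an annotation entry are dropped with a logged count. An
#' empty result raises a warning, not an error.
#'
#' @param counts count matrix.
#' @param annotation feature annotation table.
#' @param biotype biotype to keep, e.g. `"protein_coding"` or `"miRNA"`.
#' @return subsetted count matrix with a `filter_report` attribute.
#' @export
subset_biotype <- function(counts, annotation, biotype) {
  bt <- annotation$biotype[match(rownames(counts), annotation$feature_id)]
  n_unann <- sum(is.na(bt))
  if (n_unann) rw_msg(n_unann, " feature(s) without annotation dropped")
  keep <- !is.na(bt) & bt == biotype
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no features with biotype '", biotype, "' retained")
  attr(out, "layer") <- attr(counts, "layer")
  attr(out, "filter_report") <- list(step = "subset_biotype", biotype = biotype,
                                     n_in = nrow(counts), n_out = nrow(out),
                                     n_unannotated = n_unann)
  out
}

#' Write a matrix as a counts-style TSV
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_col name of the first (feature id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
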