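test_that("TSV counts are parsed and validated", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "feature_id\ts1\ts2", "g1\t5\t0", "g2\t2\t7",
               "g3\t0\t0"), tsv)
  cm <- read_counts(tsv, layer = "mRNA")
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(unname(cm["g1", ]), c(5, 0))
  expect_identical(attr(cm, "layer"), "mRNA")

  writeLines(c("feature_id\ts1\ts2", "g1\t-1\t0", "g2\t1\t1"), tsv)
  expect_error(read_counts(tsv), "negative")
  writeLines(c("feature_id\ts1\ts2", "g1\t2.5\t0", "g2\t1\t1"), tsv)
  expect_error(read_counts(tsv), "non-integral")
  writeLines(c("feature_id\ts1\ts2", "g1\t1\t0", "g1\t1\t1"), tsv)
  expect_error(read_counts(tsv), "duplicate")
})

test_that("MTX triplet input with sidecar ids round-trips", {
  dir <- tempfile()
  dir.create(dir)
  m <- matrix(c(0, 3, 1, 0, 2, 5), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(dir, "counts.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "samples.tsv"))
  cm <- read_counts(file.path(dir, "counts.mtx"), layer = "miRNA")
  expect_equal(cm, m, ignore_attr = TRUE)
  expect_equal(rownames(cm), rownames(m))
})

test_that("CPM follows counts / library size x 1e6 and columns sum to 1e6", {
  cm <- rbind(g1 = c(100, 3), g2 = c(999900 - 100, 599997))
  colnames(cm) <- c("s1", "s2")
  cm["g2", "s1"] <- 1e6 - 100  # library size exactly 1e6
  cm["g2", "s2"] <- 6e5 - 3
  em <- compute_cpm(cm)
  expect_equal(em["g1", "s1"], 100)
  expect_equal(em["g1", "s2"], 5)  # 3 / 600000 * 1e6
  expect_equal(unname(colSums(em)), c(1e6, 1e6), tolerance = 1e-6)
  zero <- rbind(a = c(0, 0), b = c(1, 1))
  colnames(zero) <- c("s1", "s2")
  expect_equal(compute_cpm(zero)["a", "s1"], 0)
})

test_that("zero library size is rejected with the sample named", {
  cm <- rbind(g1 = c(1, 0), g2 = c(2, 0))
  colnames(cm) <- c("ok", "empty")
  expect_error(compute_cpm(cm), "empty")
})

test_that("FPKM scales by transcript kilobases and library millions", {
  cm <- rbind(g1 = 100, g2 = 100, g3 = 0, filler = 1e6 - 200)
  colnames(cm) <- "s1"
  ann <- data.frame(feature_id = c("g1", "g2", "g3", "filler"),
                    biotype = "protein_coding",
                    length_bp = c(1000, 2000, 500, 1000),
                    symbol = NA)
  fp <- compute_fpkm(cm, ann)
  expect_equal(fp["g1", 1], 100)
  expect_equal(fp["g2", 1], 50)
  expect_equal(fp["g3", 1], 0)
  expect_error(compute_fpkm(cm, ann[-2, ]), "g2")
})

test_that("expression filter keeps features at the inclusive boundary", {
  set.seed(1)
  n <- 17
  lib <- rep(1e6, n)
  cm <- matrix(0, nrow = 3, ncol = n,
               dimnames = list(c("boundary", "four", "zero"),
                               sprintf("s%02d", 1:n)))
  cm["boundary", 1:5] <- 2   # exactly 2 CPM in exactly 5 samples
  cm["four", 1:4] <- 50
  filler <- matrix(rep((1e6 - colSums(cm)) / 2, each = 2), nrow = 2,
                   dimnames = list(c("f1", "f2"), colnames(cm)))
  full <- rbind(cm, filler)
  kept <- filter_expressed(full, min_cpm = 2, min_samples = 5)
  expect_true("boundary" %in% rownames(kept))
  expect_false("four" %in% rownames(kept))
  expect_false("zero" %in% rownames(kept))

  # idempotence on the same CPM basis
  cpm_raw <- compute_cpm(full)
  once <- filter_expressed(full, cpm_raw, 2, 5)
  twice <- filter_expressed(once, cpm_raw, 2, 5)
  expect_equal(rownames(once), rownames(twice))

  expect_error(filter_expressed(full, min_samples = 18), "exceeds")
})

test_that("biotype subsetting drops unannotated features with a log", {
  cm <- rbind(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 6))
  colnames(cm) <- c("s1", "s2")
  ann <- data.frame(feature_id = c("g1", "g2"),
                    biotype = c("protein_coding", "lncRNA"),
                    length_bp = c(1000, 1000), symbol = NA)
  expect_message(out <- subset_biotype(cm, ann, "protein_coding"), "without annotation")
  expect_equal(rownames(out), "g1")
  expect_warning(subset_biotype(cm, ann, "snoRNA"), "no features")
  # identity when all features match
  ann2 <- data.frame(feature_id = rownames(cm), biotype = "miRNA",
                     length_bp = 80, symbol = NA)
  expect_equal(rownames(subset_biotype(cm, ann2, "miRNA")), rownames(cm))
})

test_that("sample and annotation tables are validated", {
  f <- tempfile()
  writeLines(c("sample_id\toutcome\tyear", "s1\tAI_PREG\t1", "s2\tNON_PREG\t1"), f)
  st <- read_sample_table(f)
  expect_s3_class(st$outcome, "factor")
  writeLines(c("sample_id\toutcome\tyear", "s1\tMAYBE\t1"), f)
  expect_error(read_sample_table(f), "MAYBE")
  writeLines(c("feature_id\tbiotype\tlength_bp", "g1\tmiRNA\t-5"), f)
  expect_error(read_annotation(f), "positive")
})
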