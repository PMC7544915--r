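# shared two-year fixture with a strong planted group effect
pred_fixture <- local({
  sim <- NULL
  function() {
    if (is.null(sim))
      sim <<- simulate_dataset(simulation_spec(
        n_genes = 300, n_mirna = 10, n_years = 2,
        de = plant_de(20, log2_fc = 3, group = "NON_PREG"), seed = 17))
    sim
  }
})

test_that("year-adjusted panel selection keeps group effects, drops year effects", {
  sim <- pred_fixture()
  pan <- select_panel(sim$counts_mrna, sim$samples, fdr_threshold = 0.03)
  planted <- sim$truth$de$gene_id
  expect_gte(sum(planted %in% pan$genes), 18)
  # year effects alone must not enter the panel: non-planted selections rare
  expect_lte(sum(!pan$genes %in% planted), max(3, 0.1 * length(pan$genes)))
  # deterministic
  pan2 <- select_panel(sim$counts_mrna, sim$samples, fdr_threshold = 0.03)
  expect_identical(pan$genes, pan2$genes)
  one_year <- sim$samples[sim$samples$year == 2, ]
  expect_error(select_panel(sim$counts_mrna[, one_year$sample_id], one_year),
               "two cohorts")
})

test_that("the variance-stabilizing transform is anchored to training parameters", {
  sim <- pred_fixture()
  genes <- sim$truth$de$gene_id[1:5]
  cm <- sim$counts_mrna[, 1:8]
  vt <- vst_transform(cm, genes)
  expect_equal(dim(vt$x), c(8L, 5L))
  expect_equal(unname(colMeans(vt$x)), rep(0, 5), tolerance = 1e-12)
  # test-set transform reuses training parameters unchanged
  vt2 <- vst_transform(sim$counts_mrna[, 9:16], genes, params = vt$params)
  expect_identical(vt2$params, vt$params)
  # doubling all counts of every sample leaves values unchanged
  vt3 <- vst_transform(2 * cm, genes, params = NULL)
  expect_equal(vt3$x, vst_transform(cm, genes)$x, tolerance = 0.02)
  # constant gene in identical libraries: centred to zero with scale 1
  col <- c(const = 50, g1 = 200, g2 = 30)
  cm3 <- matrix(col, nrow = 3, ncol = 6,
                dimnames = list(names(col), paste0("s", 1:6)))
  expect_message(vt4 <- vst_transform(cm3, "const"), "zero-variance")
  expect_equal(unname(vt4$x[, "const"]), rep(0, 6), tolerance = 1e-12)
})

test_that("every registry family separates a linearly separable panel", {
  set.seed(20)
  n <- 12
  x <- matrix(rnorm(n * 30), nrow = n,
              dimnames = list(sprintf("t%02d", 1:n), sprintf("f%02d", 1:30)))
  y <- factor(rep(c("AI_PREG", "NON_PREG"), each = 6))
  x[y == "AI_PREG", 1:10] <- x[y == "AI_PREG", 1:10] + 5
  scr <- screen_algorithms(x, y, seed = 1)
  expect_equal(nrow(scr), 5L)
  expect_true(all(scr$accuracy >= 0.9))
  expect_true(all(scr$flagged))
  # registry order does not affect results
  reg <- classifier_registry()
  scr2 <- screen_algorithms(x, y, registry = rev(reg), seed = 1)
  expect_equal(scr$accuracy[match(scr2$algorithm, scr$algorithm)], scr2$accuracy)
})

test_that("label-permuted training data scores near the majority fraction", {
  set.seed(21)
  n <- 12
  x <- matrix(rnorm(n * 30), nrow = n,
              dimnames = list(sprintf("t%02d", 1:n), sprintf("f%02d", 1:30)))
  y <- factor(rep(c("AI_PREG", "NON_PREG"), each = 6))
  scr <- screen_algorithms(x, sample(y), seed = 2)
  expect_true(all(scr$accuracy <= 0.85))
})

test_that("the seed sweep is deterministic and summarizes runs", {
  set.seed(22)
  x <- matrix(rnorm(240), nrow = 12,
              dimnames = list(sprintf("t%02d", 1:12), sprintf("f%02d", 1:20)))
  y <- factor(rep(c("AI_PREG", "NON_PREG"), each = 6))
  x[y == "AI_PREG", 1:8] <- x[y == "AI_PREG", 1:8] + 4
  # training data duplicated as test: accuracy 1 for all seeds
  sw <- seed_sweep(x, y, x, y, "rf", n_runs = 10, base_seed = 3)
  expect_true(all(sw$runs$accuracy == 1))
  expect_equal(sum(sw$histogram$n_runs), 10L)
  sw2 <- seed_sweep(x, y, x, y, "rf", n_runs = 10, base_seed = 3)
  expect_identical(sw$predictions, sw2$predictions)
  expect_equal(sw$importance$rank, seq_len(nrow(sw$importance)))
  expect_true(all(sw$importance$importance >= 0))
})

test_that("accuracy and its exact p-value follow the stated definitions", {
  expect_equal(accuracy(c("A", "A", "B"), c("A", "A", "B")), 1)
  expect_equal(accuracy(c("A", "A"), c("B", "B")), 0)
  expect_equal(accuracy(rep(c("A", "B"), c(10, 1)), rep("A", 11)), 10 / 11)
  expect_error(accuracy("A", c("A", "B")), "mismatch")
  expect_equal(accuracy_pvalue(10, 11, 6 / 11),
               binom.test(10, 11, 6 / 11, alternative = "greater")$p.value)
  expect_lte(accuracy_pvalue(11, 11, 6 / 11), 0.01)
})
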