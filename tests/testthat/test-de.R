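test_that("normalization factors behave on constructed libraries", {
  set.seed(2)
  base <- rnbinom(500, mu = 200, size = 5) + 1
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- paste0("g", 1:500)
  nf <- normalization_factors(m, "TMM")
  expect_equal(unname(nf$factors), c(1, 1), tolerance = 1e-8)
  expect_equal(exp(mean(log(nf$factors))), 1, tolerance = 1e-12)

  # sample2 doubled: median-of-ratios gives {1/sqrt(2), sqrt(2)}
  m2 <- cbind(s1 = base, s2 = 2 * base)
  rownames(m2) <- paste0("g", 1:500)
  mor <- normalization_factors(m2, "median_of_ratios")
  expect_equal(unname(mor$factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  # gene-order invariance
  set.seed(3)
  m3 <- rand_counts(300, 4)
  perm <- sample(nrow(m3))
  expect_equal(normalization_factors(m3, "TMM")$factors,
               normalization_factors(m3[perm, ], "TMM")$factors)
})

test_that("TMM agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  mu <- exp(rnorm(1500, log(100), 1.5))
  m <- matrix(rnbinom(1500 * 6, mu = rep(mu, 6), size = 5), ncol = 6,
              dimnames = list(paste0("g", 1:1500), paste0("s", 1:6)))
  ours <- normalization_factors(m, "TMM")$factors
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})

test_that("dispersion estimation recovers simulation parameters", {
  set.seed(5)
  groups <- rep(c("A", "B"), each = 6)
  # Poisson counts: dispersion near zero
  mp <- matrix(rpois(2000 * 12, lambda = 80), ncol = 12,
               dimnames = list(paste0("g", 1:2000), paste0("s", 1:12)))
  php <- nb_dispersion(mp, groups, shrink_weight = 0)
  expect_lt(median(php), 0.05)
  # NB dispersion 0.4 recovered within +/- 0.15
  mn <- matrix(rnbinom(5000 * 12, mu = 100, size = 1 / 0.4), ncol = 12,
               dimnames = list(paste0("g", 1:5000), paste0("s", 1:12)))
  phn <- nb_dispersion(mn, groups, shrink_weight = 0)
  expect_lt(abs(median(phn) - 0.4), 0.15)
  # constant gene in equal libraries (identical samples) has dispersion 0
  col <- c(const = 50, g1 = 120, g2 = 80, g3 = 20)
  mc <- matrix(col, nrow = 4, ncol = 12,
               dimnames = list(names(col), paste0("s", 1:12)))
  expect_equal(unname(nb_dispersion(mc, groups, shrink_weight = 0)["const"]), 0)
  expect_true(all(nb_dispersion(mn[1:50, ], groups) >= 0))
})

test_that("the conditional NB exact test matches its closed forms", {
  # identical group sums: the observed split is the most likely one
  expect_equal(rewirenet:::nb_exact_pvalue(10, 10, 1, 1, 0), 1)
  # dispersion 0, totals 10 vs 0 in equal unit libraries
  expect_equal(rewirenet:::nb_exact_pvalue(10, 0, 1, 1, 0), 2 * 0.5^10)
  expect_error(rewirenet:::nb_exact_pvalue(1, 1, 1, 1, -0.1), "dispersion")
  # random small instances against the enumeration oracle
  set.seed(6)
  for (i in 1:60) {
    t <- sample(0:30, 1); ya <- if (t == 0) 0 else sample(0:t, 1)
    phi <- sample(c(0, 0.05, 0.2, 0.7), 1)
    expect_equal(rewirenet:::nb_exact_pvalue(ya, t - ya, 6, 5, phi),
                 nb_exact_oracle(ya, t - ya, 6, 5, phi), tolerance = 1e-9)
  }
})

test_that("large-total limits agree with enumeration near the cap", {
  for (frac in c(0.48, 0.55, 0.62)) {
    t <- 25000; ya <- round(t * frac)
    expect_equal(rewirenet:::nb_exact_pvalue(ya, t - ya, 6, 5, 0.2),
                 nb_exact_oracle(ya, t - ya, 6, 5, 0.2), tolerance = 0.01)
  }
})

test_that("the Wald test is calibrated under the null and powered", {
  set.seed(7)
  groups <- factor(rep(c("A", "B"), c(6, 5)), levels = c("A", "B"))
  mnull <- rand_counts(2000, 11, mu = 100, phi = 0.2)
  nf <- normalization_factors(mnull)
  w <- nb_wald_test(mnull, groups, rep(0.2, 2000), nf)
  expect_lt(suppressWarnings(ks.test(w$p, "punif")$statistic), 0.05)
  # planted 4-fold change, mean 100, dispersion 0.1: power >= 0.9 at p <= 0.03
  # (500 affected genes embedded in 1500 unchanged ones so normalization
  # keeps its most-genes-unchanged anchor)
  mu <- ifelse(groups == "B", 400, 100)
  mp <- rbind(
    matrix(rnbinom(500 * 11, mu = rep(mu, each = 500), size = 10), ncol = 11),
    matrix(rnbinom(1500 * 11, mu = 150, size = 10), ncol = 11))
  dimnames(mp) <- list(paste0("g", 1:2000), paste0("s", 1:11))
  wp <- nb_wald_test(mp, groups, rep(0.1, 2000), normalization_factors(mp))
  expect_gte(mean(wp$p[1:500] <= 0.03), 0.9)
  expect_true(all(wp$log2_fold_change[1:500] > 0))
})

test_that("a year covariate absorbs cohort confounding", {
  set.seed(8)
  year <- rep(c(1, 2), c(6, 6))
  groups <- factor(rep(c("A", "B", "A", "B"), each = 3), levels = c("A", "B"))
  # year shifts only, no group effect
  mu <- ifelse(year == 2, 300, 100)
  m <- matrix(rnbinom(400 * 12, mu = rep(mu, each = 400), size = 5), ncol = 12,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:12)))
  w <- nb_wald_test(m, groups, rep(0.2, 400), normalization_factors(m),
                    year = year)
  expect_gt(mean(w$p > 0.05), 0.9)
  expect_lt(suppressWarnings(ks.test(w$p, "punif")$statistic), 0.12)
})

test_that("the consensus rule is inclusive at the cut-off", {
  expect_true(consensus_de(0.02, 0.01))
  expect_false(consensus_de(0.02, 0.2))
  expect_true(consensus_de(0.03, 0.03))
  expect_equal(consensus_de(c(0.01, 0.5), c(0.01, 0.01)), c(TRUE, FALSE))
})

test_that("DE eFDR arithmetic, determinism and calibration grid", {
  set.seed(9)
  sim <- simulate_dataset(simulation_spec(
    n_genes = 120, n_mirna = 5, de = plant_de(8, log2_fc = 3), seed = 13,
    baseline_meanlog = log(60), baseline_sdlog = 0.8))
  a <- efdr_de(sim$counts_mrna, sim$samples, "AI_PREG", "NON_PREG",
               n_randomizations = 30, seed = 4)
  b <- efdr_de(sim$counts_mrna, sim$samples, "AI_PREG", "NON_PREG",
               n_randomizations = 30, seed = 4)
  expect_identical(a$scrambled_counts, b$scrambled_counts)
  expect_equal(a$efdr,
               min(1, mean(a$scrambled_counts) / a$observed_exceedances))
  cal <- calibrate_p_cut(sim$counts_mrna, sim$samples, "AI_PREG", "NON_PREG",
                         n_randomizations = 30, seed = 4,
                         p_grid = c(0.03, 0.003, 3e-4))
  expect_equal(nrow(cal$grid), 3L)
  expect_true(is.na(cal$p_cut) || cal$grid$efdr[cal$grid$p_cut == cal$p_cut] <= 0.05)
})

test_that("leave-one-out retention drops single-outlier genes", {
  set.seed(10)
  n_bg <- 150
  sm <- study_samples()[study_samples()$outcome != "NB_PREG", ]
  n <- nrow(sm)  # 6 AI + 5 NON
  m <- rand_counts(n_bg, n, mu = 150, phi = 0.05)
  colnames(m) <- sm$sample_id
  # outlier gene: flat except one extreme AI_PREG sample
  m["g0001", ] <- 100
  m["g0001", which(sm$outcome == "AI_PREG")[1]] <- 4000
  # uniform strong effect
  m["g0002", ] <- ifelse(sm$outcome == "AI_PREG", 800, 100)
  de <- de_test(m, sm, "AI_PREG", "NON_PREG")
  expect_true(de$consensus[de$gene_id == "g0002"])
  cand <- unique(c("g0002", de$gene_id[de$consensus], "g0001"))
  lp <- loo_validation(m, sm, "AI_PREG", "NON_PREG", cand)
  expect_true(lp[["g0002"]])
  expect_false(lp[["g0001"]])
  # retention implies consensus on the full data
  tab <- de_analysis(m, sm, "AI_PREG", "NON_PREG", run_efdr = FALSE)$table
  expect_true(all(is.na(tab$loo_pass) | !tab$loo_pass | tab$consensus))
  expect_equal(tab$direction, ifelse(tab$log2_fold_change >= 0, "UP", "DOWN"))
})
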