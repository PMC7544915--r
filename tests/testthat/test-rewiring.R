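test_that("edge classification reproduces the rewiring rules", {
  expect_equal(classify_edge(0.995, 0.05), "GAINED_POSITIVE")
  expect_equal(classify_edge(-0.995, 0.05), "GAINED_NEGATIVE")
  expect_equal(classify_edge(0.05, 0.995), "LOST_POSITIVE")
  expect_equal(classify_edge(0.05, -0.995), "LOST_NEGATIVE")
  expect_equal(classify_edge(0.98, -0.98), "INVERTED")  # gap 1.96 > 1.95
  expect_equal(classify_edge(0.5, 0.5), "NONE")
  # strict inequalities at every boundary
  expect_equal(classify_edge(0.99, 0.0), "NONE")
  expect_equal(classify_edge(0.995, 0.1), "NONE")
  expect_equal(classify_edge(0.975, -0.975), "NONE")  # gap exactly 1.95
})

test_that("classification is antisymmetric and single-valued", {
  set.seed(3)
  r1 <- runif(4000, -1, 1); r2 <- runif(4000, -1, 1)
  c12 <- classify_edge(r1, r2); c21 <- classify_edge(r2, r1)
  expect_true(all(c12 %in% c("GAINED_POSITIVE", "GAINED_NEGATIVE",
                             "LOST_POSITIVE", "LOST_NEGATIVE",
                             "INVERTED", "NONE")))
  swap <- c(GAINED_POSITIVE = "LOST_POSITIVE", GAINED_NEGATIVE = "LOST_NEGATIVE",
            LOST_POSITIVE = "GAINED_POSITIVE", LOST_NEGATIVE = "GAINED_NEGATIVE",
            INVERTED = "INVERTED", NONE = "NONE")
  expect_equal(unname(swap[c12]), c21)
})

test_that("threshold objects validate their ranges", {
  expect_error(rewire_thresholds(inverted_gap = 2.5), "inverted_gap")
  expect_error(rewire_thresholds(absent_band = 0.5, present_abs_r = 0.4),
               "absent_band")
  th <- rewire_thresholds(1.5, 0.9, 0.2)
  expect_equal(classify_edge(0.95, 0.1, th), "GAINED_POSITIVE")
})

test_that("within-group correlations are computed per outcome group", {
  sm <- study_samples()
  n <- nrow(sm)
  set.seed(5)
  em <- matrix(rnorm(4 * n), nrow = 4,
               dimnames = list(paste0("g", 1:4), sm$sample_id))
  # pair (g1, g2) collinear in every sample
  em[2, ] <- 2 * em[1, ] + 1
  # pair (g3, g4) collinear within NON_PREG only
  np <- sm$outcome == "NON_PREG"
  em[4, np] <- em[3, np] * 1.5 + 0.2
  gct <- groupwise_correlation(em, sm)
  row12 <- gct[gct$feature_a == "g1" & gct$feature_b == "g2", ]
  expect_equal(unlist(row12[c("r_ai", "r_nb", "r_np")]),
               c(r_ai = 1, r_nb = 1, r_np = 1))
  row34 <- gct[gct$feature_a == "g3" & gct$feature_b == "g4", ]
  expect_equal(row34$r_np, 1)
  expect_lt(max(abs(c(row34$r_ai, row34$r_nb))), 0.9)
  # undefined within-group variance flags the pair
  em[1, sm$outcome == "AI_PREG"] <- 7
  expect_message(gct2 <- groupwise_correlation(em, sm), "undefined")
  expect_false(gct2$defined[gct2$feature_a == "g1" & gct2$feature_b == "g2"])
})

test_that("consensus requires the same class against both references", {
  gct <- data.frame(
    feature_a = c("a", "a", "b", "c"), feature_b = c("b", "c", "c", "d"),
    r_np = c(0.995, 0.995, -0.995, 0.995),
    r_ai = c(0.02, 0.02, 0.0, 0.995),
    r_nb = c(-0.05, 0.5, 0.0, 0.02))
  res <- consensus_rewired_edges(gct)
  expect_equal(res$edges$rewire_class[res$edges$feature_a == "a" &
                                      res$edges$feature_b == "b"],
               "GAINED_POSITIVE")
  expect_equal(res$edges$rewire_class[res$edges$feature_a == "b"],
               "GAINED_NEGATIVE")
  # second contrast NONE -> not reported
  expect_false(any(res$edges$feature_a == "a" & res$edges$feature_b == "c"))
  # different non-NONE classes per contrast -> discordant, not headline
  gct2 <- data.frame(feature_a = "x", feature_b = "y",
                     r_np = 0.05, r_ai = 0.995, r_nb = -0.995)
  res2 <- consensus_rewired_edges(gct2)
  expect_equal(nrow(res2$edges), 0L)
  expect_equal(nrow(res2$discordant), 1L)
})

test_that("eFDR bookkeeping follows the scrambled/observed proportion", {
  r <- rewirenet:::efdr_result(10, rep(0.5, 4), 4, 0.99)
  expect_equal(r$efdr, 0.05)
  expect_equal(rewirenet:::efdr_result(5, c(0, 0, 0), 3, 0.99)$efdr, 0)
  expect_warning(r0 <- rewirenet:::efdr_result(0, c(1, 2), 2, 0.99), "undefined")
  expect_equal(r0$efdr, 1)
  expect_equal(rewirenet:::efdr_result(2, c(10, 10), 2, 0.99)$efdr, 1)
})

test_that("fast consensus counting agrees with classify_edge on random data", {
  set.seed(27)
  sm <- study_samples()
  em <- matrix(rnorm(80 * 17), nrow = 80,
               dimnames = list(sprintf("g%03d", 1:80), sm$sample_id))
  # sprinkle strong structure so several classes are populated
  np <- sm$outcome == "NON_PREG"
  em[2, ] <- em[1, ] * 0.01 + rnorm(17, sd = 1)
  em[2, np] <- em[1, np] * 3
  counts <- rewirenet:::consensus_counts(em, sm$outcome, rewire_thresholds())
  gct <- groupwise_correlation(em, sm)
  cc <- rewirenet:::consensus_class(gct$r_np, gct$r_ai, gct$r_nb,
                                    rewire_thresholds())
  tab <- table(factor(cc$class, levels = c(names(counts), "NONE")))
  expect_equal(unname(counts), as.integer(tab[names(counts)]))
})

test_that("rewiring eFDR is reproducible and invariant to reference labels", {
  set.seed(11)
  sm <- study_samples()
  sim <- simulate_dataset(simulation_spec(
    n_genes = 60, n_mirna = 5, rewired = plant_rewired(4), seed = 21))
  em <- compute_cpm(sim$counts_mrna, log = TRUE)
  a <- suppressWarnings(
    efdr_rewiring(em, sim$samples, n_randomizations = 20, seed = 9))
  b <- suppressWarnings(
    efdr_rewiring(em, sim$samples, n_randomizations = 20, seed = 9))
  expect_identical(a$pooled, b$pooled)
  expect_identical(a$scrambled_counts, b$scrambled_counts)
  # swapping the two reference-group labels leaves the statistic unchanged
  sm2 <- sim$samples
  sm2$outcome <- factor(
    ifelse(sm2$outcome == "AI_PREG", "NB_PREG",
           ifelse(sm2$outcome == "NB_PREG", "AI_PREG", "NON_PREG")),
    levels = levels(sm2$outcome))
  obs1 <- rewirenet:::consensus_counts(em, sim$samples$outcome,
                                       rewire_thresholds())
  obs2 <- rewirenet:::consensus_counts(em, sm2$outcome, rewire_thresholds())
  expect_equal(sum(obs1), sum(obs2))
})
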