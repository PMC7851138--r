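test_that("one-way ANOVA matches hand-computed sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  a <- anova_per_feature(vals, grp)
  expect_equal(a$F, 3.0, tolerance = 1e-12)  # between MS 3, within MS 1
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 6)

  # three identical groups: no between-group variance at all
  a0 <- anova_per_feature(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_equal(a0$p, 1, tolerance = 1e-12)

  # fully constant response is degenerate, flagged rather than NaN-poisoned
  ad <- anova_per_feature(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(ad$degenerate)
  expect_true(is.na(ad$F))

  expect_error(anova_per_feature(1:4, c("a", "a", "b", "c")), "2 values per group")
})

test_that("ANOVA p-value agrees with a label-permutation oracle", {
  set.seed(101)
  vals <- c(rnorm(8, 0), rnorm(8, 0.6), rnorm(8, 0.3))
  grp <- rep(c("a", "b", "c"), each = 8)
  obs <- anova_per_feature(vals, grp)
  nperm <- 1000
  fperm <- replicate(nperm, anova_per_feature(vals, sample(grp))$F)
  emp <- mean(fperm >= obs$F)
  # empirical p should sit inside a ~3.3 SE binomial band around analytic p
  se <- sqrt(obs$p * (1 - obs$p) / nperm)
  expect_lt(abs(emp - obs$p), 3.3 * se + 1 / nperm)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.03), 0.03)  # q = p when m = 1
  set.seed(3)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone in sorted p
  p <- sort(runif(20))
  expect_true(all(diff(fdr_adjust(p)) >= -1e-12))
})

test_that("pairwise Welch tests flag only real group differences", {
  set.seed(55)
  vals <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 8))
  grp <- rep(c("a", "b", "c"), each = 10)
  tab <- pairwise_tests_fdr(vals, grp, alpha = 0.02)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_identical(tab$significant, tab$q < 0.02)
  sig_pairs <- paste(tab$group1, tab$group2)[tab$significant]
  expect_setequal(sig_pairs, c("a c", "b c"))

  # all-null p-values give q = 1 and no flags
  tab1 <- pairwise_tests_fdr(rep(c(1, 2), 15), rep(c("a", "b", "c"), each = 10))
  expect_true(all(!tab1$significant[tab1$p == 1]))

  expect_warning(pairwise_tests_fdr(c(1, 2, 3, 1), c("a", "a", "a", "b")),
                 "skipped")
})

test_that("a huge effect is flagged and the null pair survives FDR", {
  # third group shifted 10 sigma: the two affected pairs must be flagged and
  # the null a-b pair must not be, in nearly every seed
  grp <- rep(c("a", "b", "c"), each = 20)
  hits <- 0
  nseed <- 100
  for (s in seq_len(nseed)) {
    set.seed(s)
    vals <- rnorm(60) + ifelse(grp == "c", 10, 0)
    tab <- pairwise_tests_fdr(vals, grp, alpha = 0.02)
    sig <- paste(tab$group1, tab$group2)[tab$significant]
    hits <- hits + setequal(sig, c("a c", "b c"))
  }
  expect_gte(hits, 95)
})

test_that("LASSO recovers known informative features and rejects pure noise", {
  grp <- factor(rep(c("CTRL", "earlyPD", "latePD"), each = 20))
  shift <- as.numeric(grp) - 2  # group means 1 SD apart
  nseed <- 50
  all_inf <- 0; noise_counts <- integer(nseed)
  for (s in seq_len(nseed)) {
    set.seed(s)
    x <- cbind(sapply(1:3, function(i) shift + rnorm(60)),
               matrix(rnorm(60 * 20), 60))
    colnames(x) <- c(paste0("inf", 1:3), paste0("noise", 1:20))
    sel <- lasso_select(x, grp, seed = s)
    all_inf <- all_inf + (sum(grepl("^inf", sel)) == 3)
    noise_counts[s] <- sum(grepl("^noise", sel))
  }
  expect_gte(all_inf, 0.9 * nseed)
  expect_lte(median(noise_counts), 2)

  # all-noise design: nothing survives the 1-SE rule in the typical seed
  null_counts <- sapply(1:50, function(s) {
    set.seed(s * 7)
    x <- matrix(rnorm(60 * 23), 60)
    colnames(x) <- paste0("V", 1:23)
    length(lasso_select(x, grp, seed = s))
  })
  expect_equal(median(null_counts), 0)
})

test_that("LASSO handles constant and duplicated columns", {
  grp <- factor(rep(c("CTRL", "earlyPD", "latePD"), each = 20))
  shift <- as.numeric(grp) - 2
  set.seed(2)
  x <- cbind(inf = shift + rnorm(60) * 0.3, dup = NA, flat = 1,
             noise = rnorm(60))
  x[, "dup"] <- x[, "inf"]
  expect_warning(sel <- lasso_select(x, grp, seed = 1), "constant column")
  # collinear duplicates: at least one of the pair is kept
  expect_true(any(c("inf", "dup") %in% sel))
  expect_false("flat" %in% sel)
  expect_error(lasso_select(x[1:5, ], grp[1:5], seed = 1), "more than 5")
})

test_that("AUC follows the Mann-Whitney pair count with fixed orientation", {
  # perfect separation
  r <- roc_evaluate(c(1, 2, 3, 10, 11, 12), rep(c("earlyPD", "latePD"), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$sensitivity, 1)

  # ties count one half: A = {1,2,3}, B = {2,3,4} gives 7/9
  r <- roc_evaluate(c(1, 2, 3, 2, 3, 4), rep(c("earlyPD", "latePD"), each = 3))
  expect_equal(r$auc, 7 / 9, tolerance = 1e-12)
  expect_equal(r$auc, oracle_auc(c(1, 2, 3), c(2, 3, 4)), tolerance = 1e-12)

  # orientation is not flipped: an anti-discriminative marker reports < 0.5
  r <- roc_evaluate(c(10, 11, 12, 1, 2, 3), rep(c("earlyPD", "latePD"), each = 3))
  expect_equal(r$auc, 0)

  # random data agrees with the enumeration oracle
  set.seed(8)
  for (rep in 1:20) {
    a <- round(rnorm(12), 1); b <- round(rnorm(15, 0.5), 1)
    r <- roc_evaluate(c(a, b), rep(c("earlyPD", "latePD"), c(12, 15)))
    expect_equal(r$auc, oracle_auc(a, b), tolerance = 1e-12)
  }

  expect_error(roc_evaluate(1:4, rep("latePD", 4)), "2 classes")
})

test_that("swapping class labels maps AUC to its complement", {
  set.seed(12)
  v <- rnorm(30)
  lab <- rep(c("earlyPD", "latePD"), 15)
  a1 <- roc_evaluate(v, lab, positive = "latePD")$auc
  a2 <- roc_evaluate(v, lab, positive = "earlyPD")$auc
  expect_equal(a1, 1 - a2, tolerance = 1e-12)
})

test_that("permuted labels give chance-level AUC on average", {
  set.seed(19)
  v <- rnorm(40)
  lab <- rep(c("earlyPD", "latePD"), each = 20)
  aucs <- replicate(200, roc_evaluate(v, sample(lab))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("Spearman correlation handles monotone, tied and missing data", {
  sp <- spearman_fdr(data.frame(f = 1:6), data.frame(s = c(2, 4, 6, 8, 10, 12)))
  expect_equal(sp$rho, 1)
  sp <- spearman_fdr(data.frame(f = 1:6), data.frame(s = 6:1))
  expect_equal(sp$rho, -1)
  # rank-difference formula: sum d^2 = 4 over n = 5 gives rho = 0.8
  sp <- spearman_fdr(data.frame(f = 1:5), data.frame(s = c(1, 3, 2, 5, 4)))
  expect_equal(sp$rho, 0.8, tolerance = 1e-12)
  # pairwise deletion reports the complete-pair n
  sp <- spearman_fdr(data.frame(f = c(1:6, NA)),
                     data.frame(s = c(2, 4, 6, 8, 10, 12, 1)))
  expect_equal(sp$n, 6)
  # constant vector: undefined, flagged as NA not an error
  sp <- spearman_fdr(data.frame(f = rep(1, 6)), data.frame(s = 1:6))
  expect_true(is.na(sp$rho))
  expect_false(isTRUE(sp$significant))
  expect_error(spearman_fdr(data.frame(f = c(1, 2, NA, NA, NA, NA)),
                            data.frame(s = 1:6)), "fewer than 5")
})

test_that("Spearman q-values are BH across the feature-by-score family", {
  set.seed(23)
  f <- data.frame(a = rnorm(20), b = rnorm(20))
  s <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  tab <- spearman_fdr(f, s)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$q, oracle_bh(tab$p), tolerance = 1e-12)
})
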