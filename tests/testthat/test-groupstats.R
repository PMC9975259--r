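make_table <- function(n = 10, seed = 1, groups = c("normal", "scar")) {
  simulate_feature_cohort(setNames(rep(n, length(groups)), groups),
                          seed = seed)
}

test_that("pooled t-test matches a hand computation and handles edge cases", {
  # textbook two-sample fixture, pooled variance, two-sided
  x <- c(5.1, 4.9, 5.6, 4.7, 5.0, 5.4)
  y <- c(4.2, 4.6, 4.0, 4.9, 4.4)
  tab <- data.frame(group = rep(c("a", "b"), c(6, 5)),
                    m = c(x, y))
  r <- two_group_test(tab, "m")
  sp2 <- (5 * var(x) + 4 * var(y)) / 9
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 6 + 1 / 5))
  p_hand <- 2 * pt(-abs(t_hand), 9)
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 9)
  expect_equal(r$p_value, p_hand, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- data.frame(group = rep(c("a", "b"), each = 4), m = rep(2, 8))
  r0 <- two_group_test(same, "m")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$stars, "ns")
  expect_error(two_group_test(make_table(groups = "normal"), "variance_collagen"),
               "two groups")
})

test_that("well-separated groups are detected in nearly all replicates", {
  hits <- sapply(1:50, function(s) {
    set.seed(s)
    tab <- data.frame(group = rep(c("a", "b"), each = 20),
                      m = c(rnorm(20, 0, 1), rnorm(20, 3, 1)))
    two_group_test(tab, "m")$p_value < 0.001
  })
  expect_gte(mean(hits), 0.99)
})

test_that("ANOVA + Tukey behaves on null and shifted configurations", {
  set.seed(5)
  null_tab <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                         m = rnorm(30))
  r <- three_group_anova_tukey(null_tab, "m")
  expect_equal(nrow(r$pairs), 3)
  # one clearly shifted group: only its two pairs significant
  hits <- sapply(1:20, function(s) {
    set.seed(s)
    tab <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                      m = c(rnorm(10), rnorm(10), rnorm(10, 4)))
    pr <- three_group_anova_tukey(tab, "m")$pairs
    sig <- pr$p_adj < 0.05
    with_c <- grepl("c", pr$pair)
    all(sig == with_c)
  })
  expect_gte(mean(hits), 0.9)
  # three identical groups: no significance anywhere
  same <- data.frame(group = rep(c("a", "b", "c"), each = 4), m = rep(1, 12))
  rs <- suppressWarnings(three_group_anova_tukey(same, "m"))
  expect_false(any(na.omit(rs$pairs$p_adj) < 0.05))
  expect_error(three_group_anova_tukey(null_tab[1:20, ], "m"), "three")
})

test_that("Tukey-adjusted p-values dominate raw pairwise p-values", {
  for (s in 1:10) {
    set.seed(s)
    tab <- data.frame(group = rep(c("a", "b", "c"), each = 8), m = rnorm(24))
    pr <- three_group_anova_tukey(tab, "m")$pairs
    raw <- c(
      t.test(tab$m[tab$group == "b"], tab$m[tab$group == "a"],
             var.equal = TRUE)$p.value,
      t.test(tab$m[tab$group == "c"], tab$m[tab$group == "a"],
             var.equal = TRUE)$p.value,
      t.test(tab$m[tab$group == "c"], tab$m[tab$group == "b"],
             var.equal = TRUE)$p.value)
    expect_true(all(pr$p_adj >= raw - 1e-9))
  }
})

test_that("collinearity screen flags duplicates, negations and degeneracy", {
  tab <- make_table(20, seed = 2)
  tab$waviness_collagen <- tab$variance_collagen          # duplicate
  tab$coverage_elastin <- 1 - tab$variance_elastin        # negation (r = -1)
  rep1 <- collinearity_screen(tab)
  pairs <- paste(rep1$flagged$feature_a, rep1$flagged$feature_b)
  expect_true("variance_collagen waviness_collagen" %in% pairs)
  expect_true(any(grepl("variance_elastin coverage_elastin", pairs)))
  expect_equal(rep1$r["variance_elastin", "coverage_elastin"], -1)
  expect_true(isSymmetric(rep1$r))
  expect_equal(unname(diag(rep1$r)), rep(1, 6))
  # constant column is degenerate, not silently passed
  tab$variance_collagen <- 0.5
  rep2 <- suppressWarnings(collinearity_screen(tab))
  expect_true("variance_collagen" %in% rep2$degenerate)
  # affine rescaling leaves the screen unchanged
  tab3 <- make_table(20, seed = 3)
  tab4 <- tab3
  tab4[feature_names()] <- sweep(tab3[feature_names()] * 3.2, 2,
                                 runif(6), "+")
  expect_equal(collinearity_screen(tab3)$r, collinearity_screen(tab4)$r,
               tolerance = 1e-12)
})

test_that("independent features are rarely flagged at n = 40", {
  flags <- sapply(1:40, function(s) {
    set.seed(s)
    tab <- data.frame(group = "g", matrix(rnorm(240), 40, 6))
    names(tab) <- c("group", feature_names())
    nrow(collinearity_screen(tab)$flagged)
  })
  expect_gte(mean(flags == 0), 0.95)
})

test_that("the discriminant matches an established LDA on clean data", {
  skip_if_not_installed("MASS")
  tab <- make_table(15, seed = 4, groups = c("normal", "scar"))
  X <- scale(as.matrix(tab[feature_names()]))
  ours <- lda_classify(tab)
  ml <- MASS::lda(X, grouping = tab$group, prior = c(0.5, 0.5))
  expect_equal(as.character(predict(ml, X)$class),
               as.character(fiberarch:::predict_pooled_lda(ours$model, X)))
  mlcv <- MASS::lda(X, grouping = tab$group, prior = c(0.5, 0.5), CV = TRUE)
  cvca_mass <- 100 * mean(as.character(mlcv$class) == tab$group)
  expect_equal(ours$cvca, cvca_mass)
})

test_that("classification accuracies behave at the extremes", {
  # perfectly separated single feature: OCA = CVCA = 100
  tab <- make_table(8, seed = 6)
  tab[feature_names()] <- 0.2
  tab$variance_collagen <- ifelse(tab$group == "scar", 0.9, 0.1)
  r <- suppressWarnings(lda_classify(tab))
  expect_equal(r$oca, 100)
  expect_equal(r$cvca, 100)
  # confusion rows sum to class sizes (three classes, 43 samples)
  t3 <- simulate_feature_cohort(c(normal = 20, scar = 20, adjacent = 3),
                                seed = 7)
  r3 <- lda_classify(t3)
  expect_equal(unname(rowSums(r3$confusion$cv)), c(3, 20, 20))
  expect_equal(unname(rowSums(r3$confusion$train)), c(3, 20, 20))
  expect_error(lda_classify(tab, feature_subset = character(0)), "non-empty")
})

test_that("label permutation drives LOOCV accuracy to chance", {
  cvcas <- sapply(1:30, function(s) {
    tab <- make_table(20, seed = s)
    set.seed(s + 1000)
    lda_classify(tab, labels = sample(tab$group))$cvca
  })
  expect_gt(mean(cvcas), 35)
  expect_lt(mean(cvcas), 65)
})

test_that("trapezoidal AUC equals the Mann-Whitney concordance to 1e-12", {
  set.seed(8)
  for (rep in 1:5) {
    scores <- round(rnorm(40), rep %% 3)   # induce ties sometimes
    pos <- rep(c(TRUE, FALSE), each = 20)
    rc <- roc_curve(scores, pos)
    expect_equal(rc$auc, naive_concordance(scores, pos), tolerance = 1e-12)
    # curve anchored at (0,0) and (1,1), monotone in both coordinates
    expect_equal(rc$roc$fpr[1], 0)
    expect_equal(rc$roc$tpr[1], 0)
    expect_equal(rc$roc$fpr[nrow(rc$roc)], 1)
    expect_equal(rc$roc$tpr[nrow(rc$roc)], 1)
    expect_true(all(diff(rc$roc$fpr) >= 0))
    expect_true(all(diff(rc$roc$tpr) >= 0))
    # AUC invariant under strictly monotone transformation of scores
    expect_equal(roc_curve(qlogis(plogis(scores)) * 3 + 1, pos)$auc, rc$auc,
                 tolerance = 1e-12)
  }
})

test_that("logistic ROC/AUC separates what is separable and not more", {
  skip_if_not_installed("pROC")
  tab <- make_table(20, seed = 9)
  r <- logistic_roc_auc(tab)
  expect_equal(r$auc, 1)
  expect_equal(r$oca, 100)
  # scores independent of labels: AUC near 1/2
  aucs <- sapply(1:30, function(s) {
    tb <- make_table(20, seed = s)
    set.seed(s + 500)
    logistic_roc_auc(tb, labels = sample(tb$group), cv = TRUE)$auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
  # independent check of the resubstitution ROC against pROC
  scores <- r$scores
  ref <- as.numeric(pROC::auc(pROC::roc(tab$group, scores, quiet = TRUE,
                                        direction = "<", levels = c("normal", "scar"))))
  expect_equal(r$auc, ref, tolerance = 1e-12)
})

test_that("subset search enumerates, ranks and reports as expected", {
  tab <- make_table(12, seed = 10)
  s46 <- subset_search(tab, min_size = 4, max_size = 6)
  expect_equal(nrow(s46), choose(6, 4) + choose(6, 5) + choose(6, 6))  # 22
  s16 <- subset_search(tab, min_size = 1, max_size = 6)
  expect_equal(nrow(s16), 63)
  expect_equal(s16$rank, seq_len(63))
  # ranking is (CVCA, AUC, OCA, size) lexicographic, best first
  key <- with(s16, order(-cvca, -auc, -oca, size))
  expect_equal(key, seq_len(63))
  # dot notation marks exactly the subset features
  expect_equal(rowSums(s16[paste0("f", 1:6)] != ""), s16$size)
})

test_that("t-SNE embedding is deterministic and groups duplicated samples", {
  tab <- make_table(12, seed = 11)
  e1 <- visne_embed(tab, seed = 3, perplexity = 6)
  e2 <- visne_embed(tab, seed = 3, perplexity = 6)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 24)
  expect_error(visne_embed(tab, perplexity = 30), "perplexity")
  expect_error(visne_embed(tab[1:4, ]), "at least 5")
  # duplicated samples land nearer each other than the median pair
  near <- sapply(1:5, function(s) {
    tb <- make_table(10, seed = s)
    tb2 <- rbind(tb, tb[3, ])
    tb2$sample_id[21] <- "dup"
    e <- visne_embed(tb2, seed = s, perplexity = 5)
    dd <- as.matrix(dist(e[, c("tsne1", "tsne2")]))
    dd[3, 21] < median(dd[upper.tri(dd)])
  })
  expect_gte(mean(near), 0.8)
})

test_that("synthetic cohorts move each feature in the reported direction", {
  tab <- simulate_feature_cohort(c(normal = 40, scar = 40), seed = 12)
  mn <- colMeans(tab[tab$group == "normal", feature_names()])
  ms <- colMeans(tab[tab$group == "scar", feature_names()])
  expect_gt(ms["variance_collagen"], mn["variance_collagen"])
  expect_gt(ms["waviness_collagen"], mn["waviness_collagen"])
  expect_lt(ms["coverage_collagen"], mn["coverage_collagen"])
  expect_gt(ms["variance_elastin"], mn["variance_elastin"])
  expect_gt(ms["waviness_elastin"], mn["waviness_elastin"])
  expect_gt(ms["coverage_elastin"], mn["coverage_elastin"])
  expect_true(all(as.matrix(tab[feature_names()]) >= 0 &
                    as.matrix(tab[feature_names()]) <= 1))
})
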