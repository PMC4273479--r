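test_that("the F-score formula matches hand-counted confusion tables", {
  expect_equal(f_score(2, 1, 1), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(f_score(2, 1, 1), 0.6667, tolerance = 1e-4)
  expect_equal(f_score(10, 0, 0), 1)
  expect_equal(f_score(0, 3, 2), 0)
  expect_error(f_score(0, 0, 0), "undefined")
  expect_error(f_score(-1, 0, 1), "non-negative")
})

test_that("CFS merit reduces to the class correlation for singletons and
           penalizes redundancy", {
  set.seed(1)
  y <- factor(rep(c("a", "b"), each = 20))
  x <- cbind(
    good = c(rbinom(20, 1, 0.9), rbinom(20, 1, 0.1)),
    noise = rbinom(40, 1, 0.5)
  )
  expect_equal(cfs_merit("good", x, y),
               symmetrical_uncertainty(x[, "good"], y))

  # duplicating a feature never increases merit: with r_ff = 1 the
  # denominator grows from sqrt(k) to sqrt(k + k(k-1))
  x_dup <- cbind(x, good2 = x[, "good"])
  m1 <- cfs_merit("good", x_dup, y)
  m2 <- cfs_merit(c("good", "good2"), x_dup, y)
  expect_lte(m2, m1)
  # algebraic check: with r_ff = 1 the merit is 2r/sqrt(2 + 2) = r exactly,
  # so a perfect duplicate can never raise the score
  r <- symmetrical_uncertainty(x[, "good"], y)
  expect_equal(m2, 2 * r / sqrt(2 + 2 * 1 * 1))
  expect_equal(m2, m1)

  # a feature independent of the class contributes almost nothing
  su_noise <- symmetrical_uncertainty(x[, "noise"], y)
  expect_lt(su_noise, 0.1)

  expect_true(is.na(symmetrical_uncertainty(rep(1, 40), y)))
})

test_that("best-first search finds the informative feature among noise", {
  set.seed(42)
  y <- factor(rep(c("a", "b"), each = 15))
  x <- matrix(rbinom(30 * 50, 1, 0.3), nrow = 30,
              dimnames = list(NULL, paste0("n", 1:50)))
  x <- cbind(x, signal = as.integer(y == "a"))
  sel <- best_first_select(x, y)
  expect_true("signal" %in% sel)

  # duplicated informative feature: redundancy keeps one copy out
  x2 <- cbind(x, signal_copy = x[, "signal"])
  sel2 <- best_first_select(x2, y)
  expect_equal(sum(c("signal", "signal_copy") %in% sel2), 1)

  # all-noise table: few, weak false positives at most
  sel3 <- best_first_select(x[, 1:50], y)
  expect_lte(length(sel3), 8)
})

test_that("naive Bayes cross-validation scores a separable cohort perfectly", {
  y <- factor(rep(c("a", "b"), each = 10))
  x <- cbind(f1 = as.integer(y == "a"), f2 = as.integer(y == "b"))
  rep_cv <- naive_bayes_cv(x, y, iterations = 20, seed = 1)
  expect_equal(rep_cv$auc, 1)
  expect_equal(rep_cv$f_score, 1)

  # label permutation gives chance-level AUC
  set.seed(9)
  x_noise <- matrix(rbinom(40 * 6, 1, 0.5), nrow = 40)
  y_noise <- factor(rep(c("a", "b"), each = 20))
  null_cv <- naive_bayes_cv(x_noise, y_noise, iterations = 50, seed = 2)
  expect_lt(abs(null_cv$auc - 0.5), 0.15)

  expect_identical(naive_bayes_cv(x, y, iterations = 5, seed = 3)$auc_per_iteration,
                   naive_bayes_cv(x, y, iterations = 5, seed = 3)$auc_per_iteration)
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4) == 1
  ours <- aluscancnv:::rank_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("hierarchical clustering separates two marked classes", {
  set.seed(13)
  cohort <- simulate_labeled_cohort(n_per_class = 8, n_signal = 6, n_noise = 30,
                                    penetrance_case = 0.95,
                                    penetrance_control = 0.05, seed = 13)
  cl <- hier_cluster(cohort$x, features = cohort$signal_features,
                     n_boot = 100, seed = 5)
  groups <- cutree(cl$hclust, k = 2)
  split_tab <- table(groups, cohort$y)
  # each top-level cluster is (near-)pure for one class
  expect_gte(sum(apply(split_tab, 1, max)) / sum(split_tab), 0.9)
  expect_true(all(cl$support >= 0 & cl$support <= 1))

  dup <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0), d = c(0, 1, 1))
  cl_dup <- hier_cluster(dup, n_boot = 10, seed = 1)
  merge_heights <- cl_dup$hclust$height
  expect_equal(min(merge_heights), 0)  # identical samples merge first at 0
  expect_error(hier_cluster(dup[1:2, ]), "at least 3")
})

test_that("newick export writes the support-annotated dendrogram", {
  set.seed(3)
  x <- matrix(rbinom(5 * 8, 1, 0.5), nrow = 5,
              dimnames = list(paste0("s", 1:5), NULL))
  cl <- hier_cluster(x, n_boot = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("s", 1:5))
})

test_that("ward.D linkage on unsquared distances is used", {
  set.seed(19)
  x <- matrix(rbinom(12 * 10, 1, 0.4), nrow = 12,
              dimnames = list(paste0("s", 1:12), NULL))
  cl <- hier_cluster(x, n_boot = 2, seed = 1)
  ref <- hclust(dist(x), method = "ward.D")
  expect_equal(cl$hclust$merge, ref$merge)
  expect_equal(cl$hclust$height, ref$height)
})
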