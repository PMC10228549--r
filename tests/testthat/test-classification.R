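pct <- function(bif = 0, pk = 0, hom = 0, lau = 0, rbo = 0) {
  c(homolactic_fermentation = hom, phosphoketolase = pk, bifid_shunt = bif,
    lactic_acid_utilization = lau, reverse_beta_oxidation = rbo)
}

test_that("the rule classifier applies the pathway bands in order", {
  expect_identical(rule_classify(pct(bif = 90, pk = 0, lau = 0,
                                     rbo = 10))$group,
                   "ferment_to_intermediates")
  expect_identical(rule_classify(pct(bif = 10, lau = 100, rbo = 100))$group,
                   "intermediate_ce")
  expect_identical(rule_classify(pct(rbo = 100))$group, "carbohydrate_ce")
  # everything between the bands -> uninvolved
  expect_identical(rule_classify(pct(bif = 50, pk = 50, hom = 50, lau = 50,
                                     rbo = 50))$group, "uninvolved")
  # homolactic alone can carry the ferment-to-intermediates call
  expect_identical(rule_classify(pct(hom = 100))$group,
                   "ferment_to_intermediates")
  # thresholds are configurable
  expect_identical(rule_classify(pct(rbo = 55),
                                 rule_thresholds(high = 50, low = 30))$group,
                   "carbohydrate_ce")
})

test_that("log loss and baseline improvement match closed forms", {
  prob1 <- matrix(c(1, 0, 0, 1), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(logloss(prob1, c("a", "b")), 0)
  prob2 <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(logloss(prob2, "a"), 0.6931, tolerance = 1e-4)
  prob3 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
                  dimnames = list(NULL, c("a", "b")))
  expect_equal(logloss(prob3, c("a", "b")), (-log(0.9) - log(0.8)) / 2)

  expect_equal(baseline_improvement(1.386, 1.386), 0)
  expect_equal(baseline_improvement(0, 1.386), 100)
  expect_equal(baseline_improvement(0.1386, 1.386), 90)
  # a predictor emitting class frequencies scores the baseline exactly
  y <- c("a", "a", "a", "b")
  freq <- matrix(c(0.75, 0.25), 4, 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b")))
  expect_equal(baseline_improvement(logloss(freq, y), logloss(freq, y)), 0)
})

test_that("the softmax classifier separates clean classes deterministically", {
  set.seed(9)
  n <- 15
  x <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 5), rnorm(n, 5)),
             cbind(rnorm(n, -4), rnorm(n, 4)))
  y <- rep(c("a", "b", "c"), each = n)
  m1 <- train_classifier(x, y, seed = 4)
  m2 <- train_classifier(x, y, seed = 4)
  expect_identical(predict(m1, x), predict(m2, x))

  p <- predict(m1, x)
  expect_equal(unname(rowSums(p)), rep(1, nrow(x)), tolerance = 1e-9)
  expect_gt(mean(predict(m1, x, type = "class") == y), 0.95)
  expect_lt(m1$report$cv_logloss, m1$report$baseline_logloss)
  expect_identical(nrow(m1$report$per_class), 3L)
  expect_true(all(m1$report$per_class$roc_auc > 0.9))
  expect_true(all(m1$report$per_class$average_precision > 0.8))

  expect_error(train_classifier(x[c(1, 16, 31), ], c("a", "b", "c")),
               "at least 2")
  expect_error(train_classifier(x, rep("a", nrow(x))), "2 classes")
})

test_that("the pluggable contract accepts other algorithms", {
  skip_if_not_installed("nnet")
  set.seed(10)
  x <- rbind(matrix(rnorm(30), ncol = 2),
             matrix(rnorm(30, mean = 4), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 15)
  m <- train_classifier(x, y, algorithm = "multinom", seed = 1)
  expect_gt(mean(predict(m, x, type = "class") == y), 0.9)
})

test_that("cohort classification respects the high-abundance set", {
  set.seed(12)
  x <- rbind(matrix(rnorm(10), ncol = 2),
             matrix(rnorm(10, mean = 5), ncol = 2))
  rownames(x) <- sprintf("g%02d", 1:10)
  y <- rep(c("intermediate_ce", "uninvolved"), each = 5)
  m <- train_classifier(x, y, seed = 2)

  res <- classify_cohort(m, x, rownames(x)[c(1, 2, 6)])
  expect_identical(nrow(res$calls), 3L)
  expect_equal(sum(res$group_counts), 3)

  empty <- classify_cohort(m, x, character(0))
  expect_identical(nrow(empty$calls), 0L)

  expect_error(classify_cohort(m, x, "nope"), "nope")
})

test_that("method comparison produces Venn counts", {
  rule <- data.frame(genome_id = c("a", "b", "c"),
                     group = rep("intermediate_ce", 3))
  ml_same <- rule
  cmp <- compare_methods(rule, ml_same)
  expect_true(all(cmp$rule_only == 0 & cmp$ml_only == 0))
  expect_equal(cmp$both[cmp$group == "intermediate_ce"], 3)

  ml_disjoint <- data.frame(genome_id = c("x", "y"),
                            group = rep("intermediate_ce", 2))
  cmp2 <- compare_methods(rule, ml_disjoint)
  expect_equal(cmp2$both[cmp2$group == "intermediate_ce"], 0)
  expect_equal(cmp2$rule_only[cmp2$group == "intermediate_ce"], 3)
  expect_equal(cmp2$ml_only[cmp2$group == "intermediate_ce"], 2)

  # planted partial disagreement
  ml_mix <- data.frame(genome_id = c("b", "c", "d"),
                       group = c("intermediate_ce", "carbohydrate_ce",
                                 "intermediate_ce"))
  cmp3 <- compare_methods(rule, ml_mix)
  expect_equal(cmp3$both[cmp3$group == "intermediate_ce"], 1)
  expect_equal(cmp3$rule_only[cmp3$group == "intermediate_ce"], 2)
  expect_equal(cmp3$ml_only[cmp3$group == "carbohydrate_ce"], 1)
})
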