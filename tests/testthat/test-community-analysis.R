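planted_table <- function() {
  abund <- rbind(gA = c(50, 40, 0, 0), gB = c(0.5, 0.8, 1.0, 0.2),
                 gC = c(0, 0, 60, 70))
  colnames(abund) <- c("e1_s1", "e1_s2", "e2_s1", "e2_s2")
  residual <- 100 - colSums(abund)
  meta <- data.frame(sample_id = colnames(abund),
                     experiment = c("e1", "e1", "e2", "e2"),
                     timepoint = c(1, 2, 1, 2))
  abundance_table(abund, setNames(residual, colnames(abund)), meta)
}

test_that("presence and the 1% filter match hand enumeration", {
  tab <- planted_table()
  pf <- presence_and_filter(tab)
  expect_setequal(pf$present$e1, c("gA", "gB"))
  expect_setequal(pf$present$e2, c("gB", "gC"))
  # gB reaches at least 1.0% only in e2_s1 (exactly 1.0) -> still included
  expect_setequal(pf$high_abundance, c("gA", "gB", "gC"))
  expect_setequal(presence_and_filter(tab, high_floor = 1.1)$high_abundance,
                  c("gA", "gC"))
  expect_setequal(presence_and_filter(tab, high_floor = 61)$high_abundance,
                  "gC")
  summ <- pf$summary
  expect_equal(summ$n_present, c(2, 2))
  expect_equal(summ$min_total[1], 40.8)
  expect_equal(summ$max_total[1], 50.5)
  expect_equal(summ$median_total[2], mean(c(61, 70.2)))
  expect_error(abundance_table(matrix(1, 1, 1, dimnames = list("g", "s")),
                               c(s = 50), data.frame(sample_id = "s",
                                                     experiment = "e")),
               "100")
})

test_that("Bray-Curtis matches its closed forms", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_equal(bray_curtis(c(60, 40), c(20, 80)), 0.4)
  # and agrees with the vegan implementation on random vectors
  set.seed(2)
  x <- runif(10); y <- runif(10)
  expect_equal(bray_curtis(x, y),
               as.numeric(vegan::vegdist(rbind(x, y), method = "bray")))
})

test_that("NMDS recovers planar configurations with near-zero stress", {
  set.seed(5)
  X <- matrix(rnorm(24), ncol = 2)
  d <- dist(X)
  ord <- nmds(d, k = 2, n_restarts = 3, seed = 1)
  expect_lt(ord$stress, 0.01)
  expect_true(all(diff(ord$trajectory) <= 1e-12))
  expect_identical(nrow(ord$points), 12L)

  # stress is invariant under consistent relabeling of the matrix
  dm <- as.matrix(d)
  p <- sample(nrow(dm))
  ord2 <- nmds(dm[p, p], k = 2, n_restarts = 3, seed = 1)
  expect_equal(ord2$stress, ord$stress, tolerance = 1e-3)

  bad <- as.matrix(d)
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(nmds(bad), "symmetric")
})

test_that("NMDS stress is comparable to the vegan reference", {
  set.seed(8)
  m <- matrix(runif(60), nrow = 10) # 10 samples, no planar structure
  d <- vegan::vegdist(m, method = "bray")
  ours <- nmds(d, k = 2, n_restarts = 5, seed = 1)
  ref <- vegan::monoMDS(d, k = 2) # independent minimiser, same stress-1
  expect_lt(ours$stress, ref$stress + 0.05)
  expect_gt(ours$stress, 0) # genuinely non-embeddable configuration
})

test_that("NMDS separates the simulated experiments", {
  ids <- sprintf("G%02d", 1:15)
  ok <- vapply(1:10, function(s) {
    tb <- simulate_abundance(ids, small_config(
      s, abundance_experiments = 3, samples_per_experiment = 4), seed = s)
    ord <- nmds(bray_curtis_dist(tb), n_restarts = 3, seed = s)
    d <- as.matrix(dist(ord$points))
    same <- outer(tb$metadata$experiment, tb$metadata$experiment, "==")
    diag(same) <- NA
    mean(d[which(same)], na.rm = TRUE) < mean(d[which(!same)])
  }, logical(1))
  expect_true(all(ok))
})

test_that("PerMANOVA matches vegan and detects separated groups", {
  set.seed(11)
  X <- rbind(matrix(rnorm(20), ncol = 2),
             matrix(rnorm(20, mean = 4), ncol = 2))
  labels <- rep(c("a", "b"), each = 10)
  d <- dist(X)
  pm <- permanova(d, labels, n_perm = 999, seed = 3)
  expect_lte(pm$p_value, 0.001)
  expect_equal(pm$p_value, 1 / (999 + 1)) # F exceeds every permutation
  # pseudo-F agrees with the vegan implementation
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = labels),
                       permutations = 10)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)

  expect_error(permanova(d, c("a", rep("b", 19))), "at least 2 samples")
  expect_error(permanova(d, rep("a", 20)), "2 groups")
})

test_that("pairwise PerMANOVA applies the BH step-up correctly", {
  # hand evaluation of BH on (0.01, 0.02, 0.04): (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(13)
  X <- rbind(matrix(rnorm(12), ncol = 2),
             matrix(rnorm(12, mean = 3), ncol = 2),
             cbind(rnorm(6, -3), rnorm(6, 3)))
  labels <- rep(c("a", "b", "c"), each = 6)
  pw <- pairwise_permanova_bh(dist(X), labels, n_perm = 199, seed = 5)
  expect_identical(nrow(pw), 3L)
  expect_equal(pw$p_adj, p.adjust(pw$p, method = "BH"))
  # adjusted p-values are monotone in the raw ones
  expect_true(all(diff(pw$p_adj[order(pw$p)]) >= 0))
  expect_true(all(pw$p_adj >= pw$p))
})
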