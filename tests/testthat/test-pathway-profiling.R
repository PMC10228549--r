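fake_hit <- function(q, genome = "g1") {
  data.frame(qseqid = q, sseqid = "c1", pident = 90, length = 100,
             qstart = 1, qend = 100, sstart = 1, send = 300,
             evalue = 1e-30, bitscore = 100, frame = 1, qcovhsp = 100,
             raw_score = 300, genome_id = genome)
}

test_that("profiles compute roster percentages from presence", {
  catal <- small_catalog(1)
  lau <- catal$pathways$lactic_acid_utilization
  hits <- do.call(rbind, lapply(lau, fake_hit))
  p <- build_profile(hits, catal, "g1")
  expect_equal(p$per_pathway_percent[["lactic_acid_utilization"]], 100)
  expect_equal(p$per_pathway_percent[["bifid_shunt"]], 0)
  expect_equal(sum(p$per_enzyme_present), 3)
  expect_equal(p$unique_enzyme_percent[["lactic_acid_utilization"]], 100)

  # empty hit list -> all zero
  p0 <- build_profile(hits[0, ], catal, "gX")
  expect_true(all(p0$per_pathway_percent == 0))

  # duplicate hits and hit order do not matter
  p2 <- build_profile(rbind(hits[3:1, ], hits[1, ]), catal, "g1")
  expect_equal(p2$per_pathway_percent, p$per_pathway_percent)

  expect_error(build_profile(fake_hit("nonsense"), catal, "g1"),
               "nonsense")
})

test_that("the shared phosphoketolase enzyme counts in both rosters", {
  catal <- small_catalog(1)
  p <- build_profile(fake_hit("xpk"), catal, "g1")
  expect_gt(p$per_pathway_percent[["phosphoketolase"]], 0)
  expect_gt(p$per_pathway_percent[["bifid_shunt"]], 0)
  # but it is not pathway-unique, so unique percentages stay at zero
  expect_equal(p$unique_enzyme_percent[["phosphoketolase"]], 0)
})

test_that("profile matrix has the documented shape and round-trips", {
  catal <- small_catalog(1)
  profs <- list(build_profile(fake_hit("ecLDH", "gB"), catal, "gB"),
                build_profile(fake_hit("thlA", "gA"), catal, "gA"))
  m <- profile_matrix(profs)
  expect_identical(dim(m), c(2L, 5L + length(catal$proteins)))
  expect_identical(rownames(m), c("gA", "gB")) # sorted by genome id
  expect_identical(colnames(m)[1:5],
                   paste0("pct_", names(catal$pathways)))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  magce:::write_tsv(data.frame(genome_id = rownames(m), m,
                               check.names = FALSE), tmp)
  back <- magce:::read_tsv(tmp)
  m2 <- as.matrix(back[, -1])
  rownames(m2) <- back$genome_id
  expect_equal(m2, m)

  expect_error(profile_matrix(list(profs[[1]], profs[[1]])), "duplicate")
})

test_that("hierarchical clustering merges identical rows first", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 10, 10),
             d = c(40, 0, 0))
  cl <- hierarchical_cluster(m)
  expect_identical(sort(cl$hclust$merge[1, ]), c(-2L, -1L))
  expect_equal(cl$hclust$height[1], 0)
  # complete linkage: merge heights are monotone non-decreasing
  expect_true(all(diff(cl$hclust$height) >= 0))
  expect_match(cl$newick, "^\\(")
  expect_error(hierarchical_cluster(rbind(a = c(1, NA), b = c(1, 2))),
               "non-finite")
  expect_error(hierarchical_cluster(m[1, , drop = FALSE]), "2 rows")
})

test_that("cohort profiles cluster genomes by functional group", {
  catal <- small_catalog(1)
  contiguous <- vapply(1:5, function(s) {
    cfg <- small_config(s, n_genomes_per_group = 3)
    co <- simulate_cohort(catal, cfg, seed = s)
    hits <- search_cohort(catal, co$genomes)
    m <- profile_matrix(build_profiles(hits, catal, names(co$genomes)))
    pct <- m[, startsWith(colnames(m), "pct_")]
    ord <- hierarchical_cluster(pct)$order
    grp <- vapply(co$truths[ord], `[[`, character(1), "true_group")
    all(rle(grp)$lengths == 3) # same-group genomes contiguous
  }, logical(1))
  expect_true(mean(contiguous) >= 0.9)
})
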