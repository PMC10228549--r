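test_that("catalog has the fixed LAU and rBOX rosters and is deterministic", {
  cat1 <- make_pathway_catalog(seed = 1)
  expect_length(cat1$pathways$lactic_acid_utilization, 3)
  expect_length(cat1$pathways$reverse_beta_oxidation, 4)
  expect_setequal(cat1$pathways$lactic_acid_utilization,
                  c("ecLDH", "etfA", "etfB"))
  expect_true(all(c("thlA", "acdEB") %in%
                    cat1$pathways$reverse_beta_oxidation))
  expect_named(cat1$pathways,
               c("homolactic_fermentation", "phosphoketolase", "bifid_shunt",
                 "lactic_acid_utilization", "reverse_beta_oxidation"))
  # shared phosphoketolase enzyme is flagged non-unique, the rest unique
  expect_false(any(cat1$table$is_unique[cat1$table$enzyme == "xpk"]))
  expect_true(all(cat1$table$is_unique[cat1$table$enzyme == "ecLDH"]))

  expect_identical(cat1, make_pathway_catalog(seed = 1))
  expect_false(identical(cat1$proteins, make_pathway_catalog(seed = 2)$proteins))

  lens <- nchar(cat1$proteins)
  expect_true(all(lens >= 200 & lens <= 500))
})

test_that("embedded genes honour group content rules and target identity", {
  catal <- small_catalog(1)
  cfg <- small_config(1)
  roster_of <- function(p) catal$pathways[[p]]

  for (group in ce_groups()) {
    sim <- simulate_genome(group, catal, cfg, seed = 11)
    tg <- sim$truth$embedded_genes
    expect_identical(sim$truth$true_group, group)
    # per-pathway embedded counts
    counts <- vapply(names(catal$pathways), function(p)
      sum(tg$enzyme %in% roster_of(p)), integer(1))
    assigned <- magce:::.group_pathways[[group]]
    for (p in names(counts)) {
      if (p %in% assigned) {
        expect_identical(counts[[p]], length(roster_of(p)))
      } else {
        expect_lte(counts[[p]], 1L)
      }
    }
    # coordinates in bounds, lengths divisible by 3
    expect_true(all(tg$start >= 1 & tg$end <= cfg$contig_length))
    expect_true(all((tg$end - tg$start + 1) %% 3 == 0))
    # realized identity within 2 points of target, recomputed from sequence
    for (i in seq_len(nrow(tg))) {
      ident <- truth_gene_identity(sim$genome, tg[i, ], catal)
      expect_lt(abs(ident - tg$target_identity[i]), 0.02 + 1e-9)
    }
    q <- sim$genome$quality
    expect_true(q$completeness >= 75 && q$completeness <= 100)
    expect_true(q$contamination >= 0 && q$contamination <= 7.5)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  catal <- small_catalog(3)
  cfg <- small_config(5, n_genomes_per_group = 2)
  c1 <- simulate_cohort(catal, cfg, seed = 5)
  c2 <- simulate_cohort(catal, cfg, seed = 5)
  expect_identical(c1, c2)
  expect_false(identical(
    c1$genomes[[1]]$contigs,
    simulate_cohort(catal, cfg, seed = 6)$genomes[[1]]$contigs))
})

test_that("genes that cannot fit raise a sizing error", {
  catal <- small_catalog(1)
  cfg <- sim_config(seed = 1, contig_length = 1000, n_contigs = 1)
  expect_error(simulate_genome("ferment_to_intermediates", catal, cfg,
                               seed = 1), "too short")
})

test_that("clones diverge at the requested substitution rate", {
  catal <- small_catalog(1)
  cfg <- small_config(1)
  g <- simulate_genome("uninvolved", catal, cfg, seed = 2)$genome

  same <- simulate_clone(g, 0, seed = 3)
  expect_identical(unname(same$contigs), unname(g$contigs))

  d <- 0.005
  cl <- simulate_clone(g, d, seed = 3)
  L <- sum(nchar(g$contigs))
  mism <- sum(vapply(seq_along(g$contigs), function(i)
    sum(utf8ToInt(g$contigs[[i]]) != utf8ToInt(cl$contigs[[i]])),
    numeric(1)))
  sd3 <- 3 * sqrt(L * d * (1 - d))
  expect_lt(abs(mism - L * d), sd3)

  expect_error(simulate_clone(g, 0.2, seed = 1))
})

test_that("abundance tables normalise and separate experiments", {
  cfg <- small_config(1, abundance_experiments = 3,
                      samples_per_experiment = 4)
  ids <- sprintf("G%02d", 1:20)
  tab <- simulate_abundance(ids, cfg, seed = 4)
  expect_equal(unname(colSums(tab$abund) + tab$residual),
               rep(100, ncol(tab$abund)), tolerance = 1e-9)
  expect_true(all(tab$residual >= cfg$residual_range[1] &
                    tab$residual <= cfg$residual_range[2]))
  expect_identical(simulate_abundance(ids, cfg, seed = 4), tab)

  # within-experiment Bray-Curtis below between-experiment, replicated
  deltas <- vapply(1:10, function(s) {
    tb <- simulate_abundance(ids, cfg, seed = s)
    d <- as.matrix(bray_curtis_dist(tb))
    same <- outer(tb$metadata$experiment, tb$metadata$experiment, "==")
    diag(same) <- NA
    mean(d[which(!same)]) - mean(d[which(same)], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(deltas > 0))

  # concentration -> infinity collapses within-experiment dissimilarity
  # (residual fixed so compositions are compared on the same scale)
  cfg_hi <- small_config(1, abundance_experiments = 2,
                         samples_per_experiment = 3,
                         dirichlet_concentration = 1e7,
                         residual_range = c(20, 20))
  tb <- simulate_abundance(ids, cfg_hi, seed = 2)
  d <- as.matrix(bray_curtis_dist(tb))
  same <- outer(tb$metadata$experiment, tb$metadata$experiment, "==")
  diag(same) <- NA
  expect_lt(mean(d[which(same)], na.rm = TRUE), 0.02)

  expect_error(simulate_abundance(ids, small_config(
    1, abundance_experiments = 1), seed = 1))
})
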