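test_that("chain-elongating genomes carry the expected EtfB repertoires", {
  catal <- small_catalog(1)
  cfg <- small_config(1)
  refs <- simulate_etfb_references(catal, seed = 2)
  expect_identical(nrow(refs), 6L)
  expect_setequal(unique(refs$label), c("LAU_associated", "ACD_associated"))

  label_set <- function(genome) {
    cands <- find_etfb_homologs(genome, refs)
    vapply(cands$candidate_seq, function(s)
      assign_label(s, refs)$label, character(1))
  }

  # intermediate CE: the LAU-roster EtfB plus the ACD-associated copy
  ice <- simulate_genome("intermediate_ce", catal, cfg, seed = 3)$genome
  labs <- label_set(ice)
  expect_length(labs, 2)
  expect_setequal(unname(labs), c("LAU_associated", "ACD_associated"))

  # carbohydrate CE: always an ACD copy; the LAU pathway is not assigned,
  # so at most one stray LAU enzyme (possibly EtfB) can join it
  cce <- simulate_genome("carbohydrate_ce", catal, cfg, seed = 4)$genome
  labs_cce <- label_set(cce)
  expect_identical(sum(labs_cce == "ACD_associated"), 1L)

  # ferment-to-intermediates genomes never carry the ACD-associated copy
  fti <- simulate_genome("ferment_to_intermediates", catal, cfg,
                         seed = 5)$genome
  expect_false(any(label_set(fti) == "ACD_associated"))

  # a genome of plain random sequence has no EtfB locus at all
  bare <- structure(list(genome_id = "bare",
                         contigs = c(b_c1 = magce:::random_dna(8000)),
                         quality = list()), class = "genome_record")
  expect_identical(nrow(find_etfb_homologs(bare, refs)), 0L)
})

test_that("label assignment uses nearest reference with a margin", {
  catal <- small_catalog(1)
  refs <- simulate_etfb_references(catal, seed = 2)
  acd_ref <- refs$sequence[refs$label == "ACD_associated"][1]
  r <- assign_label(acd_ref, refs)
  expect_identical(r$label, "ACD_associated")
  expect_equal(min(r$distances), 0, tolerance = 1e-9)

  # equidistant candidate: same sequence under both labels -> "other"
  tie <- data.frame(id = c("r1", "r2"),
                    label = c("LAU_associated", "ACD_associated"),
                    sequence = rep(acd_ref, 2))
  expect_identical(assign_label(acd_ref, tie)$label, "other")

  # decreasing the margin floor never turns a labeled call into "other"
  loose <- assign_label(acd_ref, refs, margin_min = 0.01)
  strict <- assign_label(acd_ref, refs, margin_min = 0.10)
  expect_true(strict$label == "other" || loose$label == strict$label)

  # reference order does not change the call
  r2 <- assign_label(acd_ref, refs[rev(seq_len(nrow(refs))), ])
  expect_identical(r2$label, r$label)

  expect_error(assign_label(acd_ref, refs[0, ]), "empty")
})

test_that("references round-trip through labeled FASTA", {
  catal <- small_catalog(1)
  refs <- simulate_etfb_references(catal, seed = 7)
  tmp <- withr::local_tempfile(fileext = ".faa")
  write_etfb_references(refs, tmp)
  back <- read_etfb_references(tmp)
  expect_equal(back$id, refs$id)
  expect_equal(back$label, refs$label)
  expect_equal(back$sequence, refs$sequence)
})

test_that("the EtfB summary tallies genomes with both homolog types", {
  catal <- small_catalog(1)
  cfg <- small_config(1)
  refs <- simulate_etfb_references(catal, seed = 2)
  genomes <- list(
    ice = simulate_genome("intermediate_ce", catal, cfg, seed = 8,
                          genome_id = "ice")$genome,
    bare = structure(list(genome_id = "bare",
                          contigs = c(n_c1 = magce:::random_dna(8000)),
                          quality = list()), class = "genome_record"))
  calls <- etfb_calls(genomes, refs)
  fn <- data.frame(genome_id = c("ice", "bare"),
                   group = c("intermediate_ce", "uninvolved"))
  summ <- summarize_etfb(calls, fn)
  tab <- summ$table
  # the intermediate chain elongator counts in the dual-copy tally
  expect_true(tab$has_lau[tab$genome_id == "ice"])
  expect_true(tab$has_acd[tab$genome_id == "ice"])
  expect_identical(summ$n_both, 1L)
  expect_false(any(tab$has_lau[tab$genome_id == "bare"],
                   tab$has_acd[tab$genome_id == "bare"]))
  expect_equal(summ$counts$has_acd[summ$counts$group == "intermediate_ce"],
               1)

  empty <- summarize_etfb(calls[0, ], fn[0, ])
  expect_identical(nrow(empty$table), 0L)
  expect_identical(empty$n_both, 0L)
})
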