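test_that("six-frame translation follows the standard code", {
  expect_identical(six_frame_translate("ATGAAA")[["+1"]], "MK")
  expect_identical(six_frame_translate("")[[1]], "")
  # reverse-complement consistency and frame lengths
  set.seed(1)
  s <- magce:::random_dna(101)
  fr <- six_frame_translate(s)
  expect_identical(fr[["-1"]], six_frame_translate(revcomp(s))[["+1"]])
  expect_identical(fr[["-3"]], six_frame_translate(revcomp(s))[["+3"]])
  expect_identical(nchar(fr[["+2"]]), (101L - 1L) %/% 3L)
  # stops retained, N translates to X
  expect_identical(six_frame_translate("TAAAAT")[["+1"]], "*N")
  expect_identical(substr(six_frame_translate("ANGAAA")[["+1"]], 1, 1), "X")
})

test_that("self-alignment is perfect and hopeless pairs return no hit", {
  q <- random_aa(80)
  r <- local_align(q, q)
  expect_identical(r$identities, nchar(q))
  expect_identical(r$aln_length, nchar(q))
  expect_identical(c(r$qstart, r$qend, r$sstart, r$send),
                   c(1L, 80L, 1L, 80L))
  # no shared word, no positive-scoring region (W vs P scores -4)
  expect_null(local_align(strrep("W", 30), strrep("P", 30)))
})

test_that("the aligner matches the independent Smith-Waterman oracle", {
  set.seed(7)
  for (i in 1:60) {
    q <- random_aa(sample(20:300, 1))
    s <- random_aa(sample(20:300, 1))
    r <- local_align(q, s)
    expect_equal(if (is.null(r)) 0 else r$score, oracle_sw_score(q, s))
  }
  # related pairs with indels exercise the gap states
  for (i in 1:20) {
    q <- random_aa(150)
    s <- paste0(random_aa(10), substr(q, 1, 70), random_aa(3),
                substr(q, 81, 150), random_aa(10))
    r <- local_align(q, s)
    expect_equal(r$score, oracle_sw_score(q, s))
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  p <- search_params()
  # hand evaluation of E = m*n*2^(-(lambda*S - ln K)/ln 2)
  bits <- (0.267 * 100 - log(0.041)) / log(2)
  expect_equal(evalue(bits, 300, 1e6), 300 * 1e6 * 2^(-bits))
  expect_equal(evalue(bitscore(100, p), 300, 1e6),
               300 * 1e6 * exp(-(0.267 * 100 - log(0.041))))
  # bits chosen so m*n*2^(-bits) = 1
  expect_equal(evalue(log2(300 * 1e6), 300, 1e6), 1)
  # doubling the database doubles E; E decreases with bitscore
  expect_equal(evalue(50, 300, 2e6), 2 * evalue(50, 300, 1e6))
  expect_lt(evalue(60, 300, 1e6), evalue(50, 300, 1e6))
})

test_that("search recovers planted genes and applies the three filters", {
  set.seed(21)
  query <- setNames(random_aa(250), "enzQ")
  g90 <- plant_gene(query[[1]], 0.90, genome_id = "g90")
  hits <- search_genome(query, g90)
  expect_identical(nrow(hits), 1L)
  expect_gt(hits$pident, 80)
  expect_gt(hits$qcovhsp, 99)
  expect_lt(hits$evalue, 1e-10)

  g15 <- plant_gene(query[[1]], 0.15, genome_id = "g15")
  expect_identical(nrow(search_genome(query, g15)), 0L)

  # empty genome -> empty table with stable columns
  empty <- structure(list(genome_id = "none", contigs = character(0),
                          quality = list()), class = "genome_record")
  expect_identical(nrow(search_genome(query, empty)), 0L)

  # tightening any threshold never adds hits
  g60 <- plant_gene(query[[1]], 0.60, genome_id = "g60")
  loose <- search_genome(query, g60, search_params())
  tight <- search_genome(query, g60, search_params(pident_min = 70))
  expect_true(all(tight$qseqid %in% loose$qseqid))
  expect_lte(nrow(tight), nrow(loose))
})

test_that("searching the reverse-complemented genome mirrors the hits", {
  set.seed(31)
  query <- setNames(random_aa(200), "enzQ")
  g <- plant_gene(query[[1]], 0.85, contig_length = 6000)
  grc <- g
  grc$contigs <- vapply(g$contigs, revcomp, character(1))
  h1 <- search_genome(query, g)
  h2 <- search_genome(query, grc)
  expect_identical(nrow(h1), 1L)
  expect_identical(nrow(h2), 1L)
  expect_identical(h1$raw_score, h2$raw_score)
  expect_identical(h1$frame, -h2$frame)
  L <- nchar(g$contigs[[1]])
  expect_identical(h2$sstart, L - h1$send + 1L)
  expect_identical(h2$send, L - h1$sstart + 1L)
})

test_that("recovery is monotone in divergence at the default thresholds", {
  set.seed(41)
  query <- setNames(random_aa(220), "enzQ")
  rates <- vapply(c(0.95, 0.8, 0.6, 0.4, 0.2), function(ident) {
    mean(vapply(1:8, function(i) {
      g <- plant_gene(query[[1]], ident, contig_length = 6000)
      nrow(search_genome(query, g)) == 1
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_identical(rates[1], 1)   # high identity always found
  expect_identical(rates[5], 0)   # 20% sits below the identity floor
})
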