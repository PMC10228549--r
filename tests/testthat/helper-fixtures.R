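# small-scale fixtures used across the suite; the full study-scale
# configuration (50 kb x 4 contigs, 200-500 aa queries) is exercised in
# test-acceptance.R

small_catalog <- function(seed = 1) {
  make_pathway_catalog(seed = seed, protein_length_range = c(120, 200))
}

small_config <- function(seed = 1, n_genomes_per_group = 3, ...) {
  sim_config(seed = seed, contig_length = 15000, n_contigs = 2,
             n_genomes_per_group = n_genomes_per_group, ...)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

# independent Smith-Waterman oracle (Biostrings), same gap convention
oracle_sw_score <- function(q, s, params = search_params()) {
  mat <- substitution_matrix(params$substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  max(0, Biostrings::score(aln))
}

# plant one reverse-translated, identity-controlled gene in a random contig
plant_gene <- function(protein, identity, contig_length = 10000,
                       contig_id = "c1", genome_id = "planted") {
  mut <- magce:::mutate_protein(protein, identity)
  nt <- magce:::reverse_translate(mut$seq)
  contig <- magce:::random_dna(contig_length)
  start <- sample.int(contig_length - nchar(nt) - 1, 1)
  strand <- sample(c("+", "-"), 1)
  ins <- if (strand == "+") nt else revcomp(nt)
  substr(contig, start, start + nchar(nt) - 1) <- ins
  structure(list(genome_id = genome_id,
                 contigs = setNames(contig, contig_id),
                 quality = list(completeness = 90, contamination = 1,
                                n50 = contig_length, size = contig_length)),
            class = "genome_record")
}

# realized amino-acid identity of an embedded gene, recomputed from the
# emitted contig sequence and the truth coordinates
truth_gene_identity <- function(genome, truth_row, catalog) {
  nt <- substr(genome$contigs[[truth_row$contig]], truth_row$start,
               truth_row$end)
  if (truth_row$strand == "-") nt <- revcomp(nt)
  aa <- magce:::translate_offset(nt, 1)
  query <- if (truth_row$enzyme == "etfb_acd") catalog$aux[["etfb_acd"]]
           else catalog$proteins[[truth_row$enzyme]]
  a <- strsplit(aa, "")[[1]]
  b <- strsplit(query, "")[[1]]
  stopifnot(length(a) == length(b))
  mean(a == b)
}
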