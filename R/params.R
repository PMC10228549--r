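#' Translated homology search parameters
#'
#' Thresholds and scoring constants for the six-frame translated protein
#' search.  The filter thresholds are the ones used for homolog calling:
#' subject hits are kept when `evalue < evalue_max`, `pident > pident_min`
#' and `qcovhsp > qcovhsp_min`.
#'
#' @param evalue_max maximum expectation value (default `1e-10`).
#' @param pident_min minimum percent identity of the alignment (default 25).
#' @param qcovhsp_min minimum percent of the query covered (default 70).
#' @param substitution_matrix scoring matrix name; any matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap costs; a gap of length L costs
#'   `gap_open + L * gap_extend` (defaults 11 and 1, the BLAST convention).
#' @param seed_word_length exact-word seed length in amino acids (default 4).
#' @param karlin_lambda,karlin_K gapped Karlin-Altschul parameters used to
#'   convert raw scores to bit scores; defaults 0.267 and 0.041 are the
#'   published constants for BLOSUM62 with 11/1 gaps.
#' @param ungapped_min minimum x-drop-extended ungapped seed score for a
#'   region to be passed to the exact aligner (default 50; any alignment
#'   able to pass the identity/coverage/E-value filters contains an
#'   ungapped segment far above this).
#' @param xdrop x-drop cutoff for the ungapped extension (default 20).
#'
#' @return An object of class `search_params`.
#' @export
search_params <- function(evalue_max = 1e-10, pident_min = 25,
                          qcovhsp_min = 70,
                          substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          seed_word_length = 4,
                          karlin_lambda = 0.267, karlin_K = 0.041,
                          ungapped_min = 50, xdrop = 20) {
  stopifnot(evalue_max > 0, pident_min >= 0, pident_min <= 100,
            qcovhsp_min >= 0, qcovhsp_min <= 100,
            gap_open >= 0, gap_extend > 0, seed_word_length >= 2,
            karlin_lambda > 0, karlin_K > 0)
  structure(list(evalue_max = evalue_max, pident_min = pident_min,
                 qcovhsp_min = qcovhsp_min,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_word_length = seed_word_length,
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K,
                 ungapped_min = ungapped_min, xdrop = xdrop),
            class = "search_params")
}

#' Dereplication parameters
#'
#' Controls Mash-style ANI estimation and score-weighted representative
#' selection.  The genome score is
#' `comp_weight * completeness - con_weight * contamination +
#'  n50_weight * log10(N50) + size_weight * log10(size)`.
#'
#' @param ani_threshold ANI fraction at or above which two genomes are
#'   considered redundant (default 0.99).
#' @param kmer_size nucleotide k-mer size for sketching (default 16).
#' @param sketch_size number of bottom hashes retained per genome (default
#'   5000).
#' @param comp_weight,con_weight,n50_weight,size_weight score weights;
#'   defaults 1, 0.5, 5 and 0.
#'
#' @return An object of class `derep_params`.
#' @export
derep_params <- function(ani_threshold = 0.99, kmer_size = 16,
                         sketch_size = 5000, comp_weight = 1,
                         con_weight = 0.5, n50_weight = 5, size_weight = 0) {
  stopifnot(ani_threshold > 0.8, ani_threshold <= 1,
            kmer_size >= 4, kmer_size <= 31, sketch_size >= 10,
            is.finite(c(comp_weight, con_weight, n50_weight, size_weight)))
  structure(list(ani_threshold = ani_threshold, kmer_size = kmer_size,
                 sketch_size = sketch_size, comp_weight = comp_weight,
                 con_weight = con_weight, n50_weight = n50_weight,
                 size_weight = size_weight),
            class = "derep_params")
}

#' Rule-classifier thresholds
#'
#' The "high" and "low" pathway-detection bands used by [rule_classify()].
#' A pathway is counted as strongly detected at or above `high` percent of
#' its enzyme roster and as weakly detected at or below `low` percent.
#'
#' @param high high band in percent (default 60).
#' @param low low band in percent (default 40).
#'
#' @return An object of class `rule_thresholds`.
#' @export
rule_thresholds <- function(high = 60, low = 40) {
  stopifnot(low >= 0, low < high, high <= 100)
  structure(list(high = high, low = low), class = "rule_thresholds")
}

#' Simulation configuration
#'
#' Study-condition parameters for the synthetic-data generator.
#'
#' @param seed integer seed; the same seed reproduces byte-identical
#'   outputs.
#' @param n_genomes_per_group genomes simulated per functional group
#'   (default 10).
#' @param contig_length contig length in bp (default 50000).
#' @param n_contigs contigs per genome (default 4).
#' @param gene_identity_levels amino-acid identity levels, fractions in
#'   (0, 1], from which each embedded gene samples its target identity.
#' @param clone_divergence per-site nucleotide substitution rate used by
#'   [simulate_clone()]; must lie in \[0, 0.05\].
#' @param groups group names (default [ce_groups()]).
#' @param abundance_experiments number of simulated experiments (default 4).
#' @param samples_per_experiment samples per experiment (default 6).
#' @param dirichlet_concentration concentration of the per-sample Dirichlet
#'   draw around each experiment's base composition; larger values give
#'   more similar samples within an experiment (default 60).
#' @param residual_range range in percent of the per-sample "unmapped"
#'   residual, drawn uniformly (default `c(5, 35)`).
#' @param embed_etfb whether chain-elongating genomes additionally carry an
#'   ACD-associated EtfB gene (default TRUE).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genomes_per_group = 10,
                       contig_length = 50000, n_contigs = 4,
                       gene_identity_levels = c(0.95, 0.85, 0.75),
                       clone_divergence = 0.005, groups = ce_groups(),
                       abundance_experiments = 4, samples_per_experiment = 6,
                       dirichlet_concentration = 60,
                       residual_range = c(5, 35), embed_etfb = TRUE) {
  stopifnot(all(gene_identity_levels > 0), all(gene_identity_levels <= 1),
            clone_divergence >= 0, clone_divergence <= 0.05,
            n_contigs >= 1, contig_length >= 1000,
            n_genomes_per_group >= 1,
            residual_range[1] >= 0, residual_range[2] < 100,
            all(groups %in% ce_groups()))
  structure(list(seed = as.integer(seed),
                 n_genomes_per_group = n_genomes_per_group,
                 contig_length = contig_length, n_contigs = n_contigs,
                 gene_identity_levels = gene_identity_levels,
                 clone_divergence = clone_divergence, groups = groups,
                 abundance_experiments = abundance_experiments,
                 samples_per_experiment = samples_per_experiment,
                 dirichlet_concentration = dirichlet_concentration,
                 residual_range = residual_range, embed_etfb = embed_etfb),
            class = "sim_config")
}
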