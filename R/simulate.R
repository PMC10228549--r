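# pathways whose full enzyme roster a genome of each group carries
.group_pathways <- list(
  ferment_to_intermediates = c("homolactic_fermentation", "bifid_shunt"),
  intermediate_ce = c("lactic_acid_utilization", "reverse_beta_oxidation"),
  carbohydrate_ce = "reverse_beta_oxidation",
  uninvolved = character(0)
)

#' Simulate a genome with known pathway content
#'
#' Builds a draft genome of `config$n_contigs` random-nucleotide contigs in
#' which every enzyme of the pathways assigned to `group` is embedded as a
#' reverse-translated gene mutated to a sampled target amino-acid identity,
#' on a random strand and frame at a random non-overlapping position.
#' Pathways not assigned to the group contribute at most one enzyme each
#' (embedded with probability 1/2), creating the "low" detection signal.
#' When `config$embed_etfb` is TRUE, intermediate chain elongators
#' additionally carry one ACD-associated EtfB gene (so they hold both EtfB
#' types) and carbohydrate chain elongators carry one ACD-associated EtfB
#' only.
#'
#' Quality metrics are drawn uniformly from completeness 75-100% and
#' contamination 0-7.5%, the bounds observed for curated MAG sets.
#'
#' @param group one of [ce_groups()].
#' @param catalog a [make_pathway_catalog()] object.
#' @param config a [sim_config()] object.
#' @param genome_id identifier (default derived from the group).
#' @param seed integer seed (default `config$seed`).
#'
#' @return A list with `genome` (class `genome_record`: `genome_id`,
#'   `contigs` named character vector, `quality` list) and `truth` (class
#'   `truth_record`: `genome_id`, `true_group`, `embedded_genes` data
#'   frame).
#' @export
simulate_genome <- function(group, catalog, config = sim_config(),
                            genome_id = NULL, seed = config$seed) {
  group <- match.arg(group, ce_groups())
  if (is.null(genome_id)) genome_id <- paste0("MAG_", group)
  with_seed(seed, {
    assigned <- .group_pathways[[group]]
    embed <- unique(unlist(catalog$pathways[assigned]))
    # pathways outside the group contribute <= 1 enzyme
    for (p in setdiff(names(catalog$pathways), assigned)) {
      roster <- catalog$pathways[[p]]
      if (length(intersect(roster, embed)) == 0 && runif(1) < 0.5)
        embed <- c(embed, sample(roster, 1))
    }
    genes <- data.frame(enzyme = embed,
                        pathway = vapply(embed, function(e) {
                          hit <- intersect(assigned, names(catalog$pathways)[
                            vapply(catalog$pathways, function(r) e %in% r,
                                   logical(1))])
                          if (length(hit)) hit[1] else
                            catalog$table$pathway[match(e,
                                                        catalog$table$enzyme)]
                        }, character(1)),
                        protein = unname(catalog$proteins[embed]),
                        row.names = NULL)
    if (config$embed_etfb && group %in% c("intermediate_ce",
                                          "carbohydrate_ce")) {
      genes <- rbind(genes, data.frame(enzyme = "etfb_acd", pathway = "aux",
                                       protein = unname(
                                         catalog$aux[["etfb_acd"]])))
    }

    n_genes <- nrow(genes)
    contig_ids <- sprintf("%s_c%d", genome_id, seq_len(config$n_contigs))
    contigs <- setNames(vapply(seq_len(config$n_contigs),
                               function(i) random_dna(config$contig_length),
                               character(1)), contig_ids)

    truth <- NULL
    if (n_genes > 0) {
      genes$target_identity <- sample(config$gene_identity_levels, n_genes,
                                      replace = TRUE)
      mut <- lapply(seq_len(n_genes), function(i)
        mutate_protein(genes$protein[i], genes$target_identity[i]))
      genes$mut_protein <- vapply(mut, `[[`, character(1), "seq")
      genes$realized_identity <- vapply(mut, `[[`, numeric(1),
                                        "realized_identity")
      genes$nt <- vapply(genes$mut_protein, reverse_translate, character(1))
      genes$len_nt <- nchar(genes$nt)
      genes$contig <- sample(contig_ids, n_genes, replace = TRUE)

      placed <- lapply(contig_ids, function(cid) {
        sub <- genes[genes$contig == cid, , drop = FALSE]
        if (nrow(sub) == 0) return(NULL)
        free <- config$contig_length - sum(sub$len_nt)
        if (free < nrow(sub) + 1)
          stop("contig '", cid, "' too short for ", nrow(sub),
               " requested genes (", sum(sub$len_nt), " nt of genes in ",
               config$contig_length, " nt)")
        sub <- sub[sample.int(nrow(sub)), , drop = FALSE]
        cuts <- sort(sample.int(free, nrow(sub)))
        sub$start <- cuts + c(0, cumsum(sub$len_nt))[seq_len(nrow(sub))]
        sub$end <- sub$start + sub$len_nt - 1
        sub$strand <- sample(c("+", "-"), nrow(sub), replace = TRUE)
        sub
      })
      placed <- do.call(rbind, placed)

      for (i in seq_len(nrow(placed))) {
        cid <- placed$contig[i]
        ins <- if (placed$strand[i] == "+") placed$nt[i]
               else revcomp(placed$nt[i])
        substr(contigs[[cid]], placed$start[i], placed$end[i]) <- ins
      }
      L <- config$contig_length
      placed$frame <- ifelse(
        placed$strand == "+", ((placed$start - 1) %% 3) + 1,
        -((((L - placed$end + 1) - 1) %% 3) + 1))
      truth <- placed[, c("pathway", "enzyme", "contig", "strand", "frame",
                          "start", "end", "target_identity",
                          "realized_identity")]
      rownames(truth) <- NULL
    } else {
      truth <- data.frame(pathway = character(0), enzyme = character(0),
                          contig = character(0), strand = character(0),
                          frame = integer(0), start = integer(0),
                          end = integer(0), target_identity = numeric(0),
                          realized_identity = numeric(0))
    }

    quality <- list(completeness = runif(1, 75, 100),
                    contamination = runif(1, 0, 7.5),
                    n50 = config$contig_length,
                    size = config$n_contigs * config$contig_length)

    genome <- structure(list(genome_id = genome_id, contigs = contigs,
                             quality = quality), class = "genome_record")
    truth_rec <- structure(list(genome_id = genome_id, true_group = group,
                                embedded_genes = truth),
                           class = "truth_record")
    list(genome = genome, truth = truth_rec)
  })
}

#' Simulate a near-clone of a genome
#'
#' Applies independent per-site nucleotide substitutions at rate
#' `divergence` to every contig, so the expected ANI to the parent is
#' `1 - divergence`.  Quality metrics are re-drawn near the parent's.
#'
#' @param genome a `genome_record`.
#' @param divergence substitution rate per site, in \[0, 0.05\].
#' @param seed integer seed.
#' @param genome_id identifier for the clone (default parent id +
#'   `"_clone"`).
#' @return A `genome_record`.
#' @export
simulate_clone <- function(genome, divergence, seed = 1,
                           genome_id = paste0(genome$genome_id, "_clone")) {
  stopifnot(divergence >= 0, divergence <= 0.05)
  with_seed(seed, {
    contigs <- vapply(genome$contigs, mutate_dna, character(1),
                      rate = divergence)
    names(contigs) <- sub(genome$genome_id, genome_id, names(genome$contigs),
                          fixed = TRUE)
    q <- genome$quality
    quality <- list(
      completeness = min(100, max(75, q$completeness + runif(1, -2, 2))),
      contamination = min(7.5, max(0, q$contamination + runif(1, -0.5, 0.5))),
      n50 = q$n50, size = q$size)
    structure(list(genome_id = genome_id, contigs = contigs,
                   quality = quality), class = "genome_record")
  })
}

#' Simulate a labeled cohort of genomes
#'
#' Generates `config$n_genomes_per_group` genomes for every group in
#' `config$groups`, each with its truth record.
#'
#' @param catalog a [make_pathway_catalog()] object.
#' @param config a [sim_config()] object.
#' @param seed integer seed (default `config$seed`).
#' @return A list with `genomes` (named list of `genome_record`), `truths`
#'   (named list of `truth_record`) and `quality` (data frame with columns
#'   `genome_id`, `completeness`, `contamination`, `n50`, `size`).
#' @export
simulate_cohort <- function(catalog, config = sim_config(),
                            seed = config$seed) {
  abbr <- c(ferment_to_intermediates = "fti", intermediate_ce = "ice",
            carbohydrate_ce = "cce", uninvolved = "unv")
  genomes <- list()
  truths <- list()
  i <- 0
  for (group in config$groups) {
    for (g in seq_len(config$n_genomes_per_group)) {
      i <- i + 1
      id <- sprintf("MAG_%s_%02d", abbr[[group]], g)
      sim <- simulate_genome(group, catalog, config, genome_id = id,
                             seed = sub_seed(seed, i))
      genomes[[id]] <- sim$genome
      truths[[id]] <- sim$truth
    }
  }
  quality <- do.call(rbind, lapply(genomes, function(g)
    data.frame(genome_id = g$genome_id, completeness = g$quality$completeness,
               contamination = g$quality$contamination, n50 = g$quality$n50,
               size = g$quality$size)))
  rownames(quality) <- NULL
  list(genomes = genomes, truths = truths, quality = quality)
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate experiment-structured relative abundances
#'
#' Draws per-sample MAG relative abundances from experiment-specific
#' Dirichlet distributions: each experiment has a sparse base composition
#' and samples within it are Dirichlet draws concentrated around that base,
#' so within-experiment Bray-Curtis dissimilarity is smaller than
#' between-experiment dissimilarity in expectation.  Each sample carries an
#' "unmapped" residual drawn uniformly from `config$residual_range`, and
#' MAG fractions plus residual sum to exactly 100%.
#'
#' @param genome_ids character vector of genome identifiers (or a list of
#'   `truth_record`s).
#' @param config a [sim_config()] object.
#' @param seed integer seed (default `config$seed`).
#' @return An [abundance_table()] object.
#' @export
simulate_abundance <- function(genome_ids, config = sim_config(),
                               seed = config$seed) {
  if (is.list(genome_ids))
    genome_ids <- vapply(genome_ids, `[[`, character(1), "genome_id")
  n_exp <- config$abundance_experiments
  n_samp <- config$samples_per_experiment
  stopifnot(n_exp >= 2, n_samp >= 2)
  ng <- length(genome_ids)
  with_seed(seed, {
    cols <- list()
    meta <- list()
    residuals <- numeric(0)
    for (e in seq_len(n_exp)) {
      base <- rdirichlet1(rep(0.3, ng))
      base <- pmax(base, 1e-8)
      base <- base / sum(base)
      for (s in seq_len(n_samp)) {
        p <- rdirichlet1(config$dirichlet_concentration * ng * base / ng)
        res <- runif(1, config$residual_range[1], config$residual_range[2])
        frac <- (100 - res) * p / sum(p)
        sid <- sprintf("exp%d_s%02d", e, s)
        cols[[sid]] <- frac
        residuals[sid] <- res
        meta[[sid]] <- data.frame(sample_id = sid,
                                  experiment = sprintf("experiment_%d", e),
                                  timepoint = s)
      }
    }
    abund <- do.call(cbind, cols)
    rownames(abund) <- genome_ids
    abundance_table(abund, residuals, do.call(rbind, meta))
  })
}

#' Simulate a dereplication fixture with planted near-clones
#'
#' Generates `n_total - n_clones` mutually unrelated random genomes plus
#' `n_clones` near-clones of distinct parents at the given nucleotide
#' divergence, together with a quality table.  With the default divergence
#' the clones sit above the 99% ANI dereplication threshold, so the fixture
#' collapses to exactly `n_total - n_clones` representatives.
#'
#' @param n_total total genome count (default 240).
#' @param n_clones planted near-clone count (default 23).
#' @param divergence per-site substitution rate of the clones (default
#'   0.0025, i.e. about 99.75% ANI).
#' @param contig_length,n_contigs genome shape (defaults 25000 and 2).
#' @param seed integer seed.
#' @return A list with `genomes`, `quality` and `parent` (named character
#'   vector mapping each clone to its parent).
#' @export
simulate_derep_fixture <- function(n_total = 240, n_clones = 23,
                                   divergence = 0.0025,
                                   contig_length = 25000, n_contigs = 2,
                                   seed = 1) {
  stopifnot(n_clones < n_total)
  n_base <- n_total - n_clones
  genomes <- list()
  with_seed(seed, {
    for (i in seq_len(n_base)) {
      id <- sprintf("G%03d", i)
      contigs <- setNames(vapply(seq_len(n_contigs),
                                 function(k) random_dna(contig_length),
                                 character(1)),
                          sprintf("%s_c%d", id, seq_len(n_contigs)))
      quality <- list(completeness = runif(1, 75, 100),
                      contamination = runif(1, 0, 7.5),
                      n50 = contig_length, size = n_contigs * contig_length)
      genomes[[id]] <- structure(list(genome_id = id, contigs = contigs,
                                      quality = quality),
                                 class = "genome_record")
    }
    parents <- sample(names(genomes), n_clones)
    parent_map <- character(0)
    for (j in seq_len(n_clones)) {
      id <- sprintf("G%03d_dup", match(parents[j], names(genomes)))
      genomes[[id]] <- simulate_clone(genomes[[parents[j]]], divergence,
                                      seed = sub_seed(seed, j),
                                      genome_id = id)
      parent_map[id] <- parents[j]
    }
    quality <- do.call(rbind, lapply(genomes, function(g)
      data.frame(genome_id = g$genome_id,
                 completeness = g$quality$completeness,
                 contamination = g$quality$contamination, n50 = g$quality$n50,
                 size = g$quality$size)))
    rownames(quality) <- NULL
    list(genomes = genomes, quality = quality, parent = parent_map)
  })
}
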