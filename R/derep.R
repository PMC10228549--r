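#' Quality-weighted genome score
#'
#' `score = comp_weight * completeness - con_weight * contamination +
#'  n50_weight * log10(N50) + size_weight * log10(size)`.
#' With the default weights (1, 0.5, 5, 0) a genome at 100% completeness,
#' 0% contamination and N50 of 1 Mb scores 130.
#'
#' @param completeness percent in \[0, 100\].
#' @param contamination percent, non-negative.
#' @param n50 assembly N50 in bp (must be >= 1).
#' @param size genome size in bp (only used when `size_weight != 0`).
#' @param params a [derep_params()] object.
#' @return Numeric score (vectorised over the inputs).
#' @export
genome_score <- function(completeness, contamination, n50, size = 1,
                         params = derep_params()) {
  if (any(n50 < 1)) stop("N50 must be >= 1")
  stopifnot(all(completeness >= 0), all(completeness <= 100),
            all(contamination >= 0))
  params$comp_weight * completeness - params$con_weight * contamination +
    params$n50_weight * log10(n50) + params$size_weight * log10(size)
}

genome_sketch <- function(genome, params = derep_params()) {
  contigs <- if (inherits(genome, "genome_record")) genome$contigs
             else genome
  if (sum(nchar(contigs)) < params$kmer_size)
    stop("genome shorter than k-mer size")
  parts <- lapply(contigs, cpp_sketch, k = params$kmer_size,
                  sketch_size = params$sketch_size)
  merged <- sort(unique(unlist(parts)))
  merged[seq_len(min(length(merged), params$sketch_size))]
}

sketch_ani <- function(s1, s2, params) {
  k <- params$kmer_size
  s <- min(params$sketch_size, length(s1), length(s2))
  uni <- sort(unique(c(s1, s2)))[seq_len(min(s, length(unique(c(s1, s2)))))]
  shared <- sum(uni %in% s1 & uni %in% s2)
  if (shared < 3) return(0) # below detection: unrelated sentinel
  j <- shared / length(uni)
  ani <- 1 + log(2 * j / (1 + j)) / k
  min(1, max(0, ani))
}

#' Mash-style ANI estimate between two genomes
#'
#' Sketches both genomes with bottom-s canonical k-mer hashing, computes
#' the sketch Jaccard index `j` and converts it with the Mash relation
#' `ANI = 1 + (1/k) * ln(2j / (1 + j))`.  Genomes sharing fewer sketch
#' hashes than expected by chance report 0 (the "unrelated" sentinel).
#'
#' @param g1,g2 `genome_record` objects (or named contig vectors).
#' @param params a [derep_params()] object.
#' @return ANI as a fraction in \[0, 1\]; identical genomes give 1.
#' @export
estimate_ani <- function(g1, g2, params = derep_params()) {
  sketch_ani(genome_sketch(g1, params), genome_sketch(g2, params), params)
}

#' Dereplicate a genome set at an ANI threshold
#'
#' Greedy best-first clustering: genomes are sorted by
#' [genome_score()] descending (ties by id) and each genome joins the
#' first existing representative with ANI at or above
#' `params$ani_threshold`, otherwise it founds a new cluster.
#' Representatives are therefore the highest-scoring member of each
#' cluster, and the representative set does not depend on input order.
#'
#' @param genomes named list of `genome_record` objects.
#' @param quality data frame with columns `genome_id`, `completeness`,
#'   `contamination`, `n50` and optionally `size`; every genome must be
#'   present.
#' @param params a [derep_params()] object.
#' @return Data frame with columns `genome_id`, `cluster_id`,
#'   `is_representative`, `score`, `ani_to_rep`, ordered by score
#'   descending.
#' @export
dereplicate <- function(genomes, quality, params = derep_params()) {
  stopifnot(length(genomes) >= 1)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  missing <- setdiff(ids, quality$genome_id)
  if (length(missing))
    stop("genomes missing from quality table: ",
         paste(missing, collapse = ", "))
  qrow <- quality[match(ids, quality$genome_id), ]
  size <- if ("size" %in% names(qrow)) qrow$size
          else vapply(genomes, function(g) sum(nchar(g$contigs)), numeric(1))
  scores <- genome_score(qrow$completeness, qrow$contamination, qrow$n50,
                         size, params)
  names(scores) <- ids
  ord <- order(-scores, ids)

  sketches <- new.env(parent = emptyenv())
  get_sketch <- function(id) {
    if (is.null(sketches[[id]]))
      sketches[[id]] <- genome_sketch(genomes[[match(id, ids)]], params)
    sketches[[id]]
  }

  reps <- character(0)
  assign_rep <- character(0)
  ani_to_rep <- numeric(0)
  for (i in ord) {
    id <- ids[i]
    sk <- get_sketch(id)
    placed <- FALSE
    for (r in reps) {
      ani <- sketch_ani(sk, get_sketch(r), params)
      if (ani >= params$ani_threshold) {
        assign_rep[id] <- r
        ani_to_rep[id] <- ani
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign_rep[id] <- id
      ani_to_rep[id] <- 1
    }
  }

  cluster_id <- setNames(sprintf("cluster_%03d", seq_along(reps)), reps)
  out <- data.frame(genome_id = ids[ord],
                    cluster_id = unname(cluster_id[assign_rep[ids[ord]]]),
                    is_representative = ids[ord] %in% reps,
                    score = unname(scores[ids[ord]]),
                    ani_to_rep = unname(ani_to_rep[ids[ord]]))
  rownames(out) <- NULL
  out
}
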