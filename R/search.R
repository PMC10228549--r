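# map alignment coordinates on a translated frame back to 1-based inclusive
# nucleotide coordinates on the forward strand of the contig
frame_to_nt <- function(frame, aa_start, aa_end, contig_len) {
  k <- abs(frame)
  a <- k + 3 * (aa_start - 1)
  b <- k + 3 * aa_end - 1
  if (frame > 0) c(a, b) else c(contig_len - b + 1, contig_len - a + 1)
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), qstart = integer(0),
             qend = integer(0), sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0), frame = integer(0),
             qcovhsp = numeric(0), raw_score = integer(0),
             genome_id = character(0))
}

#' Search a genome for pathway-enzyme homologs
#'
#' Runs every catalog query against all six translated frames of every
#' contig.  Candidate regions are located by exact-word seeding with
#' x-drop ungapped extension, then aligned with the exact affine-gap local
#' aligner in a window around the seeded region.  Hits are kept only if
#' they pass all three filters — `evalue < evalue_max`, `pident >
#' pident_min` and `qcovhsp > qcovhsp_min` — and at most one hit per query
#' is retained for the genome: the highest bit score, ties broken by
#' contig id and then subject start.
#'
#' `pident` is `100 * identities / aln_length` and `qcovhsp` is
#' `100 * (qend - qstart + 1) / query_length`.  Subject coordinates are
#' reported 1-based inclusive on the forward strand; `frame` is one of
#' +1..+3 (forward) or -1..-3 (reverse complement).
#'
#' @param catalog a [make_pathway_catalog()] object, or a named character
#'   vector of protein query sequences.
#' @param genome a `genome_record` (or a named character vector of
#'   contigs).
#' @param params a [search_params()] object.
#' @param best_per_query keep only the best filtered hit per query
#'   (default TRUE; FALSE retains every filtered locus, as needed for
#'   multi-copy gene families).
#' @return Data frame with BLAST outfmt-6-like columns: `qseqid`,
#'   `sseqid`, `pident`, `length`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `frame`, `qcovhsp`, plus `raw_score` and
#'   `genome_id`.
#' @export
search_genome <- function(catalog, genome, params = search_params(),
                          best_per_query = TRUE) {
  queries <- if (inherits(catalog, "pathway_catalog")) catalog$proteins
             else catalog
  stopifnot(length(queries) > 0)
  contigs <- if (inherits(genome, "genome_record")) genome$contigs
             else genome
  genome_id <- if (inherits(genome, "genome_record")) genome$genome_id
               else "genome"
  if (length(contigs) == 0) return(empty_hits())

  mat <- substitution_matrix(params$substitution_matrix)
  alphabet <- paste(rownames(mat), collapse = "")
  qlen <- nchar(queries)

  frames_per_contig <- lapply(contigs, six_frame_translate)
  db_len <- sum(vapply(frames_per_contig, function(f) sum(nchar(f)),
                       numeric(1)))

  frame_codes <- c(1L, 2L, 3L, -1L, -2L, -3L)
  rows <- list()
  for (ci in seq_along(contigs)) {
    fr <- frames_per_contig[[ci]]
    raw <- cpp_search_frames(unname(queries), unname(fr), mat, alphabet,
                             params$gap_open, params$gap_extend,
                             params$seed_word_length, params$ungapped_min,
                             params$xdrop)
    if (nrow(raw) == 0) next
    raw$qseqid <- names(queries)[raw$qidx]
    raw$frame <- frame_codes[raw$fidx]
    raw$sseqid <- names(contigs)[ci]
    raw$contig_len <- nchar(contigs[[ci]])
    rows[[length(rows) + 1]] <- raw
  }
  if (length(rows) == 0) return(empty_hits())
  h <- do.call(rbind, rows)

  h$bitscore <- bitscore(h$raw_score, params)
  h$evalue <- evalue(h$bitscore, qlen[h$qseqid], db_len)
  h$length <- h$aln_length
  h$pident <- 100 * h$identities / h$aln_length
  h$qcovhsp <- 100 * (h$qend - h$qstart + 1) / qlen[h$qseqid]

  keep <- h$evalue < params$evalue_max & h$pident > params$pident_min &
    h$qcovhsp > params$qcovhsp_min
  h <- h[keep, , drop = FALSE]
  if (nrow(h) == 0) return(empty_hits())

  nt <- t(mapply(frame_to_nt, h$frame, h$sstart_aa, h$send_aa,
                 h$contig_len))
  h$sstart <- as.integer(nt[, 1])
  h$send <- as.integer(nt[, 2])
  h$genome_id <- genome_id

  h <- h[order(h$qseqid, -h$bitscore, h$sseqid, h$sstart), , drop = FALSE]
  if (best_per_query) h <- h[!duplicated(h$qseqid), , drop = FALSE]
  out <- h[, c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
               "sstart", "send", "evalue", "bitscore", "frame", "qcovhsp",
               "raw_score", "genome_id")]
  rownames(out) <- NULL
  out
}

#' Search a cohort of genomes
#'
#' @param catalog a [make_pathway_catalog()] object.
#' @param genomes list of `genome_record` objects.
#' @param params a [search_params()] object.
#' @return Row-bound hit table over all genomes (see [search_genome()]).
#' @export
search_cohort <- function(catalog, genomes, params = search_params()) {
  out <- do.call(rbind, lapply(genomes, search_genome, catalog = catalog,
                               params = params))
  rownames(out) <- NULL
  out
}
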