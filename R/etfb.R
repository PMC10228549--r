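#' Simulate labeled EtfB reference sequences
#'
#' Builds two divergent EtfB families: the lactic-acid-utilization
#' (ecLDH-partnered) family descends from the catalog's LAU-roster EtfB
#' query, and the chain-elongation (acyl-CoA-dehydrogenase-partnered)
#' family from the catalog's auxiliary `etfb_acd` ancestor.  Members of a
#' family are mutants of their ancestor at the given amino-acid identity;
#' the two ancestors are unrelated random proteins, so between-family
#' identity sits at background level.
#'
#' @param catalog a [make_pathway_catalog()] object.
#' @param seed integer seed.
#' @param n_per_label references per label (default 3, minimum 2).
#' @param identity within-family identity of each reference to its
#'   ancestor (default 0.9).
#' @return Data frame of class `etfb_references`: columns `id`, `label`
#'   (`LAU_associated` / `ACD_associated`), `sequence`.
#' @export
simulate_etfb_references <- function(catalog, seed = 1, n_per_label = 3,
                                     identity = 0.9) {
  stopifnot(n_per_label >= 2)
  anc <- c(LAU_associated = unname(catalog$proteins[["etfB"]]),
           ACD_associated = unname(catalog$aux[["etfb_acd"]]))
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(anc), function(lab) {
      seqs <- vapply(seq_len(n_per_label), function(i)
        mutate_protein(anc[[lab]], identity)$seq, character(1))
      data.frame(id = sprintf("%s_ref%d", tolower(substr(lab, 1, 3)),
                              seq_len(n_per_label)),
                 label = lab, sequence = seqs)
    }))
    rownames(out) <- NULL
    class(out) <- c("etfb_references", class(out))
    out
  })
}

#' Write / read labeled EtfB references as FASTA
#'
#' Labels are carried in the header as `>id|label`.
#'
#' @param refs an `etfb_references` data frame.
#' @param path FASTA path.
#' @return Invisibly `path`; `read_etfb_references` returns the data
#'   frame.
#' @export
write_etfb_references <- function(refs, path) {
  seqs <- setNames(refs$sequence, paste(refs$id, refs$label, sep = "|"))
  write_fasta(seqs, path, type = "aa")
  invisible(path)
}

#' @rdname write_etfb_references
#' @export
read_etfb_references <- function(path) {
  seqs <- read_fasta(path, type = "aa")
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  out <- data.frame(id = vapply(parts, `[`, character(1), 1),
                    label = vapply(parts, `[`, character(1), 2),
                    sequence = unname(seqs))
  class(out) <- c("etfb_references", class(out))
  out
}

#' Find EtfB homolog loci in a genome
#'
#' Searches all labeled references against the genome with the translated
#' homology search (default thresholds: identity > 25%, query coverage >
#' 70%), keeping every filtered locus.  Hits from different references
#' that overlap on the same contig are merged into one candidate; the hit
#' with the longest alignment (ties by bit score) represents the locus,
#' and the candidate protein is the translated subject region of that
#' hit.
#'
#' @param genome a `genome_record`.
#' @param references an `etfb_references` data frame.
#' @param params a [search_params()] object.
#' @return Data frame with one row per candidate locus: `genome_id`,
#'   `contig`, `sstart`, `send`, `frame`, `best_ref`, `n_refs`,
#'   `candidate_seq`.  Zero rows when the genome has no EtfB locus.
#' @export
find_etfb_homologs <- function(genome, references,
                               params = search_params()) {
  queries <- setNames(references$sequence, references$id)
  hits <- search_genome(queries, genome, params, best_per_query = FALSE)
  if (nrow(hits) == 0)
    return(data.frame(genome_id = character(0), contig = character(0),
                      sstart = integer(0), send = integer(0),
                      frame = integer(0), best_ref = character(0),
                      n_refs = integer(0), candidate_seq = character(0)))
  hits <- hits[order(hits$sseqid, hits$sstart), , drop = FALSE]
  locus <- integer(nrow(hits))
  cur <- 0
  cur_end <- -Inf
  cur_contig <- ""
  for (i in seq_len(nrow(hits))) {
    if (hits$sseqid[i] != cur_contig || hits$sstart[i] > cur_end) {
      cur <- cur + 1
      cur_contig <- hits$sseqid[i]
      cur_end <- hits$send[i]
    } else {
      cur_end <- max(cur_end, hits$send[i])
    }
    locus[i] <- cur
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(hits)), locus),
                               function(idx) {
    sub <- hits[idx, , drop = FALSE]
    best <- sub[order(-sub$length, -sub$bitscore), ][1, ]
    contig <- genome$contigs[[best$sseqid]]
    fr <- six_frame_translate(contig)
    aa <- fr[[c("+1", "+2", "+3", "-1", "-2", "-3")[
      match(best$frame, c(1, 2, 3, -1, -2, -3))]]]
    # recover the frame-local aa coordinates of the reported nt interval
    L <- nchar(contig)
    k <- abs(best$frame)
    if (best$frame > 0) {
      aa_start <- (best$sstart - k) / 3 + 1
      aa_end <- (best$send - k + 1) / 3
    } else {
      aa_start <- ((L - best$send + 1) - k) / 3 + 1
      aa_end <- ((L - best$sstart + 1) - k + 1) / 3
    }
    data.frame(genome_id = best$genome_id, contig = best$sseqid,
               sstart = best$sstart, send = best$send, frame = best$frame,
               best_ref = best$qseqid, n_refs = length(unique(sub$qseqid)),
               candidate_seq = substr(aa, aa_start, aa_end))
  }))
  rownames(out) <- NULL
  out
}

ref_identity_distance <- function(candidate, ref_seq, params) {
  mat <- substitution_matrix(params$substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(candidate), Biostrings::AAString(ref_seq),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  # identity relative to the shorter sequence: a short spurious overlap of
  # unrelated proteins then scores as distant, a true homolog as close
  1 - Biostrings::pid(aln, type = "PID3") / 100
}

#' Assign a function label to an EtfB candidate
#'
#' Computes an ends-free pairwise-alignment identity distance
#' (`1 - identity`) from the candidate to every labeled reference and
#' assigns the label of the nearest reference, provided the gap between
#' the best distances of the two labels reaches `margin_min`; otherwise
#' the candidate is `"other"` (no clear function).
#'
#' @param candidate amino-acid string.
#' @param references an `etfb_references` data frame (non-empty).
#' @param margin_min minimum identity-distance margin (default 0.10).
#' @param params a [search_params()] object (alignment scoring).
#' @return A list with `label` (`LAU_associated`, `ACD_associated` or
#'   `other`), `margin` and `distances` (best distance per label).
#' @export
assign_label <- function(candidate, references, margin_min = 0.10,
                         params = search_params()) {
  if (nrow(references) == 0) stop("empty reference set")
  d <- vapply(references$sequence, ref_identity_distance, numeric(1),
              candidate = candidate, params = params)
  best_per_label <- tapply(d, references$label, min)
  ord <- order(best_per_label)
  margin <- if (length(best_per_label) < 2) Inf
            else best_per_label[ord[2]] - best_per_label[ord[1]]
  label <- if (margin >= margin_min) names(best_per_label)[ord[1]]
           else "other"
  list(label = label, margin = unname(margin),
       distances = best_per_label)
}

#' EtfB calls for a set of genomes
#'
#' Convenience wrapper: finds candidate loci per genome and labels each.
#'
#' @param genomes named list of `genome_record` objects.
#' @param references an `etfb_references` data frame.
#' @param margin_min minimum label margin (default 0.10).
#' @param params a [search_params()] object.
#' @return Data frame: `genome_id`, `contig`, `sstart`, `send`, `frame`,
#'   `label`, `margin`.
#' @export
etfb_calls <- function(genomes, references, margin_min = 0.10,
                       params = search_params()) {
  rows <- lapply(genomes, function(g) {
    cands <- find_etfb_homologs(g, references, params)
    if (nrow(cands) == 0) return(NULL)
    lab <- lapply(cands$candidate_seq, assign_label,
                  references = references, margin_min = margin_min,
                  params = params)
    cands$label <- vapply(lab, `[[`, character(1), "label")
    cands$margin <- vapply(lab, `[[`, numeric(1), "margin")
    cands[, c("genome_id", "contig", "sstart", "send", "frame", "label",
              "margin")]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(genome_id = character(0), contig = character(0),
                      sstart = integer(0), send = integer(0),
                      frame = integer(0), label = character(0),
                      margin = numeric(0))
  rownames(out) <- NULL
  out
}

#' Summarise EtfB calls by functional group
#'
#' Produces the per-genome presence table of LAU-associated,
#' ACD-associated and unresolved EtfB homologs, joined with the
#' functional-group calls, plus per-group counts and the tally of genomes
#' carrying both homolog types.
#'
#' @param calls output of [etfb_calls()].
#' @param functional_calls data frame with `genome_id` and `group`.
#' @return A list with `table` (per-genome booleans `has_lau`, `has_acd`,
#'   `has_other` and `group`), `counts` (per-group sums) and `n_both`
#'   (genomes with both labeled homolog types).  Empty input gives empty
#'   output.
#' @export
summarize_etfb <- function(calls, functional_calls) {
  ids <- unique(functional_calls$genome_id)
  if (length(ids) == 0)
    return(list(table = data.frame(genome_id = character(0),
                                   group = character(0),
                                   has_lau = logical(0),
                                   has_acd = logical(0),
                                   has_other = logical(0)),
                counts = NULL, n_both = 0L))
  tab <- data.frame(
    genome_id = ids,
    group = functional_calls$group[match(ids, functional_calls$genome_id)],
    has_lau = vapply(ids, function(g)
      any(calls$genome_id == g & calls$label == "LAU_associated"),
      logical(1)),
    has_acd = vapply(ids, function(g)
      any(calls$genome_id == g & calls$label == "ACD_associated"),
      logical(1)),
    has_other = vapply(ids, function(g)
      any(calls$genome_id == g & calls$label == "other"), logical(1)))
  rownames(tab) <- NULL
  counts <- aggregate(cbind(has_lau, has_acd, has_other) ~ group, tab, sum)
  list(table = tab, counts = counts,
       n_both = sum(tab$has_lau & tab$has_acd))
}
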