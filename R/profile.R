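#' Build a per-genome pathway profile from filtered hits
#'
#' An enzyme counts as present when it has at least one retained hit in
#' the genome.  Pathway completeness is the percent of the roster
#' detected; `unique_enzyme_percent` restricts the roster to enzymes that
#' occur in exactly one pathway (the `is_unique` flag).
#'
#' @param hits a filtered hit table from [search_genome()] (rows for other
#'   genomes are ignored via `genome_id`).
#' @param catalog a [make_pathway_catalog()] object.
#' @param genome_id the genome the profile describes.
#' @return An object of class `pathway_profile`: `genome_id`,
#'   `per_pathway_percent`, `per_enzyme_present`, `unique_enzyme_percent`.
#' @export
build_profile <- function(hits, catalog, genome_id) {
  h <- hits[hits$genome_id == genome_id, , drop = FALSE]
  enzymes <- names(catalog$proteins)
  unknown <- setdiff(unique(h$qseqid), enzymes)
  if (length(unknown))
    stop("hit table references unknown queries: ",
         paste(unknown, collapse = ", "))
  present <- setNames(as.integer(enzymes %in% h$qseqid), enzymes)
  uniq <- catalog$table$enzyme[catalog$table$is_unique]
  per_pathway <- vapply(catalog$pathways, function(r)
    100 * sum(present[r]) / length(r), numeric(1))
  per_unique <- vapply(catalog$pathways, function(r) {
    ru <- intersect(r, uniq)
    if (length(ru) == 0) return(NA_real_)
    100 * sum(present[ru]) / length(ru)
  }, numeric(1))
  structure(list(genome_id = genome_id, per_pathway_percent = per_pathway,
                 per_enzyme_present = present,
                 unique_enzyme_percent = per_unique),
            class = "pathway_profile")
}

#' Build profiles for every genome in a hit table
#'
#' @param hits hit table from [search_cohort()].
#' @param catalog a [make_pathway_catalog()] object.
#' @param genome_ids genomes to profile (defaults to those in `hits`;
#'   pass the full cohort so genomes without hits get all-zero profiles).
#' @return Named list of `pathway_profile` objects.
#' @export
build_profiles <- function(hits, catalog, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- unique(hits$genome_id)
  profs <- lapply(genome_ids, build_profile, hits = hits, catalog = catalog)
  names(profs) <- genome_ids
  profs
}

#' Profile matrix (genomes x features)
#'
#' Fixed column order: pathway completeness percentages first (catalog
#' pathway order, prefixed `pct_`), then per-enzyme presence bits
#' (prefixed `enz_`).  Rows are sorted by genome id.
#'
#' @param profiles list of `pathway_profile` objects.
#' @return Numeric matrix with genome ids as row names.
#' @export
profile_matrix <- function(profiles) {
  ids <- vapply(profiles, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids))
    stop("duplicate genome_id in profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids)
  m <- do.call(rbind, lapply(profiles[ord], function(p)
    c(p$per_pathway_percent, p$per_enzyme_present)))
  colnames(m) <- c(paste0("pct_", names(profiles[[1]]$per_pathway_percent)),
                   paste0("enz_", names(profiles[[1]]$per_enzyme_present)))
  rownames(m) <- ids[ord]
  m
}

#' Hierarchical clustering of genome profiles
#'
#' Agglomerative clustering of the rows of a profile matrix, by default
#' with Euclidean distance and complete linkage (the defaults of the
#' heatmap tooling this emulates).  Returns the merge tree, the leaf order
#' and a Newick rendering of the dendrogram.
#'
#' @param m numeric matrix (rows are clustered); must be finite.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @param distance distance method for [stats::dist()] (default
#'   `"euclidean"`).
#' @return A list with `hclust`, `order` (leaf labels in dendrogram
#'   order) and `newick`.
#' @export
hierarchical_cluster <- function(m, linkage = "complete",
                                 distance = "euclidean") {
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  if (!all(is.finite(m))) stop("profile matrix contains non-finite values")
  hc <- hclust(dist(m, method = distance), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, order = rownames(m)[hc$order], newick = newick)
}
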