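AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# canonical enzyme name pools per pathway; "xpk" (phosphoketolase) is shared
# between the heterolactic phosphoketolase pathway and the bifid shunt
.default_rosters <- list(
  homolactic_fermentation = c("glk", "pgi", "pfkA", "fba", "gap", "pgk",
                              "pyk", "ldh"),
  phosphoketolase = c("xpk", "zwf", "pgl", "gnd", "rpe", "rpiA", "ackA",
                      "adhE", "eno"),
  bifid_shunt = c("xpk", "glkB", "tal", "tkt", "r5pi", "xu5pe", "ldhB",
                  "pta", "ackB", "galE"),
  lactic_acid_utilization = c("ecLDH", "etfA", "etfB"),
  reverse_beta_oxidation = c("thlA", "hbd", "crt", "acdEB")
)

#' Build a synthetic pathway catalog
#'
#' Generates the five default fermentation/chain-elongation pathways with
#' random protein query sequences for every enzyme.  The lactic acid
#' utilization roster holds exactly three enzymes (ecLDH and the two
#' electron-transfer flavoprotein subunits EtfA/EtfB) and the reverse
#' beta-oxidation roster exactly four (including the acetyl-CoA
#' C-acetyltransferase `thlA` and the electron-bifurcating acyl-CoA
#' dehydrogenase `acdEB`).  One enzyme, the phosphoketolase `xpk`, appears
#' in both heterolactic rosters, so it is not flagged `is_unique`.
#'
#' The catalog also carries one auxiliary (non-roster) sequence,
#' `etfb_acd`, the ancestor of the ACD-associated EtfB family used by the
#' EtfB function-assignment analysis.
#'
#' @param seed integer seed; identical seeds give identical catalogs.
#' @param roster_sizes named integer vector of enzymes per pathway.  Only
#'   the roster sizes of the three carbohydrate-fermentation pathways are
#'   meant to be varied; the analysis consumes percentages, so absolute
#'   roster sizes beyond the fixed LAU (3) and rBOX (4) rosters are free
#'   parameters.
#' @param protein_length_range amino-acid length range of the generated
#'   query proteins (default 200-500).
#'
#' @return An object of class `pathway_catalog`: a list with `pathways`
#'   (named list of enzyme rosters), `proteins` (named character vector of
#'   amino-acid sequences), `table` (data frame with columns `pathway`,
#'   `enzyme`, `is_unique`) and `aux` (auxiliary sequences).
#' @export
make_pathway_catalog <- function(seed = 1,
                                 roster_sizes = c(
                                   homolactic_fermentation = 8,
                                   phosphoketolase = 9,
                                   bifid_shunt = 10,
                                   lactic_acid_utilization = 3,
                                   reverse_beta_oxidation = 4),
                                 protein_length_range = c(200, 500)) {
  stopifnot(all(names(roster_sizes) %in% names(.default_rosters)),
            all(roster_sizes >= 1))
  with_seed(seed, {
    pathways <- lapply(names(.default_rosters), function(p) {
      pool <- .default_rosters[[p]]
      size <- roster_sizes[[p]]
      if (size <= length(pool)) pool[seq_len(size)]
      else c(pool, sprintf("%s_enz%02d", p, seq_len(size - length(pool))))
    })
    names(pathways) <- names(.default_rosters)

    enzymes <- unique(unlist(pathways))
    proteins <- vapply(enzymes, function(e) {
      random_protein(sample(protein_length_range[1]:protein_length_range[2],
                            1))
    }, character(1))

    counts <- table(unlist(lapply(pathways, unique)))
    tab <- do.call(rbind, lapply(names(pathways), function(p) {
      data.frame(pathway = p, enzyme = pathways[[p]],
                 is_unique = counts[pathways[[p]]] == 1,
                 row.names = NULL)
    }))
    rownames(tab) <- NULL

    aux <- c(etfb_acd = random_protein(
      sample(protein_length_range[1]:protein_length_range[2], 1)))

    structure(list(pathways = pathways, proteins = proteins, table = tab,
                   aux = aux),
              class = "pathway_catalog")
  })
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat("pathway catalog:", length(x$pathways), "pathways,",
      length(x$proteins), "distinct enzymes\n")
  for (p in names(x$pathways)) {
    ros <- x$pathways[[p]]
    uniq <- sum(x$table$is_unique[x$table$pathway == p])
    cat(sprintf("  %-24s %2d enzymes (%d unique)\n", p, length(ros), uniq))
  }
  invisible(x)
}

#' Write a pathway catalog to disk
#'
#' Writes the query proteins as a FASTA file (`queries.faa`) and the
#' pathway definitions as a TSV (`pathways.tsv`, columns `pathway`,
#' `enzyme`, `is_unique`).  Auxiliary sequences go to `aux.faa`.
#'
#' @param catalog a [make_pathway_catalog()] object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  faa <- file.path(dir, "queries.faa")
  tsv <- file.path(dir, "pathways.tsv")
  aux <- file.path(dir, "aux.faa")
  write_fasta(catalog$proteins, faa, type = "aa")
  write_tsv(catalog$table, tsv)
  write_fasta(catalog$aux, aux, type = "aa")
  invisible(c(faa, tsv, aux))
}

#' Read a pathway catalog from disk
#'
#' @param dir directory holding `queries.faa`, `pathways.tsv` and
#'   optionally `aux.faa`, as written by [write_catalog()].
#' @return A `pathway_catalog` object.
#' @export
read_catalog <- function(dir) {
  proteins <- read_fasta(file.path(dir, "queries.faa"), type = "aa")
  tab <- read_tsv(file.path(dir, "pathways.tsv"))
  tab$is_unique <- as.logical(tab$is_unique)
  missing <- setdiff(tab$enzyme, names(proteins))
  if (length(missing))
    stop("pathway table names enzymes absent from queries.faa: ",
         paste(missing, collapse = ", "))
  pathways <- split(tab$enzyme, tab$pathway)
  pathways <- pathways[intersect(names(.default_rosters), names(pathways))]
  aux_path <- file.path(dir, "aux.faa")
  aux <- if (file.exists(aux_path)) read_fasta(aux_path, type = "aa")
         else character(0)
  structure(list(pathways = pathways, proteins = proteins, table = tab,
                 aux = aux),
            class = "pathway_catalog")
}
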