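.matrix_env <- new.env(parent = emptyenv())

#' Fetch a protein substitution matrix
#'
#' Loads a scoring matrix shipped with Biostrings (e.g. BLOSUM62) and
#' caches it.
#'
#' @param name matrix name (default `"BLOSUM62"`).
#' @return Integer matrix with residue row/column names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (is.null(.matrix_env[[name]])) {
    e <- new.env()
    data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    storage.mode(m) <- "integer"
    .matrix_env[[name]] <- m
  }
  .matrix_env[[name]]
}

#' Optimal local protein alignment (affine gaps)
#'
#' Computes the exact affine-gap Smith-Waterman optimum between two
#' protein sequences, scored with the named substitution matrix; a gap of
#' length L costs `gap_open + L * gap_extend`.  Residues absent from the
#' matrix (and stop codons in translated frames, which BLOSUM62 carries as
#' `*`) are scored through the corresponding matrix row.  Among
#' equal-scoring alignments the one with the smallest query end, then
#' subject end, is reported.
#'
#' @param query,subject amino-acid strings.
#' @param params a [search_params()] object.
#' @return A list with `score`, `qstart`, `qend`, `sstart`, `send`
#'   (1-based inclusive), `identities` and `aln_length`, or `NULL` when no
#'   positive-scoring local alignment exists.
#' @export
local_align <- function(query, subject, params = search_params()) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  mat <- substitution_matrix(params$substitution_matrix)
  r <- cpp_sw_align(toupper(query), toupper(subject), mat,
                    paste(rownames(mat), collapse = ""),
                    params$gap_open, params$gap_extend)
  if (r$score <= 0) return(NULL)
  r
}

#' Bit score from a raw alignment score
#'
#' `bits = (lambda * raw - ln K) / ln 2` with the gapped Karlin-Altschul
#' parameters in `params`.
#'
#' @param raw_score raw alignment score.
#' @param params a [search_params()] object.
#' @return Bit score.
#' @export
bitscore <- function(raw_score, params = search_params()) {
  (params$karlin_lambda * raw_score - log(params$karlin_K)) / log(2)
}

#' Karlin-Altschul expectation value
#'
#' `E = m * n * 2^(-bits)` for query length `m` and database length `n`
#' (amino acids).
#'
#' @param bits bit score.
#' @param query_len query length in residues.
#' @param db_len searched database length in residues.
#' @return Expectation value (> 0, monotone decreasing in `bits`).
#' @export
evalue <- function(bits, query_len, db_len) {
  stopifnot(query_len > 0, db_len > 0)
  query_len * db_len * 2^(-bits)
}
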