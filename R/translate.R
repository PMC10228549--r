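# codon machinery built from the standard genetic code shipped with
# Biostrings (identical to the bacterial/archaeal table 11 for all sense
# codons); lookups are arithmetic on base indices for speed.

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # codon index = 16*a + 4*b + c + 1 with A,C,G,T -> 0..3
  idx <- vapply(codons, function(cd) {
    v <- match(strsplit(cd, "")[[1]], bases) - 1L
    16L * v[1] + 4L * v[2] + v[3] + 1L
  }, integer(1))
  aa <- character(64)
  aa[idx] <- unname(gc[codons])
  .codon_env$aa <- aa
  .codon_env$aa_code <- utf8ToInt(paste(aa, collapse = ""))
  .codon_env$base_val <- {
    bv <- rep(NA_integer_, 256)
    bv[utf8ToInt("A")] <- 0L; bv[utf8ToInt("C")] <- 1L
    bv[utf8ToInt("G")] <- 2L; bv[utf8ToInt("T")] <- 3L
    bv
  }
  syn <- split(codons, unname(gc[codons]))
  .codon_env$synonymous <- syn[setdiff(names(syn), "*")]
  .codon_env
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq a single nucleotide string over A, C, G, T, N.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_offset <- function(seq, offset) {
  L <- nchar(seq)
  n_codons <- (L - offset + 1) %/% 3
  if (n_codons <= 0) return("")
  tb <- codon_tables()
  v <- tb$base_val[utf8ToInt(substr(seq, offset, offset + 3 * n_codons - 1))]
  i1 <- v[seq.int(1, by = 3, length.out = n_codons)]
  i2 <- v[seq.int(2, by = 3, length.out = n_codons)]
  i3 <- v[seq.int(3, by = 3, length.out = n_codons)]
  idx <- 16L * i1 + 4L * i2 + i3 + 1L
  bad <- is.na(idx)
  if (any(bad)) idx[bad] <- 1L
  code <- tb$aa_code[idx]
  if (any(bad)) code[bad] <- 88L # 'X' for codons containing N
  intToUtf8(code)
}

#' Six-frame translation
#'
#' Translates a contig in all six reading frames: `+1..+3` from the forward
#' strand and `-1..-3` from the reverse complement.  Stop codons are
#' retained as `*`; codons containing `N` translate to `X`.
#'
#' @param seq a single nucleotide string over A, C, G, T, N (case
#'   insensitive).
#' @return Named character vector of six amino-acid sequences, names
#'   `"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`.
#' @export
six_frame_translate <- function(seq) {
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  if (nchar(seq) == 0)
    return(setNames(rep("", 6), c("+1", "+2", "+3", "-1", "-2", "-3")))
  rc <- revcomp(seq)
  out <- c(translate_offset(seq, 1), translate_offset(seq, 2),
           translate_offset(seq, 3), translate_offset(rc, 1),
           translate_offset(rc, 2), translate_offset(rc, 3))
  setNames(out, c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# uniform-random synonymous reverse translation of a protein (no stop codon
# appended: embedded genes are plain CDS fragments)
reverse_translate <- function(protein) {
  tb <- codon_tables()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    syn <- tb$synonymous[[a]]
    if (is.null(syn)) stop("cannot reverse-translate residue '", a, "'")
    syn[sample.int(length(syn), 1)]
  }, character(1)), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

# substitute enough residues to hit the target amino-acid identity exactly
# (up to rounding); substitutions are always to a different residue
mutate_protein <- function(protein, target_identity) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  k <- round((1 - target_identity) * n)
  if (k > 0) {
    pos <- sample.int(n, k)
    aa[pos] <- vapply(aa[pos], function(a) sample(setdiff(AA20, a), 1),
                      character(1))
  }
  list(seq = paste(aa, collapse = ""), realized_identity = 1 - k / n)
}

# per-site nucleotide substitution at the given rate
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  code <- utf8ToInt(seq)
  pos <- which(runif(length(code)) < rate)
  if (length(pos)) {
    bases <- c(65L, 67L, 71L, 84L)
    # shift each mutated base to one of the three other bases
    cur <- match(code[pos], bases)
    code[pos] <- bases[((cur - 1L + sample.int(3, length(pos),
                                               replace = TRUE)) %% 4L) + 1L]
  }
  intToUtf8(code)
}
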