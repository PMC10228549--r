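#' Read a FASTA file
#'
#' Tolerates wrapped lines and CRLF endings; sequences are upper-cased on
#' read.  Duplicate record ids and malformed records are errors that name
#' the file (and, for malformed input, the offending line).
#'
#' @param path file path.
#' @param type `"dna"` (validated against A, C, G, T, N) or `"aa"`.
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  nonempty <- which(nzchar(lines))
  if (length(nonempty) == 0) return(setNames(character(0), character(0)))
  if (!startsWith(lines[nonempty[1]], ">"))
    stop("corrupt FASTA '", path, "': line ", nonempty[1],
         " should begin a record with '>'")
  ok_chars <- if (type == "dna") "^[ACGTN]*$" else "^[A-Z*]*$"
  headers <- integer(0)
  for (i in nonempty) {
    if (startsWith(lines[i], ">")) {
      headers <- c(headers, i)
    } else if (!grepl(ok_chars, toupper(lines[i]))) {
      stop("corrupt FASTA '", path, "': invalid characters at line ", i)
    }
  }
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bounds <- c(headers, length(lines) + 1)
  seqs <- vapply(seq_along(headers), function(j) {
    body <- lines[seq(bounds[j] + 1, bounds[j + 1] - 1)]
    body <- body[nzchar(body)]
    toupper(paste(body, collapse = ""))
  }, character(1))
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path file path.
#' @param type `"dna"` or `"aa"` (controls the Biostrings container used).
#' @param width line wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa"), width = 70) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write genome records to a directory of FASTA files
#'
#' One `<genome_id>.fna` multi-FASTA per genome.
#'
#' @param genomes list of `genome_record` objects.
#' @param dir output directory.
#' @return Invisibly, the file paths.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(genomes, function(g) {
    p <- file.path(dir, paste0(g$genome_id, ".fna"))
    write_fasta(g$contigs, p, type = "dna")
    p
  }, character(1))
  invisible(paths)
}

#' Read genome records from a directory of FASTA files
#'
#' @param dir directory of `.fna`/`.fa`/`.fasta` files; the genome id is
#'   the file name without extension.
#' @param quality optional quality data frame (columns `genome_id`,
#'   `completeness`, `contamination`, `n50`, optionally `size`) used to
#'   populate the quality slot.
#' @return Named list of `genome_record` objects.
#' @export
read_genomes <- function(dir, quality = NULL) {
  files <- list.files(dir, pattern = "\\.(fna|fa|fasta)$", full.names = TRUE)
  genomes <- lapply(files, function(f) {
    id <- sub("\\.(fna|fa|fasta)$", "", basename(f))
    contigs <- read_fasta(f, type = "dna")
    q <- list(completeness = NA_real_, contamination = NA_real_,
              n50 = NA_real_, size = sum(nchar(contigs)))
    if (!is.null(quality) && id %in% quality$genome_id) {
      row <- quality[quality$genome_id == id, ]
      q <- list(completeness = row$completeness[1],
                contamination = row$contamination[1], n50 = row$n50[1],
                size = if ("size" %in% names(row)) row$size[1]
                       else sum(nchar(contigs)))
    }
    structure(list(genome_id = id, contigs = contigs, quality = q),
              class = "genome_record")
  })
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  genomes
}

write_abundance <- function(table, abund_path, meta_path) {
  m <- rbind(table$abund, unmapped = table$residual)
  df <- data.frame(genome_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, abund_path)
  write_tsv(table$metadata, meta_path)
  invisible(c(abund_path, meta_path))
}

read_abundance <- function(abund_path, meta_path) {
  df <- read_tsv(abund_path)
  meta <- read_tsv(meta_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genome_id
  res <- m["unmapped", ]
  m <- m[rownames(m) != "unmapped", , drop = FALSE]
  abundance_table(m, res, meta)
}
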