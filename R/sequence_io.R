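#' Clean a raw nucleotide string
#'
#' Uppercases `a/c/g/t` and strips every character outside the four-letter
#' DNA alphabet (Ns, IUPAC ambiguity codes, gaps, whitespace), counting the
#' removals. Block entropies are defined over \{A,C,G,T\} only, so ambiguous
#' positions are deleted rather than masked; this keeps every downstream
#' block at exactly `B` valid bases.
#'
#' @param raw Character scalar, the sequence as read (any case, may contain
#'   non-ACGT characters).
#' @return A list with `residues` (cleaned string), `source_length` (number
#'   of characters in `raw`) and `removed_count`.
#' @examples
#' clean_sequence("ACGTNNNacgt")
#' @export
clean_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop("'raw' must be a non-empty character scalar")
  src <- nchar(raw)
  residues <- gsub("[^ACGT]", "", toupper(raw))
  if (nchar(residues) == 0L)
    stop("no valid A/C/G/T bases remain after cleaning")
  list(residues = residues,
       source_length = src,
       removed_count = src - nchar(residues))
}

#' Construct a genome sequence record
#'
#' The unit of comparison for the whole pipeline: a labelled DNA string over
#' \{A,C,G,T\} together with bookkeeping of how much was removed by cleaning.
#'
#' @param label Non-empty character scalar identifying the genome.
#' @param raw Character scalar; cleaned with [clean_sequence()].
#' @return An object of class `genome_seq` with fields `label`, `residues`,
#'   `source_length`, `removed_count`.
#' @export
genome_sequence <- function(label, raw) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      nchar(label) == 0L)
    stop("'label' must be a non-empty character scalar")
  cl <- clean_sequence(raw)
  structure(c(list(label = label), cl), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp (%d of %d input characters removed)\n",
              x$label, nchar(x$residues), x$removed_count, x$source_length))
  invisible(x)
}

#' @export
length.genome_seq <- function(x) nchar(x$residues)

#' Read genomes from a FASTA file
#'
#' Reads one FASTA file (plain or gzipped) into `genome_seq` records. By
#' default all records in the file are concatenated, in file order, into a
#' single genome labelled by the file stem -- the natural treatment for
#' multi-chromosome assemblies, giving one entropy distribution per
#' organism. With `combine = FALSE` each record becomes its own genome,
#' labelled by the first word of its header.
#'
#' Cleaning (see [clean_sequence()]) is applied after concatenation.
#'
#' @param path Path to a FASTA file.
#' @param combine Concatenate all records into one genome? Default `TRUE`.
#' @return A list of `genome_seq` objects.
#' @export
read_fasta <- function(path, combine = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("cannot parse FASTA file '", path, "': ",
                             conditionMessage(e)))
  if (length(set) == 0L)
    stop("no FASTA records in '", path, "'")
  seqs <- unname(as.character(set))
  if (all(nchar(seqs) == 0L))
    stop("all records in '", path, "' are empty")
  if (isTRUE(combine)) {
    stem <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                basename(path), ignore.case = TRUE)
    return(list(genome_sequence(stem, paste(seqs, collapse = ""))))
  }
  labels <- vapply(names(set), function(h) strsplit(trimws(h), "\\s+")[[1L]][1L],
                   character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate record labels in '", path, "'")
  genomes <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    genomes[[i]] <- tryCatch(
      genome_sequence(labels[i], seqs[i]),
      error = function(e) stop("record '", labels[i], "' in '", path, "': ",
                               conditionMessage(e)))
  }
  genomes
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `genome_seq` or list of them.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param width Line width for wrapping, default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  stopifnot(all(vapply(genomes, inherits, logical(1L), "genome_seq")))
  seqs <- Biostrings::BStringSet(vapply(genomes, `[[`, character(1L), "residues"))
  names(seqs) <- vapply(genomes, `[[`, character(1L), "label")
  Biostrings::writeXStringSet(seqs, path, format = "fasta",
                              compress = grepl("\\.gz$", path), width = width)
  invisible(path)
}
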