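# Internal: map an ACGT string to integer codes 1..4 (A,C,G,T).
.base_codes <- c(A = 65L, C = 67L, G = 71L, T = 84L)

.encode_bases <- function(residues) {
  v <- utf8ToInt(residues)
  idx <- integer(length(v))
  idx[v == 65L] <- 1L
  idx[v == 67L] <- 2L
  idx[v == 71L] <- 3L
  idx[v == 84L] <- 4L
  if (any(idx == 0L))
    stop("sequence contains characters outside {A,C,G,T}; clean it first")
  idx
}

#' Partition a genome into fixed-size blocks
#'
#' Splits the cleaned sequence into `floor(len / B)` consecutive,
#' non-overlapping blocks of exactly `B` bases, in genome order. The
#' trailing remainder (fewer than `B` bases) is discarded, never padded:
#' the entropy of a short block is not on the same scale as that of a
#' full-length block.
#'
#' @param genome A `genome_seq` object.
#' @param B Block size in nucleotides, integer >= 2.
#' @return A list with `blocks` (character vector of length-`B` strings)
#'   and `discarded_tail` (number of trailing bases dropped).
#' @export
block_partition <- function(genome, B) {
  stopifnot(inherits(genome, "genome_seq"))
  B <- .check_block_size(B)
  len <- nchar(genome$residues)
  if (len < B)
    stop("genome '", genome$label, "' (", len,
         " bp) is shorter than block size B = ", B)
  n <- len %/% B
  starts <- (seq_len(n) - 1L) * B + 1L
  list(blocks = substring(genome$residues, starts, starts + B - 1L),
       discarded_tail = len - n * B)
}

.check_block_size <- function(B) {
  if (length(B) != 1L || is.na(B) || B < 2 || B != as.integer(B))
    stop("block size B must be a single integer >= 2")
  as.integer(B)
}

#' Nucleotide counts of one block
#'
#' @param block A string over \{A,C,G,T\}.
#' @return Named integer vector of counts for A, C, G, T.
#' @export
block_counts <- function(block) {
  idx <- .encode_bases(block)
  counts <- tabulate(idx, nbins = 4L)
  names(counts) <- c("A", "C", "G", "T")
  counts
}

#' Shannon entropy of a block composition
#'
#' Plug-in Shannon entropy, in bits, of the single-nucleotide frequency
#' vector of one block: `H = -sum_x p(x) log2 p(x)` with the convention
#' `0 * log 0 = 0`. Ranges from 0 (homopolymer) to 2 bits (all four bases
#' equally frequent).
#'
#' @param counts Named or unnamed vector of four non-negative counts
#'   (A, C, G, T order if unnamed).
#' @return Entropy in bits, a scalar in `[0, 2]`.
#' @examples
#' block_entropy(c(A = 25, C = 25, G = 25, T = 25))  # 2 bits
#' block_entropy(c(A = 100, C = 0, G = 0, T = 0))    # 0 bits
#' @export
block_entropy <- function(counts) {
  counts <- .check_counts(counts)
  total <- sum(counts)
  p <- counts[counts > 0] / total
  h <- -sum(p * log2(p))
  min(max(h, 0), 2)
}

#' GC fraction of a block composition
#'
#' Local entropy tracks GC fraction almost one-to-one under Chargaff's
#' second parity rule, so the per-block GC fraction is carried alongside
#' the entropy as a diagnostic.
#'
#' @inheritParams block_entropy
#' @return `(C + G) / B`, a scalar in `[0, 1]`.
#' @export
block_gc <- function(counts) {
  counts <- .check_counts(counts)
  unname((counts[2L] + counts[3L]) / sum(counts))
}

.check_counts <- function(counts) {
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0))
    stop("'counts' must be four non-negative values (A, C, G, T)")
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), c("A", "C", "G", "T")))
      stop("named 'counts' must use names A, C, G, T")
    counts <- counts[c("A", "C", "G", "T")]
  }
  if (sum(counts) <= 0) stop("all-zero counts")
  counts
}

#' Per-block entropy profile of a genome
#'
#' Partitions the genome into blocks of `B` nucleotides and computes the
#' Shannon entropy (bits) and GC fraction of every block, preserving
#' genome order.
#'
#' @param genome A `genome_seq` object.
#' @param B Block size in nucleotides (default 100).
#' @return An object of class `entropy_profile`: a list with
#'   `genome_label`, `block_size`, `entropies`, `gc`, `n_blocks`,
#'   `discarded_tail`.
#' @export
entropy_profile <- function(genome, B = 100L) {
  stopifnot(inherits(genome, "genome_seq"))
  B <- .check_block_size(B)
  len <- nchar(genome$residues)
  if (len < B)
    stop("genome '", genome$label, "' (", len,
         " bp) is shorter than block size B = ", B)
  n <- len %/% B
  idx <- .encode_bases(substr(genome$residues, 1L, n * B))
  m <- matrix(idx, nrow = B)
  counts <- matrix(0L, nrow = n, ncol = 4L)
  for (k in 1:4) counts[, k] <- colSums(m == k)
  p <- counts / B
  terms <- p * log2(p)
  terms[p == 0] <- 0
  h <- pmin(pmax(-rowSums(terms), 0), 2)
  structure(list(genome_label = genome$label,
                 block_size = B,
                 entropies = h,
                 gc = (counts[, 2L] + counts[, 3L]) / B,
                 n_blocks = n,
                 discarded_tail = len - n * B),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf(paste0("<entropy_profile> %s: N = %d blocks of B = %d nt ",
                     "(tail %d nt discarded)\n  entropy [bits]: "),
              x$genome_label, x$n_blocks, x$block_size, x$discarded_tail))
  print(summary(x$entropies))
  invisible(x)
}

#' Profile as a per-block table
#'
#' One row per block with 0-based half-open coordinates on the cleaned
#' sequence: block `i` covers positions `[i * B, (i + 1) * B)`.
#'
#' @param profile An `entropy_profile`.
#' @return A data.frame with columns `genome`, `block_index`, `start`,
#'   `end`, `entropy_bits`, `gc_fraction`.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "entropy_profile"))
  i <- seq_len(profile$n_blocks) - 1L
  data.frame(genome = profile$genome_label,
             block_index = i,
             start = i * profile$block_size,
             end = (i + 1L) * profile$block_size,
             entropy_bits = profile$entropies,
             gc_fraction = profile$gc,
             stringsAsFactors = FALSE)
}
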