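# Independent oracles and small fixture builders. These deliberately use
# different primitives (table(), strsplit(), plain sums) from the package
# code they check.

# Brute-force Shannon entropy (bits) of one block string.
brute_block_entropy <- function(block) {
  chars <- strsplit(block, "")[[1]]
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  p <- as.numeric(tab) / length(chars)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Shannon entropy (bits) of a probability vector; used for the
# mixture-entropy form of the Jensen-Shannon divergence.
vec_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Mixture-entropy form of D_JS: H((p+q)/2) - H(p)/2 - H(q)/2.
js_mixture_form <- function(p, q) {
  vec_entropy((p + q) / 2) - vec_entropy(p) / 2 - vec_entropy(q) / 2
}

binary_entropy <- function(x) {
  out <- numeric(length(x))
  ok <- x > 0 & x < 1
  out[ok] <- -x[ok] * log2(x[ok]) - (1 - x[ok]) * log2(1 - x[ok])
  out
}

random_block <- function(B) {
  paste(sample(c("A", "C", "G", "T"), B, replace = TRUE,
               prob = runif(4) + 0.05), collapse = "")
}

# Random block satisfying Chargaff parity: count(A) == count(T),
# count(C) == count(G). B must be even.
random_parity_block <- function(B) {
  at <- 2L * sample.int(B %/% 2 + 1L, 1L) - 2L  # even in [0, B]
  cg <- B - at
  paste(sample(c(rep("A", at / 2), rep("T", at / 2),
                 rep("C", cg / 2), rep("G", cg / 2))), collapse = "")
}

random_prob_vector <- function(n) {
  x <- stats::rexp(n)
  # sprinkle structural zeros so zero-handling paths are exercised
  x[stats::runif(n) < 0.3] <- 0
  if (sum(x) == 0) x[1] <- 1
  x / sum(x)
}

write_tmp_fasta <- function(lines, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# entropy_distribution with prescribed two-bin probabilities, built through
# the public pipeline (M = 2 over [0, 2]: entropy 0 -> bin 1, 2 -> bin 2).
two_bin_dist <- function(label, probs2) {
  n0 <- round(probs2[1] * 4)
  seqs <- c(rep("AAAA", n0), rep("ACGT", 4 - n0))
  g <- genome_sequence(label, paste(seqs, collapse = ""))
  histogram_entropies(entropy_profile(g, 4), make_binning(2, 0, 2))
}
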