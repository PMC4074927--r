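#' Along-sequence GC composition regime
#'
#' Describes how the GC fraction of a synthetic genome varies along the
#' sequence. A fresh GC value is drawn per segment (see [genome_spec()]),
#' so the regime controls the spread of blockwise composition -- and
#' hence the shape of the block-entropy distribution: a fixed GC gives a
#' unimodal, narrow distribution (virus-like), a wide beta distribution
#' gives a broad one (plant-like), and a two-point mixture gives up to
#' two modes.
#'
#' Within a drawn GC value `g`, base probabilities are
#' `p(C) = g/2 (1 + cg_skew)`, `p(G) = g/2 (1 - cg_skew)`,
#' `p(A) = (1 - g)/2 (1 + at_skew)`, `p(T) = (1 - g)/2 (1 - at_skew)`.
#' Zero skews give exact Chargaff parity in expectation.
#'
#' @param type `"fixed"`, `"beta"` or `"two_point"`.
#' @param gc GC fraction for `type = "fixed"`.
#' @param alpha,beta Shape parameters for `type = "beta"`.
#' @param gc1,gc2,weight Two-point mixture: GC is `gc1` with probability
#'   `weight`, else `gc2`.
#' @param at_skew,cg_skew A-vs-T and C-vs-G imbalances in `[-1, 1]`.
#' @return An object of class `composition_regime`.
#' @export
composition_regime <- function(type = c("fixed", "beta", "two_point"),
                               gc = 0.5, alpha = 2, beta = 2,
                               gc1 = 0.35, gc2 = 0.65, weight = 0.5,
                               at_skew = 0, cg_skew = 0) {
  type <- match.arg(type)
  if (abs(at_skew) > 1 || abs(cg_skew) > 1)
    stop("skews must lie in [-1, 1]")
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("'", nm, "' must be a single value in [0, 1]")
  }
  switch(type,
         fixed = chk01(gc, "gc"),
         beta = {
           if (alpha <= 0 || beta <= 0) stop("beta shapes must be positive")
         },
         two_point = {
           chk01(gc1, "gc1"); chk01(gc2, "gc2"); chk01(weight, "weight")
         })
  structure(list(type = type, gc = gc, alpha = alpha, beta = beta,
                 gc1 = gc1, gc2 = gc2, weight = weight,
                 at_skew = at_skew, cg_skew = cg_skew),
            class = "composition_regime")
}

.regime_label <- function(r) {
  switch(r$type,
         fixed = sprintf("fixed(gc=%g)", r$gc),
         beta = sprintf("beta(%g,%g)", r$alpha, r$beta),
         two_point = sprintf("two_point(%g,%g,w=%g)", r$gc1, r$gc2, r$weight))
}

.draw_gc <- function(regime, n) {
  switch(regime$type,
         fixed = rep(regime$gc, n),
         beta = stats::rbeta(n, regime$alpha, regime$beta),
         two_point = ifelse(stats::runif(n) < regime$weight,
                            regime$gc1, regime$gc2))
}

.base_probs <- function(gc, regime) {
  p <- c(A = (1 - gc) / 2 * (1 + regime$at_skew),
         C = gc / 2 * (1 + regime$cg_skew),
         G = gc / 2 * (1 - regime$cg_skew),
         T = (1 - gc) / 2 * (1 - regime$at_skew))
  if (any(p < 0) || any(p > 1))
    stop("skew/gc combination implies base probabilities outside [0, 1]")
  p
}

#' Specification of one synthetic genome
#'
#' @param label Genome label.
#' @param length Total length in nucleotides.
#' @param regime A [composition_regime()].
#' @param segment_length Granularity (nt) at which a fresh GC value is
#'   drawn; default 1000, deliberately decoupled from any block size so
#'   segment boundaries need not align with analysis blocks.
#' @param seed Mandatory integer seed; identical specs give identical
#'   sequences.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(label, length, regime, segment_length = 1000L, seed) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory: synthetic genomes carry no implicit randomness")
  if (length < segment_length || segment_length < 1L)
    stop("need length >= segment_length >= 1")
  stopifnot(inherits(regime, "composition_regime"))
  structure(list(label = label, length = as.integer(length),
                 segment_length = as.integer(segment_length),
                 regime = regime, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome
#'
#' Draws a GC value per segment from the spec's composition regime, then
#' draws bases i.i.d. within each segment from the implied base
#' probabilities. Bases are independent within a segment (no dinucleotide
#' structure): the block-entropy method only sees single-nucleotide
#' composition, so first-order structure exercises every code path.
#' The caller's RNG state is left untouched.
#'
#' @param spec A [genome_spec()].
#' @return A `genome_seq` of exactly `spec$length` bases.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  nseg <- ceiling(spec$length / spec$segment_length)
  gc_vals <- .draw_gc(spec$regime, nseg)
  lens <- rep(spec$segment_length, nseg)
  lens[nseg] <- spec$length - (nseg - 1L) * spec$segment_length
  codes <- c(65L, 67L, 71L, 84L)  # A C G T
  parts <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    p <- .base_probs(gc_vals[s], spec$regime)
    parts[[s]] <- sample.int(4L, lens[s], replace = TRUE, prob = p)
  }
  genome_sequence(spec$label, intToUtf8(codes[unlist(parts)]))
}

#' Derive a per-genome seed from a cohort master seed
#'
#' Polynomial hash `((master * 31 + group_index) * 31 + genome_index + 1)`
#' reduced modulo `2^31 - 1`, so any single cohort member can be
#' regenerated in isolation from `(master_seed, group_index,
#' genome_index)` alone.
#'
#' @param master_seed Integer master seed.
#' @param group_index,genome_index 1-based indices within the cohort.
#' @return A positive integer seed below `2^31`.
#' @export
derive_seed <- function(master_seed, group_index, genome_index) {
  m <- 2147483647
  h <- (as.numeric(master_seed) %% m)
  h <- (h * 31 + group_index) %% m
  as.integer((h * 31 + genome_index + 1) %% m)
}

#' Generate a labelled cohort of synthetic genomes
#'
#' Produces `n` genomes per group, each group under its own composition
#' regime, with per-genome seeds derived from the master seed via
#' [derive_seed()] so the cohort is reproducible as a whole and each
#' member individually. This is the planted-grouping fixture: groups with
#' distinct regimes should be recovered as clades by the entropy-distance
#' pipeline, mimicking host-specific virus clusters.
#'
#' @param groups List of group descriptions, each a list with `name`,
#'   `regime` (a [composition_regime()]), `n` (>= 2 genomes) and `length`
#'   (nt). At least two groups.
#' @param seed Integer master seed.
#' @param segment_length Passed to [genome_spec()].
#' @return A list with `genomes` (list of `genome_seq`), `group` (character
#'   vector, parallel to `genomes`) and `manifest` (data.frame with label,
#'   group, length, regime, seed).
#' @export
generate_cohort <- function(groups, seed, segment_length = 1000L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  for (g in groups) {
    if (!all(c("name", "regime", "n", "length") %in% names(g)))
      stop("each group needs fields name, regime, n, length")
    if (g$n < 2L) stop("group '", g$name, "' needs at least 2 genomes")
  }
  genomes <- list()
  group_of <- character(0)
  manifest <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    for (ji in seq_len(g$n)) {
      s <- derive_seed(seed, gi, ji)
      lab <- sprintf("%s_%02d", g$name, ji)
      spec <- genome_spec(lab, g$length, g$regime,
                          segment_length = segment_length, seed = s)
      genomes[[length(genomes) + 1L]] <- generate_genome(spec)
      group_of <- c(group_of, g$name)
      manifest[[length(manifest) + 1L]] <-
        data.frame(label = lab, group = g$name, length = g$length,
                   regime = .regime_label(g$regime), seed = s,
                   stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes, group = group_of,
       manifest = do.call(rbind, manifest))
}
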