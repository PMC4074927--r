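.check_prob_vector <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0))
    stop("'", what, "' must be a vector of non-negative probabilities")
  if (abs(sum(p) - 1) > 1e-8)
    stop("'", what, "' is not normalized (sums to ", format(sum(p)), ")")
  p
}

#' Kullback-Leibler divergence (bits)
#'
#' Relative entropy `sum_j p_j log2(p_j / m_j)` of `p` against `m`, with
#' zero-probability terms of `p` contributing nothing. Requires the
#' support of `p` to be contained in the support of `m`; within the
#' Jensen-Shannon construction this always holds because `m` is a mixture
#' containing `p`.
#'
#' @param p,m Probability vectors of equal length.
#' @return Divergence in bits, non-negative.
#' @export
kl_divergence <- function(p, m) {
  if (length(p) != length(m))
    stop("'p' and 'm' have different lengths (", length(p), " vs ",
         length(m), ")")
  p <- .check_prob_vector(p, "p")
  m <- .check_prob_vector(m, "m")
  on <- p > 0
  if (any(m[on] == 0))
    stop("support violation: p > 0 where m == 0, KL divergence is infinite")
  max(sum(p[on] * log2(p[on] / m[on])), 0)
}

.dist_probs <- function(x, what) {
  if (inherits(x, "entropy_distribution")) x$probs
  else .check_prob_vector(x, what)
}

.check_shared_scheme <- function(p, q) {
  if (inherits(p, "entropy_distribution") &&
      inherits(q, "entropy_distribution") &&
      !.same_scheme(p$scheme, q$scheme))
    stop("distributions were built on different binning schemes ",
         "(M or range differ); rebuild them on a shared scheme ",
         "rather than comparing across binnings")
  invisible(NULL)
}

#' Jensen-Shannon divergence between entropy distributions (bits)
#'
#' `D_JS(p, q) = (1/2) D_KL(p || m) + (1/2) D_KL(q || m)` with the
#' equal-weight mixture `m = (p + q) / 2` as the intermediate
#' distribution. Symmetric, always finite, and bounded by 1 bit with
#' base-2 logarithms. Bins empty in both distributions contribute
#' nothing. Distributions must share an identical binning scheme;
#' mismatches are refused rather than silently rebinned.
#'
#' @param p,q `entropy_distribution` objects on one shared binning scheme,
#'   or bare probability vectors of equal length.
#' @return Divergence in bits, in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  .check_shared_scheme(p, q)
  pv <- .dist_probs(p, "p")
  qv <- .dist_probs(q, "q")
  if (length(pv) != length(qv))
    stop("'p' and 'q' have different lengths")
  m <- (pv + qv) / 2
  keep <- m > 0
  kl_term <- function(a) {
    on <- keep & a > 0
    sum(a[on] * log2(a[on] / m[on]))
  }
  min(max(0.5 * kl_term(pv) + 0.5 * kl_term(qv), 0), 1)
}

#' Jensen-Shannon metric distance
#'
#' The square root of the Jensen-Shannon divergence, which (unlike the
#' divergence itself) satisfies the triangle inequality and is therefore
#' a true metric suitable for distance-matrix clustering. The raw
#' divergence is available with `mode = "raw_js"` for comparison.
#'
#' @inheritParams js_divergence
#' @param mode `"sqrt_js"` (default, the metric) or `"raw_js"`.
#' @return Distance in `[0, 1]`.
#' @export
js_metric <- function(p, q, mode = c("sqrt_js", "raw_js")) {
  mode <- match.arg(mode)
  d <- js_divergence(p, q)
  if (mode == "sqrt_js") sqrt(d) else d
}

#' Pairwise Jensen-Shannon distance matrix over a genome set
#'
#' @param dists List of >= 2 `entropy_distribution` objects on one shared
#'   binning scheme, with unique genome labels.
#' @param mode Passed to [js_metric()].
#' @return An object of class `js_distmat`: a list with `labels`,
#'   `values` (symmetric matrix with zero diagonal) and `meta`
#'   (`B`, `M`, bin range, mode).
#' @export
distance_matrix <- function(dists, mode = c("sqrt_js", "raw_js")) {
  mode <- match.arg(mode)
  if (!is.list(dists) || length(dists) < 2L ||
      !all(vapply(dists, inherits, logical(1L), "entropy_distribution")))
    stop("'dists' must be a list of at least two entropy_distribution objects")
  labels <- vapply(dists, `[[`, character(1L), "genome_label")
  if (anyDuplicated(labels))
    stop("duplicate genome labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  schemes <- lapply(dists, `[[`, "scheme")
  for (s in schemes[-1L])
    if (!.same_scheme(schemes[[1L]], s))
      stop("distributions use mixed binning schemes; rebuild on one scheme")
  n <- length(dists)
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- js_metric(dists[[i]], dists[[j]], mode = mode)
      v[i, j] <- d
      v[j, i] <- d
    }
  }
  Bs <- unique(vapply(dists, `[[`, integer(1L), "block_size"))
  structure(list(labels = labels, values = v,
                 meta = list(B = Bs,
                             M = schemes[[1L]]$n_bins,
                             lower = schemes[[1L]]$lower,
                             upper = schemes[[1L]]$upper,
                             mode = mode)),
            class = "js_distmat")
}

#' @export
print.js_distmat <- function(x, ...) {
  cat(sprintf("<js_distmat> %d genomes (B = %s, M = %d, %s)\n",
              length(x$labels), paste(x$meta$B, collapse = ","),
              x$meta$M, x$meta$mode))
  print(round(x$values, 4))
  invisible(x)
}

#' Write a distance matrix as tab-separated text
#'
#' Square matrix with a header row and a leading label column.
#'
#' @param dm A `js_distmat`.
#' @param path Output path.
#' @param digits Decimal places (fixed-width formatting), default 6.
#' @return `path`, invisibly.
#' @export
write_distmat_tsv <- function(dm, path, digits = 6L) {
  stopifnot(inherits(dm, "js_distmat"))
  fmt <- paste0("%.", digits, "f")
  rows <- vapply(seq_along(dm$labels), function(i)
    paste(c(dm$labels[i], sprintf(fmt, dm$values[i, ])), collapse = "\t"),
    character(1L))
  writeLines(c(paste(c("genome", dm$labels), collapse = "\t"), rows), path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line holds the number of taxa; each following line holds a
#' whitespace-delimited label and the full row of distances, readable by
#' standard distance-based tree tools.
#'
#' @inheritParams write_distmat_tsv
#' @export
write_distmat_phylip <- function(dm, path, digits = 6L) {
  stopifnot(inherits(dm, "js_distmat"))
  fmt <- paste0("%.", digits, "f")
  labs <- gsub("\\s+", "_", dm$labels)
  rows <- vapply(seq_along(labs), function(i)
    paste(c(sprintf("%-12s", labs[i]), sprintf(fmt, dm$values[i, ])),
          collapse = " "),
    character(1L))
  writeLines(c(sprintf("%5d", length(labs)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Path to a PHYLIP square-format distance matrix.
#' @return A `js_distmat` (with empty `meta`).
#' @export
read_distmat_phylip <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 2L)
    stop("'", path, "' is not a PHYLIP square distance matrix")
  if (length(lines) < n + 1L)
    stop("'", path, "' declares ", n, " taxa but has too few rows")
  labels <- character(n)
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) != n + 1L)
      stop("row ", i, " of '", path, "' has ", length(parts) - 1L,
           " values; expected ", n)
    labels[i] <- parts[1L]
    v[i, ] <- as.numeric(parts[-1L])
  }
  if (anyNA(v)) stop("non-numeric distances in '", path, "'")
  v <- (v + t(v)) / 2
  diag(v) <- 0
  dimnames(v) <- list(labels, labels)
  structure(list(labels = labels, values = v, meta = list()),
            class = "js_distmat")
}
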