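#' Hierarchical clustering of a genome distance matrix
#'
#' Agglomerative clustering (UPGMA by default, i.e. average linkage) or
#' neighbor-joining on a Jensen-Shannon distance matrix. UPGMA, complete
#' and single linkage produce rooted ultrametric dendrograms via
#' [stats::hclust()]; neighbor-joining produces an unrooted tree via
#' [ape::nj()]. Genomes are ordered lexicographically by label before
#' clustering so that ties are broken deterministically and the result is
#' independent of input order.
#'
#' @param dm A `js_distmat` (or a symmetric numeric matrix with
#'   dimnames).
#' @param method One of `"average"` (UPGMA, default), `"complete"`,
#'   `"single"`, `"nj"`.
#' @return An object of class `cluster_tree`: a list with `phylo` (an
#'   [ape] tree with branch lengths), `method`, `labels`, `rooted`, and
#'   for the hclust methods `merge_table` (one row per merge step).
#' @export
hierarchical_cluster <- function(dm, method = c("average", "complete",
                                                "single", "nj")) {
  method <- match.arg(method)
  if (is.matrix(dm)) {
    if (is.null(rownames(dm))) stop("matrix 'dm' needs genome labels as dimnames")
    dm <- structure(list(labels = rownames(dm), values = dm, meta = list()),
                    class = "js_distmat")
  }
  stopifnot(inherits(dm, "js_distmat"))
  v <- dm$values
  if (!isSymmetric(unname(v), tol = 1e-12))
    stop("distance matrix is not symmetric")
  if (any(v < 0)) stop("distance matrix has negative entries")
  if (nrow(v) < 2L) stop("need at least two genomes to cluster")
  ord <- order(dm$labels, method = "radix")
  v <- v[ord, ord, drop = FALSE]
  labels <- dm$labels[ord]
  if (method == "nj") {
    phy <- ape::nj(structure(v, dimnames = list(labels, labels)))
    phy$edge.length[phy$edge.length < 0] <- 0
    return(structure(list(phylo = phy, method = method, labels = labels,
                          rooted = FALSE, merge_table = NULL),
                     class = "cluster_tree"))
  }
  d <- stats::as.dist(v)
  attr(d, "Labels") <- labels
  hc <- stats::hclust(d, method = method)
  phy <- ape::as.phylo(hc)   # node depths = merge height / 2 -> ultrametric
  sizes <- .merge_sizes(hc$merge)
  mt <- data.frame(step = seq_len(nrow(hc$merge)),
                   cluster1 = .merge_member(hc, hc$merge[, 1L]),
                   cluster2 = .merge_member(hc, hc$merge[, 2L]),
                   height = hc$height,
                   size = sizes,
                   stringsAsFactors = FALSE)
  structure(list(phylo = phy, method = method, labels = labels,
                 rooted = TRUE, merge_table = mt),
            class = "cluster_tree")
}

.merge_sizes <- function(merge) {
  n <- nrow(merge)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    s <- 0L
    for (k in merge[i, ]) s <- s + if (k < 0) 1L else sizes[k]
    sizes[i] <- s
  }
  sizes
}

.merge_member <- function(hc, col) {
  vapply(col, function(k)
    if (k < 0) hc$labels[-k] else paste0("node", k), character(1L))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, method = %s (%s)\n",
              length(x$labels), x$method,
              if (x$rooted) "rooted dendrogram" else "unrooted"))
  invisible(x)
}

.needs_quoting <- function(label) grepl("[\\s()\\[\\]:;,']", label, perl = TRUE)

#' Serialize a cluster tree to Newick
#'
#' Branch lengths are included; labels containing Newick metacharacters
#' (parentheses, brackets, colons, semicolons, commas, whitespace) are
#' single-quoted. The output round-trips through [ape::read.tree()].
#'
#' @param tree A `cluster_tree`.
#' @param digits Significant digits for branch lengths, default 10.
#' @return A Newick string ending in `";"`.
#' @export
to_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- tree$phylo
  orig <- phy$tip.label
  safe <- paste0("t", seq_along(orig))
  phy$tip.label <- safe
  nwk <- ape::write.tree(phy, digits = digits)
  quoted <- ifelse(vapply(orig, .needs_quoting, logical(1L)),
                   paste0("'", gsub("'", "''", orig), "'"), orig)
  for (i in rev(seq_along(safe)))   # t10 before t1
    nwk <- sub(paste0("([(,])", safe[i], ":"),
               paste0("\\1", quoted[i], ":"), nwk)
  nwk
}

#' Write Newick and merge-step outputs
#'
#' @param tree A `cluster_tree`.
#' @param newick_path Output path for the Newick file.
#' @param merge_path Optional output path for a TSV of merge steps
#'   (`cluster1`, `cluster2`, `height`, `size`); only available for the
#'   hclust-based linkage methods.
#' @return `newick_path`, invisibly.
#' @export
write_tree <- function(tree, newick_path, merge_path = NULL) {
  writeLines(to_newick(tree), newick_path)
  if (!is.null(merge_path)) {
    if (is.null(tree$merge_table))
      stop("merge table is only defined for hclust-based methods, not '",
           tree$method, "'")
    mt <- tree$merge_table
    mt$height <- sprintf("%.6f", mt$height)
    utils::write.table(mt, merge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(newick_path)
}

#' Test whether label groups form clades of a tree
#'
#' Checks, for every group of a partition of the leaf labels, whether the
#' group is monophyletic. For rooted dendrograms this is clade membership
#' under the root; for unrooted (neighbor-joining) trees a group counts
#' as a clade when it forms one side of some bipartition, assessed by
#' rooting at a leaf outside the group. This is the test surface for
#' planted-cluster recovery: a planted grouping is "recovered" when every
#' group is a clade.
#'
#' @param tree A `cluster_tree`.
#' @param groups A named or unnamed list of character vectors that
#'   together partition the leaf labels.
#' @return `TRUE` iff every group is a clade.
#' @export
bipartition_check <- function(tree, groups) {
  stopifnot(inherits(tree, "cluster_tree"), is.list(groups))
  leaves <- tree$phylo$tip.label
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members) || !setequal(all_members, leaves))
    stop("'groups' must partition the tree's leaf labels exactly")
  for (g in groups) {
    if (length(g) == length(leaves)) next   # the whole tree is a clade
    phy <- tree$phylo
    if (!tree$rooted) {
      out <- setdiff(leaves, g)[1L]
      phy <- ape::root(phy, outgroup = out, resolve.root = TRUE)
    }
    if (!ape::is.monophyletic(phy, g)) return(FALSE)
  }
  TRUE
}
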