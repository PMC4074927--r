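mat_dm <- function(v, labels) {
  dimnames(v) <- list(labels, labels)
  v
}

test_that("UPGMA on two genomes gives a cherry with half-height branches", {
  v <- mat_dm(matrix(c(0, 0.6, 0.6, 0), 2), c("A", "B"))
  tree <- hierarchical_cluster(v)
  expect_identical(sort(tree$phylo$tip.label), c("A", "B"))
  expect_equal(unname(tree$phylo$edge.length), c(0.3, 0.3), tolerance = 1e-12)
  expect_match(to_newick(tree), "^\\(A:0.3,B:0.3\\);$")
})

test_that("UPGMA reproduces the hand-executed three-genome merge sequence", {
  v <- mat_dm(matrix(c(0, 0.1, 0.8,
                       0.1, 0, 0.8,
                       0.8, 0.8, 0), 3, byrow = TRUE), c("A", "B", "C"))
  tree <- hierarchical_cluster(v)
  mt <- tree$merge_table
  expect_identical(sort(c(mt$cluster1[1], mt$cluster2[1])), c("A", "B"))
  expect_equal(mt$height, c(0.1, 0.8), tolerance = 1e-12)
  expect_true(bipartition_check(tree, list(c("A", "B"), "C")))
  expect_false(bipartition_check(tree, list(c("A", "C"), "B")))
  # C joins at height 0.8 -> its leaf branch is 0.4 in the ultrametric tree
  c_edge <- tree$phylo$edge.length[
    tree$phylo$edge[, 2] == which(tree$phylo$tip.label == "C")]
  expect_equal(unname(c_edge), 0.4, tolerance = 1e-12)
})

test_that("all-zero matrices merge at height zero, deterministically", {
  v <- mat_dm(matrix(0, 3, 3), c("b", "c", "a"))
  tree <- hierarchical_cluster(v)
  expect_equal(tree$merge_table$height, c(0, 0), tolerance = 0)
  expect_identical(tree$labels, c("a", "b", "c"))  # lexicographic ordering
})

test_that("average-linkage trees are ultrametric with non-decreasing merge heights", {
  set.seed(103)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * n), n)
    v <- mat_dm((m + t(m)) / 2, paste0("g", seq_len(n)))
    diag(v) <- 0
    tree <- hierarchical_cluster(v)
    expect_true(all(diff(tree$merge_table$height) >= -1e-12))
    depths <- ape::node.depth.edgelength(tree$phylo)
    leaf_depths <- depths[seq_along(tree$phylo$tip.label)]
    expect_lt(max(leaf_depths) - min(leaf_depths), 1e-9)
    expect_true(all(tree$phylo$edge.length >= 0))
  }
})

test_that("clustering is invariant to input label order", {
  set.seed(107)
  n <- 6
  m <- matrix(runif(n * n, 0.2, 0.9), n)
  v <- (m + t(m)) / 2
  diag(v) <- 0
  labels <- paste0("tax", 1:n)
  perm <- sample(n)
  t1 <- hierarchical_cluster(mat_dm(v, labels))
  t2 <- hierarchical_cluster(mat_dm(v[perm, perm], labels[perm]))
  expect_identical(to_newick(t1), to_newick(t2))
})

test_that("exact two-block structure is recovered as clades by every method", {
  labels <- c("x1", "x2", "x3", "y1", "y2")
  v <- matrix(0.9, 5, 5)
  v[1:3, 1:3] <- 0.2
  v[4:5, 4:5] <- 0.2
  diag(v) <- 0
  groups <- list(c("x1", "x2", "x3"), c("y1", "y2"))
  for (method in c("average", "complete", "single", "nj")) {
    tree <- hierarchical_cluster(mat_dm(v, labels), method = method)
    expect_true(bipartition_check(tree, groups),
                label = paste("clade recovery under", method))
  }
})

test_that("Newick output round-trips and quotes awkward labels", {
  set.seed(109)
  n <- 5
  m <- matrix(runif(n * n, 0.1, 1), n)
  v <- (m + t(m)) / 2
  diag(v) <- 0
  tree <- hierarchical_cluster(mat_dm(v, paste0("leaf", 1:n)))
  back <- ape::read.tree(text = to_newick(tree))
  expect_identical(sort(back$tip.label), sort(tree$phylo$tip.label))
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tree$phylo)),
               0, ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(back)
  d2 <- ape::cophenetic.phylo(tree$phylo)
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-9)

  vq <- mat_dm(matrix(c(0, 0.6, 0.6, 0), 2), c("v 1", "v2"))
  expect_match(to_newick(hierarchical_cluster(vq)), "'v 1'", fixed = TRUE)
})

test_that("neighbor-joining trees are unrooted and support bipartition checks", {
  labels <- c("p1", "p2", "q1", "q2")
  v <- matrix(0.8, 4, 4)
  v[1:2, 1:2] <- 0.1
  v[3:4, 3:4] <- 0.1
  diag(v) <- 0
  tree <- hierarchical_cluster(mat_dm(v, labels), method = "nj")
  expect_false(tree$rooted)
  expect_false(ape::is.rooted(tree$phylo))
  expect_true(bipartition_check(tree, list(c("p1", "p2"), c("q1", "q2"))))
  expect_false(bipartition_check(tree, list(c("p1", "q1"), c("p2", "q2"))))
  expect_true(bipartition_check(tree, list(labels)))
})

test_that("bipartition_check validates that groups partition the leaves", {
  v <- mat_dm(matrix(c(0, 0.6, 0.6, 0), 2), c("A", "B"))
  tree <- hierarchical_cluster(v)
  expect_error(bipartition_check(tree, list("A")), "partition")
  expect_error(bipartition_check(tree, list(c("A", "B"), "B")), "partition")
})
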