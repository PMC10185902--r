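# Independent brute-force oracles. These deliberately avoid the package's
# own traversal code paths: everything is recomputed from the parent map.

oracle_root_path <- function(tree, node) {
  p <- node
  while (!is.na(tree$parent[[p[1]]])) p <- c(tree$parent[[p[1]]], p)
  p
}

oracle_lca <- function(tree, nodes) {
  common <- Reduce(intersect, lapply(nodes, function(n) oracle_root_path(tree, n)))
  common[length(common)]  # root paths list ancestors root-first
}

oracle_descendants <- function(tree, node) {
  tree$nodes[vapply(tree$nodes, function(x) node %in% oracle_root_path(tree, x),
                    logical(1))]
}

# exhaustive-node assignment oracle: the deepest node whose entire root path
# is eligible (>=1 derived call and strict-majority support per branch).
# Under missing/heterozygous-only noise, derived marker calls arise only on
# the sample's true lineage, so eligible nodes form a chain and the deepest
# one is unique; the oracle asserts that.
oracle_assign <- function(states, tree, min_support = 0.5) {
  eligible_branch <- function(node) {
    s <- states[tree$node_markers[[node]]]
    d <- sum(s == 1L, na.rm = TRUE); a <- sum(s == 0L, na.rm = TRUE)
    d >= 1 && d / (d + a) > min_support
  }
  valid <- vapply(tree$nodes, function(n) {
    path <- setdiff(oracle_root_path(tree, n), tree$root)
    all(vapply(path, eligible_branch, logical(1)))
  }, logical(1))
  cand <- tree$nodes[valid]
  deepest <- cand[tree$depth[cand] == max(tree$depth[cand])]
  stopifnot(length(deepest) == 1)
  deepest
}

# clade-exactness oracle: scan every node for an exact census match
oracle_exact_clade <- function(D, censuses) {
  hits <- names(censuses)[vapply(censuses, function(cs) setequal(cs, D), logical(1))]
  if (length(hits) == 0) NULL else hits
}
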