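test_that("minimal topology parses with markers attached to the root branch", {
  tr <- parse_haplogroup_tree("((O1a,O1b)O1,O2)O;",
                              data.frame(name = "M175", haplogroup = "O",
                                         position = 100, ancestral = "ATTCTC",
                                         derived = "A"))
  expect_s3_class(tr, "hg_tree")
  expect_length(tr$nodes, 5)
  expect_identical(tr$root, "O")
  expect_identical(tr$children[["O1"]], c("O1a", "O1b"))
  expect_identical(tr$node_markers[["O"]], "M175")
  expect_identical(tr$markers$variant_class, "indel")
})

test_that("packaged O-M175 fixture has the nomenclature-implied ancestry", {
  tr <- om175_tree()
  expect_gt(length(tr$nodes), 30)
  anc <- tree_ancestors(tr, "O1b1a1a1a1a1")
  expect_true(all(c("O1b1a1a1a1a", "O1b1a1a", "O1b1a1", "O1b1a", "O1b1", "O1b", "O1", "O")
                  %in% anc))
  expect_true(all(c("O1b1", "O1b1a", "O1b1a1a", "O1b2", "O1b2a1a")
                  %in% tree_descendants(tr, "O1b")))
  # every published clade resolves in the tree
  expect_true(all(table1_indels()$clade %in% tr$nodes))
})

test_that("descendants and lca behave on the toy tree", {
  tr <- toy_tree()
  expect_setequal(tree_descendants(tr, "O1"), c("O1", "O1a", "O1b"))
  expect_identical(tree_descendants(tr, "O2"), "O2")
  expect_identical(tree_lca(tr, c("O1a", "O1b")), "O1")
  expect_identical(tree_lca(tr, "O1a"), "O1a")
  expect_error(tree_lca(tr, character(0)), class = "yis_contract_error")
  expect_error(tree_descendants(tr, "O9"), class = "yis_lookup_error")
})

test_that("lca over all published clades is the focal root, matching brute force", {
  tr <- om175_tree()
  clades <- unique(table1_indels()$clade)
  expect_identical(tree_lca(tr, clades), "O")
  expect_identical(oracle_lca(tr, clades), "O")
})

test_that("validation rejects bad inputs", {
  expect_error(parse_haplogroup_tree("((O1a,O1b)O1,O2)O;",
                                     data.frame(name = "x", haplogroup = "O9",
                                                position = 1, ancestral = "A",
                                                derived = "C")),
               class = "yis_validate_error")
  expect_error(parse_haplogroup_tree("((A,B)C,D;"), class = "yis_parse_error")
  expect_error(parse_haplogroup_tree("((A,B)C,B)R;"), class = "yis_validate_error")
  # duplicate (position, ancestral, derived) triple
  expect_error(parse_haplogroup_tree("((O1a,O1b)O1,O2)O;",
                                     data.frame(name = c("a", "b"),
                                                haplogroup = c("O", "O1"),
                                                position = c(5, 5),
                                                ancestral = c("A", "A"),
                                                derived = c("G", "G"))),
               class = "yis_validate_error")
  expect_error(validate_marker_table(
    data.frame(name = "m", haplogroup = "O", position = 1,
               ancestral = ".", derived = "A")), class = "yis_validate_error")
})

test_that("lca equals brute force and descendants refine a partition on random trees", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- random_haplogroup_tree(n_focal_nodes = sample(10:60, 1))
    pairs <- replicate(30, sample(tr$nodes, 2), simplify = FALSE)
    for (p in pairs)
      expect_identical(tree_lca(tr, p), oracle_lca(tr, p))
    for (n in sample(tr$nodes, min(10, length(tr$nodes)))) {
      expect_setequal(tree_descendants(tr, n), oracle_descendants(tr, n))
      kids <- tr$children[[n]]
      kid_sets <- lapply(kids, tree_descendants, tree = tr)
      if (length(kid_sets) > 1)
        for (i in seq_along(kid_sets)[-1])
          expect_length(intersect(kid_sets[[i - 1]], kid_sets[[i]]), 0)
      expect_setequal(c(n, unlist(kid_sets)), tree_descendants(tr, n))
    }
  }
})

test_that("parse -> serialize -> parse round-trips", {
  for (tr in list(toy_tree(NULL), om175_tree())) {
    tr2 <- parse_haplogroup_tree(serialize_tree(tr), tr$markers[, 1:5])
    expect_identical(tr2$nodes[order(tr2$nodes)], tr$nodes[order(tr$nodes)])
    expect_identical(tr2$parent[sort(tr2$nodes)], tr$parent[sort(tr$nodes)])
    expect_identical(serialize_tree(tr2), serialize_tree(tr))
  }
})
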