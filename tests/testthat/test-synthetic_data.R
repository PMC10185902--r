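test_that("a fixed seed reproduces the VCF byte for byte", {
  cfg <- sim_config(n_clade_perfect = 5, n_incomplete = 0, n_leaky = 0,
                    n_homoplasic = 0, n_duplicate_known = 0,
                    n_outside_focal = 0, n_snp_decoys = 0, seed = 42)
  s1 <- quietly(simulate_cohort(cfg))
  s2 <- quietly(simulate_cohort(cfg))
  expect_identical(s1$vcf, s2$vcf)
  expect_identical(s1$truth, s2$truth)
})

test_that("truth table is a ledger: planted once, clade_perfect inside focal", {
  sim <- quietly(simulate_cohort(sim_config(seed = 5)))
  expect_false(any(duplicated(sim$truth$variant_key)))
  cp <- sim$truth[sim$truth$category == "clade_perfect", ]
  focal_nodes <- tree_descendants(sim$tree, sim$config$focal)
  expect_true(all(cp$intended_clade %in% focal_nodes))
  expect_true(all(cp$derived_is %in% c("REF", "ALT")))
})

test_that("noise-free screens recover exactly the clade-perfect set", {
  sim <- quietly(simulate_cohort(sim_config(seed = 19)))
  run <- quietly(screen_sim(sim))
  novel <- run$result$novel
  cp <- sim$truth[sim$truth$category == "clade_perfect", ]
  expect_setequal(novel$variant_key, cp$variant_key)
  got <- stats::setNames(novel$assigned_clade, novel$variant_key)
  expect_identical(unname(got[cp$variant_key]), cp$intended_clade)
  # orientation recovered too
  ori <- stats::setNames(novel$orientation, novel$variant_key)
  expect_identical(unname(ori[cp$variant_key]), cp$derived_is)
  # no category leakage
  bad <- sim$truth$variant_key[sim$truth$category %in%
    c("incomplete", "leaky", "homoplasic", "snp_decoy", "outside_focal")]
  expect_length(intersect(novel$variant_key, bad), 0)
  # known duplicates annotated, never novel
  dup <- sim$truth$variant_key[sim$truth$category == "duplicate_known"]
  cand <- run$result$candidates
  expect_true(all(grepl("^duplicate_of:",
                        cand$status[cand$variant_key %in% dup])))
  expect_length(intersect(novel$variant_key, dup), 0)
})

test_that("missing-call noise never misassigns a clade-perfect variant", {
  for (seed in 101:120) {
    sim <- quietly(simulate_cohort(sim_config(seed = seed, missing_rate = 0.05,
                                              n_focal_nodes = 15)))
    run <- quietly(screen_sim(sim))
    cp <- sim$truth[sim$truth$category == "clade_perfect", ]
    novel <- run$result$novel
    rej <- run$result$rejections
    for (i in seq_len(nrow(cp))) {
      key <- cp$variant_key[i]
      if (key %in% novel$variant_key) {
        expect_identical(novel$assigned_clade[novel$variant_key == key],
                         cp$intended_clade[i])
      } else {
        expect_true(rej$reason[rej$variant_key == key] %in%
                      c("low-call", "unverifiable"))
      }
    }
  }
})

test_that("heterozygous-call noise behaves like missingness", {
  sim <- quietly(simulate_cohort(sim_config(seed = 55, het_rate = 0.1)))
  gm <- quietly(build_genotype_matrix(sim$vt))
  vcf_has_het <- any(grepl("\t0/1", sim$vcf))
  expect_true(vcf_has_het)
  # every het cell became NA in the matrix
  het_cells <- sim$vt$gt[match(gm$variants$key,
                               paste("chrY", sim$vt$records$pos, sim$vt$records$ref,
                                     vapply(sim$vt$records$alts, `[`, "", 1),
                                     sep = ":")), ] == "0/1"
  expect_true(all(is.na(gm$calls[het_cells])))
})

test_that("infeasible categories raise configuration errors", {
  # a tree with no outgroup at all: leaky/outside_focal cannot be planted
  tr <- parse_haplogroup_tree("((O1a,O1b)O1,O2)O;")
  expect_error(quietly(simulate_cohort(sim_config(tree = tr, focal = "O",
                                                  n_outside_focal = 1))),
               class = "yis_config_error")
})

test_that("the replay fixture plants published events at published coordinates", {
  sim <- quietly(table1_replay_fixture(seed = 1))
  rec <- sim$vt$records
  # rs79011057: C deletion at 15,870,505 (anchored representation)
  i <- which(rec$pos == 15870505)
  expect_identical(rec$id[i], "rs79011057")
  expect_identical(nchar(rec$ref[i]) - nchar(rec$alts[[i]][1]), 1L)
  # rs774008684: 4-base deletion at 17,452,553
  j <- which(rec$pos == 17452553)
  expect_identical(rec$id[j], "rs774008684")
  expect_identical(nchar(rec$ref[j]) - nchar(rec$alts[[j]][1]), 4L)
  # screen assigns rs759556853 to O2a1b1a1a1a1
  run <- quietly(screen_sim(sim))
  nv <- run$result$novel
  expect_identical(nv$assigned_clade[nv$rsid == "rs759556853"], "O2a1b1a1a1a1")
})

test_that("packaged extdata files mirror the in-code fixtures", {
  nwk <- system.file("extdata", "o_m175_tree.synthetic.nwk",
                     package = "yindelscreen")
  mtsv <- system.file("extdata", "o_m175_markers.synthetic.tsv",
                      package = "yindelscreen")
  tr_file <- parse_haplogroup_tree(nwk, mtsv)
  tr_code <- om175_tree()
  expect_identical(serialize_tree(tr_file), serialize_tree(tr_code))
  expect_identical(tr_file$markers, tr_code$markers)
  known <- read_marker_table(system.file("extdata",
                                         "o_m175_known_indels.synthetic.tsv",
                                         package = "yindelscreen"))
  expect_identical(known, om175_known_indels())
  t1 <- utils::read.delim(system.file("extdata", "table1_indels.tsv",
                                      package = "yindelscreen"))
  expect_identical(t1, table1_indels())
})
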