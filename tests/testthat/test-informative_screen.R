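# Three indel variants over the toy cohort: clade-exact for O1 (derived in
# s3,s4,s5), leaky into the outgroup, and an outgroup-private variant.
toy_screen_gm <- function() {
  calls <- rbind(c(0L, 0L, 1L, 1L, 1L, 0L),
                 c(1L, 0L, 1L, 1L, 1L, 0L),
                 c(1L, 0L, 0L, 0L, 0L, 0L))
  colnames(calls) <- paste0("s", 1:6)
  make_gm(calls, pos = c(7000L, 8000L, 9000L),
          ref = c("AC", "AG", "ATT"), alt = c("A", "A", "A"))
}

test_that("clade_samples matches construction", {
  tr <- toy_tree()
  calls <- toy_calls()
  expect_setequal(clade_samples(tr, calls, "O1"), c("s3", "s4", "s5"))
  expect_setequal(clade_samples(tr, calls, "Y"), paste0("s", 1:6))
  expect_error(clade_samples(tr, calls, "O9"), class = "yis_lookup_error")
})

test_that("clade_samples equals the simulator census on seeded runs", {
  sim <- quietly(simulate_cohort(sim_config(seed = 13)))
  calls <- data.frame(sample = sim$calls_truth$sample,
                      haplogroup = sim$calls_truth$true_node)
  for (n in sample(sim$tree$nodes, 10)) {
    truth_census <- sim$calls_truth$sample[
      sim$calls_truth$true_node %in% oracle_descendants(sim$tree, n)]
    expect_setequal(clade_samples(sim$tree, calls, n), truth_census)
  }
})

test_that("clade_frequencies counts by direct counting and omits uncalled clades", {
  tr <- toy_tree(); calls <- toy_calls(); gm <- toy_screen_gm()
  fr <- clade_frequencies(gm, calls, tr)
  row <- function(key, clade) fr[fr$variant_key == key & fr$clade == clade, ]
  k1 <- gm$variants$key[1]
  expect_identical(row(k1, "O1")$derived_count, 3L)
  expect_identical(row(k1, "O1")$frequency, 1.0)
  expect_identical(row(k1, "O2")$derived_count, 0L)
  expect_identical(row(k1, "O2")$called_count, 1L)
  # missing call inside the clade decrements called_count
  gm$calls[1, "s4"] <- NA_integer_
  fr2 <- clade_frequencies(gm, calls, tr)
  expect_identical(fr2[fr2$variant_key == k1 & fr2$clade == "O1", ]$called_count, 2L)
  expect_identical(fr2[fr2$variant_key == k1 & fr2$clade == "O1", ]$frequency, 1.0)
})

test_that("derived counts are conserved across the root's children", {
  sim <- quietly(simulate_cohort(sim_config(seed = 17)))
  calls <- data.frame(sample = sim$calls_truth$sample,
                      haplogroup = sim$calls_truth$true_node)
  gm <- quietly(build_genotype_matrix(sim$vt))
  fr <- clade_frequencies(gm, calls, sim$tree)
  root <- sim$tree$root
  kids <- sim$tree$children[[root]]
  direct <- calls$sample[calls$haplogroup == root]
  for (k in sample(gm$variants$key, 10)) {
    sub <- fr[fr$variant_key == k, ]
    at_root <- sub$derived_count[sub$clade == root]
    from_kids <- sum(sub$derived_count[sub$clade %in% kids])
    from_direct <- sum(gm$calls[k, direct] == 1L, na.rm = TRUE)
    expect_identical(at_root, from_kids + as.integer(from_direct))
  }
})

test_that("focal restriction recognises ALT-, REF- and non-confined alleles", {
  tr <- toy_tree(); calls <- toy_calls(); gm <- toy_screen_gm()
  focal <- clade_samples(tr, calls, "O")
  expect_identical(focal_restricted(gm$calls[1, ], focal)$orientation, "ALT")
  expect_identical(focal_restricted(gm$calls[2, ], focal)$orientation, "NONE")
  expect_identical(focal_restricted(gm$calls[3, ], focal)$orientation, "NONE")
  # REF orientation: allele swap of case 1
  expect_identical(focal_restricted(1L - gm$calls[1, ], focal)$orientation, "REF")
  # callability gate
  v <- gm$calls[1, ]; v[1:3] <- NA_integer_
  fr <- focal_restricted(v, focal, min_call_fraction = 0.9)
  expect_identical(fr$orientation, "NONE")
  expect_identical(fr$reason, "low-call")
})

test_that("assign_clade applies both criteria with LCA assignment", {
  tr <- toy_tree(); calls <- toy_calls()
  mk_v <- function(D) {
    v <- stats::setNames(rep(0L, 6), paste0("s", 1:6)); v[D] <- 1L; v
  }
  ok <- assign_clade(mk_v(c("s3", "s4", "s5")), "ALT", calls, tr)
  expect_true(ok$accepted)
  expect_identical(ok$clade, "O1")
  expect_identical(ok$carriers, 3L)
  expect_identical(ok$clade_called, 3L)
  expect_identical(ok$outside_derived, 0L)
  r1 <- assign_clade(mk_v(c("s3", "s5")), "ALT", calls, tr)
  expect_false(r1$accepted); expect_identical(r1$reason, "criterion1")
  r2 <- assign_clade(mk_v(c("s3", "s4", "s6")), "ALT", calls, tr)
  expect_false(r2$accepted)
  expect_identical(r2$clade, "O"); expect_identical(r2$reason, "criterion1")
  expect_error(assign_clade(mk_v(character(0)), "ALT", calls, tr),
               class = "yis_contract_error")
  # strict_missing rejects unverifiable clades
  v <- mk_v(c("s3", "s5")); v["s4"] <- NA_integer_
  lax <- assign_clade(v, "ALT", calls, tr)
  expect_true(lax$accepted)  # s4 uncalled; remaining O1 members all derived
  strict <- assign_clade(v, "ALT", calls, tr,
                         config = screen_config(strict_missing = TRUE))
  expect_false(strict$accepted); expect_identical(strict$reason, "unverifiable")
})

test_that("every carrier subset of the toy cohort matches the brute-force oracle", {
  tr <- toy_tree(); calls <- toy_calls()
  censuses <- yindelscreen:::census_map(tr, calls)
  samples <- paste0("s", 1:6)
  for (bits in 1:63) {
    D <- samples[as.logical(bitwAnd(bits, 2^(0:5)))]
    v <- stats::setNames(as.integer(samples %in% D), samples)
    got <- assign_clade(v, "ALT", calls, tr, censuses = censuses)
    want <- oracle_exact_clade(D, censuses)
    expect_identical(got$accepted, !is.null(want))
    if (!is.null(want)) expect_identical(got$clade, want)
  }
})

test_that("dedup_known annotates exact copies and warns on position-only hits", {
  known <- om175_known_indels()
  cand <- data.frame(variant_key = c("a", "b", "c"),
                     position = c(known$position[1], 123L, known$position[2]),
                     ref = c(known$ancestral[1], "A", "TT"),
                     alt = c(known$derived[1], "AT", "T"),
                     stringsAsFactors = FALSE)
  expect_warning(out <- dedup_known(cand, known), "shares a position")
  expect_identical(out$status,
                   c(paste0("duplicate_of:", known$name[1]), "novel", "novel"))
})

test_that("screen composes the stages with the documented counters", {
  tr <- toy_tree(); calls <- toy_calls(); gm <- toy_screen_gm()
  res <- quietly(screen_indels(gm, calls, tr, screen_config(focal_clade = "O")))
  expect_identical(unname(res$counters),
                   c(3L, 3L, 3L, 1L, 1L, 1L))
  expect_identical(res$novel$assigned_clade, "O1")
  expect_identical(res$novel$mutation, "C > -")
  expect_error(screen_indels(gm, calls, tr, screen_config(focal_clade = "Zzz")),
               class = "yis_config_error")
})

test_that("screen output is invariant under REF/ALT relabeling", {
  sim <- quietly(simulate_cohort(sim_config(seed = 41)))
  run <- quietly(screen_sim(sim))
  gm <- run$matrix
  flipped <- flip_gm(gm)
  res2 <- quietly(screen_indels(flipped, run$calls, sim$tree,
                                screen_config(focal_clade = "O"), sim$known))
  res1 <- run$result
  expect_identical(nrow(res1$novel), nrow(res2$novel))
  by_pos <- function(r) r$novel[order(r$novel$position),
                                c("position", "assigned_clade", "carriers", "status")]
  expect_identical(by_pos(res1), by_pos(res2))
  # orientations flip
  o1 <- res1$novel$orientation[order(res1$novel$position)]
  o2 <- res2$novel$orientation[order(res2$novel$position)]
  expect_identical(o1 == "ALT", o2 == "REF")
})

test_that("spoiler and subset monotonicity hold", {
  sim <- quietly(simulate_cohort(sim_config(seed = 43)))
  run <- quietly(screen_sim(sim))
  gm <- run$matrix; calls <- run$calls; tr <- sim$tree
  novel <- run$result$novel
  expect_gt(nrow(novel), 0)
  pick <- novel[1, ]
  at <- match(pick$variant_key, gm$variants$key)
  derived_code <- if (pick$orientation == "ALT") 1L else 0L
  outside <- setdiff(colnames(gm$calls),
                     clade_samples(tr, calls, pick$assigned_clade))
  # spoiler: one derived carrier outside the clade removes the candidate
  gm_sp <- gm
  gm_sp$calls[at, outside[1]] <- derived_code
  res_sp <- quietly(screen_indels(gm_sp, calls, tr, screen_config(), sim$known))
  expect_false(pick$variant_key %in% res_sp$novel$variant_key)
  # subset: dropping a non-carrier sample keeps the candidate
  drop <- outside[2]
  gm_sub <- gm
  gm_sub$calls <- gm_sub$calls[, setdiff(colnames(gm_sub$calls), drop)]
  gm_sub$samples <- setdiff(gm_sub$samples, drop)
  calls_sub <- calls[calls$sample != drop, ]
  res_sub <- quietly(screen_indels(gm_sub, calls_sub, tr, screen_config(), sim$known))
  expect_true(pick$variant_key %in% res_sub$novel$variant_key)
})

test_that("accepted candidates re-verify clade-exactness from scratch", {
  sim <- quietly(simulate_cohort(sim_config(seed = 47)))
  run <- quietly(screen_sim(sim))
  gm <- run$matrix
  for (i in seq_len(nrow(run$result$candidates))) {
    cand <- run$result$candidates[i, ]
    v <- gm$calls[match(cand$variant_key, gm$variants$key), ]
    code <- if (cand$orientation == "ALT") 1L else 0L
    D <- names(v)[!is.na(v) & v == code]
    members <- clade_samples(sim$tree, run$calls, cand$assigned_clade)
    called_members <- members[!is.na(v[members])]
    expect_setequal(D, called_members)
    expect_length(setdiff(D, members), 0)
  }
})
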