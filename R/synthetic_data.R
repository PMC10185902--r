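# Seeded cohort simulator with a planted-variant truth table.
#
# The generator emits the combinatorial structure the screen assumes — a
# rooted haplogroup tree, samples assigned to nodes, one defining SNP per
# branch so the caller can resolve every truth assignment, and InDels planted
# in controlled categories — not population-genetic realism. Truth tables
# record pre-noise states so recovery can be scored exactly.

# chrY coordinate blocks keep the synthetic position spaces disjoint:
#   2,000,000-2,999,999  packaged O-M175 marker index
#   3,000,000-3,999,999  planted/decoy variants
#   4,000,000-4,999,999  simulated tree markers
SIM_PLANT_BLOCK <- 3000000:3999999
SIM_MARKER_BLOCK <- 4000000:4999999

#' Simulation configuration
#'
#' @param tree optional \code{hg_tree}; when \code{NULL} a random tree is
#'   grown (\code{\link{random_haplogroup_tree}}).
#' @param n_focal_nodes size of the focal subtree for generated trees.
#' @param samples_per_node samples assigned directly to every focal-subtree
#'   node (constant, or a named vector of per-node overrides).
#' @param outgroup_fraction fraction of the cohort held by non-focal
#'   haplogroups (default 0.2, split over two outgroup clades so that a
#'   variant fixed outside the focal clade is never the complement of it).
#' @param n_clade_perfect,n_incomplete,n_leaky,n_homoplasic,n_duplicate_known,n_outside_focal,n_snp_decoys
#'   planted-variant counts per category.
#' @param ref_orientation_fraction fraction of clade-perfect variants planted
#'   with the derived allele as REF (reference chromosome inside the clade).
#' @param missing_rate,het_rate per-cell no-call and heterozygous-call noise
#'   applied to planted InDel genotypes after construction (branch-defining
#'   SNPs stay clean; truth reflects pre-noise states).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @param focal focal clade name (default \code{"O"}).
#' @return a validated \code{sim_config}.
#' @export
sim_config <- function(tree = NULL, n_focal_nodes = 30, samples_per_node = 3,
                       outgroup_fraction = 0.2,
                       n_clade_perfect = 5, n_incomplete = 3, n_leaky = 3,
                       n_homoplasic = 2, n_duplicate_known = 2,
                       n_outside_focal = 2, n_snp_decoys = 5,
                       ref_orientation_fraction = 0.25,
                       missing_rate = 0, het_rate = 0, seed = 1, focal = "O") {
  counts <- c(n_clade_perfect = n_clade_perfect, n_incomplete = n_incomplete,
              n_leaky = n_leaky, n_homoplasic = n_homoplasic,
              n_duplicate_known = n_duplicate_known,
              n_outside_focal = n_outside_focal, n_snp_decoys = n_snp_decoys)
  if (any(counts < 0)) yis_config_error("planted-variant counts must be >= 0")
  for (r in c(missing_rate, het_rate, outgroup_fraction, ref_orientation_fraction))
    if (r < 0 || r > 1) yis_config_error("rates must lie in [0, 1]")
  structure(list(tree = tree, n_focal_nodes = n_focal_nodes,
                 samples_per_node = samples_per_node,
                 outgroup_fraction = outgroup_fraction,
                 counts = as.list(counts),
                 ref_orientation_fraction = ref_orientation_fraction,
                 missing_rate = missing_rate, het_rate = het_rate,
                 seed = as.integer(seed), focal = focal),
            class = "sim_config")
}

#' Grow a random haplogroup-style tree
#'
#' The focal subtree is grown by repeatedly attaching a child to a random
#' existing node, with haplogroup-style names (digit and letter generations
#' alternate: O -> O1 -> O1a -> O1a1 ...). Two outgroup clades hang off the
#' root beside the focal clade. Draws from the current RNG stream.
#'
#' @param n_focal_nodes node count of the focal subtree (including its root).
#' @param focal,outgroup,root node names.
#' @return an \code{hg_tree} without markers.
#' @export
random_haplogroup_tree <- function(n_focal_nodes = 30, focal = "O",
                                   outgroup = c("P", "Q"), root = "Y") {
  children <- list()
  children[[root]] <- sort(c(focal, outgroup), method = "radix")
  nodes <- c(root, focal, outgroup)
  n_kids <- stats::setNames(integer(length(nodes)), nodes)
  focal_nodes <- focal
  while (length(focal_nodes) < n_focal_nodes) {
    p <- if (length(focal_nodes) == 1) focal_nodes else sample(focal_nodes, 1)
    k <- n_kids[[p]] + 1L
    last <- substr(p, nchar(p), nchar(p))
    suffix <- if (grepl("[0-9]", last)) {
      if (k > 26L) next else letters[k]
    } else {
      if (k > 9L) next else as.character(k)
    }
    child <- paste0(p, suffix)
    n_kids[[p]] <- k
    n_kids[[child]] <- 0L
    children[[p]] <- sort(c(children[[p]], child), method = "radix")
    children[[child]] <- character(0)
    nodes <- c(nodes, child)
    focal_nodes <- c(focal_nodes, child)
  }
  emit <- function(nd) {
    kids <- children[[nd]]
    if (is.null(kids) || length(kids) == 0) return(nd)
    paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", nd)
  }
  parse_haplogroup_tree(paste0(emit(root), ";"))
}

# anchored indel allele pair; anchor never equals the event's first base
rand_indel_event <- function() {
  n <- sample(1:5, 1)
  bases <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  anchor <- if (substr(bases, 1, 1) == "A") "C" else "A"
  if (stats::runif(1) < 0.5)
    c(anc = paste0(anchor, bases), der = anchor)    # deletion
  else
    c(anc = anchor, der = paste0(anchor, bases))    # insertion
}

rand_snp_alleles <- function() {
  a <- sample(c("A", "C", "G", "T"), 2)
  c(anc = a[1], der = a[2])
}

# neither the carrier set nor its complement may coincide with a clade census
carriers_cladelike <- function(D, censuses, all_samples) {
  comp <- setdiff(all_samples, D)
  any(vapply(censuses, function(cs) setequal(cs, D), logical(1))) ||
    (length(comp) > 0 &&
       any(vapply(censuses, function(cs) setequal(cs, comp), logical(1))))
}

#' Simulate a cohort with planted variants
#'
#' Emits standard VCF (haploid GT over one contig) plus a truth table per
#' planted variant and the true node of every sample. Category construction:
#' \describe{
#'   \item{clade_perfect}{derived in exactly the samples of one focal-subtree
#'     clade (REF- or ALT-oriented).}
#'   \item{incomplete}{derived in a strict non-empty subset of one clade that
#'     is itself no clade (violates criterion 1).}
#'   \item{leaky}{derived in a clade plus >= 1 sample outside it (violates
#'     criterion 2 / the focal restriction).}
#'   \item{homoplasic}{derived in two disjoint clades whose LCA clade is
#'     larger than their union.}
#'   \item{duplicate_known}{an exact position/allele copy of a known
#'     tree-defining InDel marker, clade-perfect for its node.}
#'   \item{outside_focal}{clade-perfect for an outgroup clade.}
#'   \item{snp_decoys}{single-base substitutions (excluded upstream by
#'     variant class).}
#' }
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{sim_cohort}: \code{vcf} (text lines), \code{vt}
#'   (\code{vcf_table}), \code{truth}, \code{calls_truth}, \code{tree}
#'   (markers attached), \code{known}, \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  focal <- config$focal

  tree0 <- if (is.null(config$tree))
    random_haplogroup_tree(config$n_focal_nodes, focal = focal) else config$tree
  check_node(tree0, focal)
  focal_nodes <- tree_descendants(tree0, focal)
  outgroup_nodes <- setdiff(tree0$nodes,
                            c(tree_ancestors(tree0, focal), focal_nodes))

  # ---- sample assignment (deterministic node order) -------------------------
  spn <- function(node) {
    s <- config$samples_per_node
    if (!is.null(names(s)) && node %in% names(s)) as.integer(s[[node]])
    else as.integer(s[[1]])
  }
  assign_nodes <- sort(focal_nodes, method = "radix")
  n_focal_samples <- sum(vapply(assign_nodes, spn, integer(1)))
  n_out_total <- max(2L, round(config$outgroup_fraction * n_focal_samples /
                                 max(1e-9, 1 - config$outgroup_fraction)))
  og_assign <- sort(outgroup_nodes, method = "radix")
  if (length(og_assign) == 0 && (config$counts$n_outside_focal > 0 ||
                                 config$counts$n_leaky > 0))
    yis_config_error("tree has no outgroup nodes; leaky/outside_focal categories infeasible")
  truth_nodes <- c(rep(assign_nodes, vapply(assign_nodes, spn, integer(1))),
                   if (length(og_assign) > 0)
                     rep(og_assign, diff(round(seq(0, n_out_total,
                                                   length.out = length(og_assign) + 1)))))
  samples <- sprintf("S%04d", seq_along(truth_nodes))
  calls_truth <- data.frame(sample = samples, true_node = truth_nodes,
                            stringsAsFactors = FALSE)

  # ---- markers: one clean SNP per branch + known InDels for dedup -----------
  marker_nodes <- setdiff(tree0$nodes, tree0$root)
  n_known <- config$counts$n_duplicate_known
  mpos <- sample(SIM_MARKER_BLOCK, length(marker_nodes) + n_known)
  snp_al <- t(vapply(seq_along(marker_nodes), function(i) rand_snp_alleles(),
                     character(2)))
  markers <- data.frame(name = paste0("SYN_", marker_nodes),
                        haplogroup = marker_nodes,
                        position = mpos[seq_along(marker_nodes)],
                        ancestral = snp_al[, 1], derived = snp_al[, 2],
                        stringsAsFactors = FALSE)
  known <- NULL
  if (n_known > 0) {
    kn_nodes <- sample(focal_nodes, n_known, replace = TRUE)
    kn_al <- t(vapply(seq_len(n_known), function(i) rand_indel_event(), character(2)))
    known <- data.frame(name = sprintf("KNOWN%02d", seq_len(n_known)),
                        haplogroup = kn_nodes,
                        position = mpos[length(marker_nodes) + seq_len(n_known)],
                        ancestral = kn_al[, 1], derived = kn_al[, 2],
                        stringsAsFactors = FALSE)
    markers <- rbind(markers, known)
  }
  tree <- parse_haplogroup_tree(serialize_tree(tree0), markers)
  known <- tree$markers[tree$markers$name %in% known$name, , drop = FALSE]

  calls_like <- data.frame(sample = samples, haplogroup = truth_nodes,
                           stringsAsFactors = FALSE)
  censuses <- census_map(tree, calls_like)
  outgroup_samples <- calls_truth$sample[calls_truth$true_node %in% outgroup_nodes]

  # ---- records --------------------------------------------------------------
  rec <- sim_recorder(samples)
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    cat_i <- if (m$name %in% known$name) "duplicate_known" else "marker_backbone"
    rec$add(m$position, m$name, m$ancestral, m$derived,
            alt_carriers = censuses[[m$haplogroup]],
            category = cat_i, intended_clade = m$haplogroup, derived_is = "ALT")
  }

  pool_n <- with(config$counts, n_clade_perfect + n_incomplete + n_leaky +
                   n_homoplasic + n_outside_focal + n_snp_decoys)
  pool <- if (pool_n > 0) sample(SIM_PLANT_BLOCK, pool_n) else integer(0)
  pi <- 0L
  next_pos <- function() { pi <<- pi + 1L; pool[pi] }

  plant_clade_perfect(rec, config$counts$n_clade_perfect, focal_nodes, censuses,
                      samples, next_pos, config$ref_orientation_fraction)
  plant_incomplete(rec, config$counts$n_incomplete, focal_nodes, censuses,
                   samples, next_pos)
  plant_leaky(rec, config$counts$n_leaky, focal_nodes, censuses, samples, next_pos)
  plant_homoplasic(rec, config$counts$n_homoplasic, focal_nodes, censuses,
                   samples, tree, next_pos)
  plant_outside_focal(rec, config$counts$n_outside_focal, outgroup_nodes,
                      censuses, outgroup_samples, next_pos)
  plant_snp_decoys(rec, config$counts$n_snp_decoys, samples, next_pos)

  finish_sim(rec, tree, known, calls_truth, config)
}

# mutable record collector shared by simulate_cohort and the replay fixture
sim_recorder <- function(samples) {
  e <- new.env(parent = emptyenv())
  e$samples <- samples
  e$rows <- list()
  e$add <- function(pos, id, ref, alt, alt_carriers, category,
                    intended_clade = NA_character_, derived_is = "ALT") {
    gt <- rep("0", length(e$samples))
    gt[match(alt_carriers, e$samples)] <- "1"
    e$rows[[length(e$rows) + 1L]] <- list(
      pos = as.integer(pos), id = as.character(id), ref = ref, alt = alt,
      gt = gt, category = category, intended_clade = intended_clade,
      derived_is = derived_is)
  }
  e
}

plant_clade_perfect <- function(rec, n, focal_nodes, censuses, samples,
                                next_pos, ref_fraction) {
  for (i in seq_len(n)) {
    C <- if (length(focal_nodes) == 1) focal_nodes else sample(focal_nodes, 1)
    al <- rand_indel_event()
    if (stats::runif(1) < ref_fraction) {
      # reference chromosome carries the derived state: clade members are REF
      rec$add(next_pos(), sprintf("CP%03d", i), ref = al[["der"]], alt = al[["anc"]],
              alt_carriers = setdiff(samples, censuses[[C]]),
              category = "clade_perfect", intended_clade = C, derived_is = "REF")
    } else {
      rec$add(next_pos(), sprintf("CP%03d", i), ref = al[["anc"]], alt = al[["der"]],
              alt_carriers = censuses[[C]],
              category = "clade_perfect", intended_clade = C, derived_is = "ALT")
    }
  }
}

plant_incomplete <- function(rec, n, focal_nodes, censuses, samples, next_pos) {
  big <- focal_nodes[vapply(focal_nodes, function(x) length(censuses[[x]]) >= 2, logical(1))]
  if (n > 0 && length(big) == 0)
    yis_config_error("incomplete category infeasible: no clade with >= 2 samples")
  for (i in seq_len(n)) {
    D <- NULL
    for (try in 1:200) {
      C <- if (length(big) == 1) big else sample(big, 1)
      cs <- censuses[[C]]
      Dtry <- sample(cs, sample(seq_len(length(cs) - 1L), 1))
      if (!carriers_cladelike(Dtry, censuses, samples)) { D <- Dtry; break }
    }
    if (is.null(D)) yis_config_error("incomplete category infeasible on this tree")
    al <- rand_indel_event()
    rec$add(next_pos(), sprintf("IC%03d", i), al[["anc"]], al[["der"]], D,
            category = "incomplete", intended_clade = C)
  }
}

plant_leaky <- function(rec, n, focal_nodes, censuses, samples, next_pos) {
  for (i in seq_len(n)) {
    D <- NULL
    for (try in 1:200) {
      C <- if (length(focal_nodes) == 1) focal_nodes else sample(focal_nodes, 1)
      outside <- setdiff(samples, censuses[[C]])
      if (length(outside) == 0) next
      k <- sample(seq_len(min(3L, length(outside))), 1)
      Dtry <- union(censuses[[C]], sample(outside, k))
      if (!carriers_cladelike(Dtry, censuses, samples)) { D <- Dtry; break }
    }
    if (is.null(D)) yis_config_error("leaky category infeasible on this tree")
    al <- rand_indel_event()
    rec$add(next_pos(), sprintf("LK%03d", i), al[["anc"]], al[["der"]], D,
            category = "leaky", intended_clade = C)
  }
}

plant_homoplasic <- function(rec, n, focal_nodes, censuses, samples, tree, next_pos) {
  for (i in seq_len(n)) {
    D <- NULL
    for (try in 1:200) {
      pick <- sample(focal_nodes, 2)
      c1 <- censuses[[pick[1]]]; c2 <- censuses[[pick[2]]]
      if (length(intersect(c1, c2)) > 0) next
      l <- tree_lca(tree, pick)
      Dtry <- union(c1, c2)
      if (length(censuses[[l]]) <= length(Dtry)) next
      if (!carriers_cladelike(Dtry, censuses, samples)) { D <- Dtry; break }
    }
    if (is.null(D))
      yis_config_error("homoplasic category infeasible: no disjoint clade pair found")
    al <- rand_indel_event()
    rec$add(next_pos(), sprintf("HP%03d", i), al[["anc"]], al[["der"]], D,
            category = "homoplasic")
  }
}

plant_outside_focal <- function(rec, n, outgroup_nodes, censuses,
                                outgroup_samples, next_pos) {
  og <- outgroup_nodes[vapply(outgroup_nodes,
                              function(x) length(censuses[[x]]) > 0, logical(1))]
  for (i in seq_len(n)) {
    ok <- og[vapply(og, function(x)
      length(setdiff(outgroup_samples, censuses[[x]])) > 0, logical(1))]
    if (length(ok) == 0)
      yis_config_error("outside_focal infeasible: a single outgroup clade would mirror the focal clade")
    C <- if (length(ok) == 1) ok else sample(ok, 1)
    al <- rand_indel_event()
    rec$add(next_pos(), sprintf("OF%03d", i), al[["anc"]], al[["der"]],
            censuses[[C]], category = "outside_focal", intended_clade = C)
  }
}

plant_snp_decoys <- function(rec, n, samples, next_pos) {
  for (i in seq_len(n)) {
    al <- rand_snp_alleles()
    D <- sample(samples, sample(seq_len(max(1L, length(samples) - 1L)), 1))
    rec$add(next_pos(), sprintf("SD%03d", i), al[["anc"]], al[["der"]], D,
            category = "snp_decoy")
  }
}

# noise, truth assembly, VCF text; shared by simulator and replay fixture
finish_sim <- function(rec, tree, known, calls_truth, config) {
  rows <- rec$rows
  samples <- rec$samples
  noisy <- c("clade_perfect", "incomplete", "leaky", "homoplasic",
             "duplicate_known", "outside_focal", "snp_decoy")
  for (j in seq_along(rows)) {
    if (!rows[[j]]$category %in% noisy) next
    gt <- rows[[j]]$gt
    if (config$het_rate > 0) {
      hit <- stats::runif(length(gt)) < config$het_rate
      gt[hit] <- "0/1"
    }
    if (config$missing_rate > 0) {
      hit <- stats::runif(length(gt)) < config$missing_rate
      gt[hit] <- "."
    }
    rows[[j]]$gt <- gt
  }
  ord <- order(vapply(rows, function(r) r$pos, integer(1)))
  rows <- rows[ord]
  key <- vapply(rows, function(r) paste("chrY", r$pos, r$ref, r$alt, sep = ":"),
                character(1))
  truth <- data.frame(
    variant_key = key,
    category = vapply(rows, function(r) r$category, character(1)),
    intended_clade = vapply(rows, function(r) r$intended_clade, character(1)),
    derived_is = vapply(rows, function(r) r$derived_is, character(1)),
    stringsAsFactors = FALSE)
  gt <- do.call(rbind, lapply(rows, function(r) r$gt))
  colnames(gt) <- samples
  records <- data.frame(
    chrom = "chrY",
    pos = vapply(rows, function(r) r$pos, integer(1)),
    id = vapply(rows, function(r) r$id, character(1)),
    ref = vapply(rows, function(r) r$ref, character(1)),
    stringsAsFactors = FALSE)
  records$alts <- lapply(rows, function(r) r$alt)
  vt <- new_vcf_table(records, gt)
  body <- vapply(seq_along(rows), function(j) {
    paste(c(records$chrom[j], records$pos[j],
            ifelse(is.na(records$id[j]) | records$id[j] == "", ".", records$id[j]),
            records$ref[j], rows[[j]]$alt, ".", ".", ".", "GT", gt[j, ]),
          collapse = "\t")
  }, character(1))
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrY,length=57227415>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"),
           body)
  structure(list(vcf = vcf, vt = vt, truth = truth, calls_truth = calls_truth,
                 tree = tree, known = known, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples, %d records (%s), tree of %d nodes\n",
              nrow(x$calls_truth), nrow(x$truth),
              paste(names(table(x$truth$category)),
                    table(x$truth$category), sep = "=", collapse = ", "),
              length(x$tree$nodes)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits \code{cohort.vcf}, \code{truth.tsv}, \code{calls_truth.tsv},
#' \code{tree.nwk}, \code{markers.tsv} and \code{known.tsv} under \code{dir}.
#'
#' @param sim a \code{sim_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sim$vcf, file.path(dir, "cohort.vcf"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- sim$calls_truth
  utils::write.table(ct, file.path(dir, "calls_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(serialize_tree(sim$tree), file.path(dir, "tree.nwk"))
  utils::write.table(sim$tree$markers[, MARKER_COLS], file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$known[, MARKER_COLS], file.path(dir, "known.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
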