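# Packaged O-M175 fixtures.
#
# The tree topology is reconstructed from published subclade names by the
# nomenclature rule (a node's parent is its name minus the trailing run of
# same-type characters: O1b1a1a -> O1b1a1), hung under a minimal outgroup
# scaffold (Y -> C + NO; NO -> N + O) so that screens against the focal clade
# O have non-focal chromosomes to discriminate against. Marker positions and
# alleles in the packaged index are SYNTHETIC stand-ins — the published
# 2019-2020 index itself is not redistributed — except that marker/node
# pairings and InDel-vs-SNP classes follow the published assignments. Only
# the 22 candidate InDels carry real GRCh38 positions and event alleles.

# parent by nomenclature: strip the trailing maximal run of digits or letters
nomenclature_parent <- function(name) sub("([0-9]+|[a-z]+)$", "", name)

#' The 22 published candidate Y-InDels
#'
#' Subclade, rsID, GRCh38 position, event notation (\code{"X > -"} deletion /
#' \code{"- > X"} insertion relative to the ancestral state) and the number
#' of validation samples typed per locus.
#'
#' @return data.frame with columns \code{clade}, \code{rsid},
#'   \code{position}, \code{mutation}, \code{n_tested}.
#' @export
table1_indels <- function() {
  txt <- "clade|rsid|position|mutation|n_tested
O1a1|rs79011057|15870505|C > -|8
O1a1|rs75465866|14101642|T > -|8
O1a1a|rs756897195|14444770|TTG > -|5
O1a1a1|rs776778598|19623371|GAA > -|3
O1b|rs200942940|12416056|C > -|8
O1b1|rs760314663|20774821|C > -|6
O1b1a|rs749761428|6796839|- > T|5
O1b1a1a|rs774008684|17452553|AAGA > -|3
O1b1a1a1a1a1|rs774805227|16596493|A > -|1
O1b2|rs201451931|7765543|T > -|4
O1b2a1a|rs200704310|12173532|TAA > -|3
O2a|rs201101541|16693737|- > C|10
O2a1a1|rs2044026501|16599674|A > -|2
O2a1b|rs1569514296|13477987|TAC > -|6
O2a1b1a|rs754348496|12420208|T > -|4
O2a1b1a1a1a1|rs759556853|12663077|T > -|3
O2a2a|rs768760512|13353588|- > T|8
O2a2a1a|rs776330196|13497196|T > -|6
O2a2b|rs79480324|14153309|A > -|7
O2a2b1a1a1a4a|rs796937681|12821143|- > A|2
O2a2b1a2a|rs201510546|8044404|TAAAG > -|5
O2a2b1a2a1a|rs762474604|15235863|AT > -|2"
  utils::read.delim(text = txt, sep = "|", stringsAsFactors = FALSE)
}

# event notation -> anchored VCF alleles; the anchor is a synthetic base that
# never equals the event's first base, so the representation is unambiguous
parse_mutation_event <- function(mutation) {
  mut <- gsub("−", "-", trimws(mutation))
  parts <- trimws(strsplit(mut, ">", fixed = TRUE)[[1]])
  if (length(parts) != 2) yis_parse_error("cannot parse mutation notation '%s'", mutation)
  if (parts[2] == "-") {            # deletion of parts[1]
    bases <- parts[1]
    anchor <- if (substr(bases, 1, 1) == "A") "C" else "A"
    c(anc = paste0(anchor, bases), der = anchor)
  } else if (parts[1] == "-") {     # insertion of parts[2]
    bases <- parts[2]
    anchor <- if (substr(bases, 1, 1) == "A") "C" else "A"
    c(anc = anchor, der = paste0(anchor, bases))
  } else {
    c(anc = parts[1], der = parts[2])
  }
}

# named markers of the 2019-2020 O-M175 index that the fixture reconstructs.
# positions/alleles are synthetic; node pairing and SNP/InDel class are real.
om175_named_markers <- function() {
  txt <- "name|haplogroup|offset|ancestral|derived
M175|O|0|ATTCTC|A
M111|O1b1a1a1a1a1|1|AC|A
A15721|O1b1a1a1a1a1a1a1a|2|AG|A
M121|O2a1a1a1a1|3|AT|A
FGC12511|O2a1b1a|4|A|AT
M134|O2a2b1|5|AG|A
M117|O2a2b1a1|6|ACT|A
M133|O2a2b1a1a|7|A|AC
M333|O2a4|8|AGA|A
B384|O1a1|9|C|T
M1470|O1b1a|10|G|A
M188|O2a2a|11|A|G
CTS4658|O2a2b1a1a1a4a|12|C|A"
  df <- utils::read.delim(text = txt, sep = "|", stringsAsFactors = FALSE)
  df$position <- 2950000L + 100L * df$offset
  df[, c("name", "haplogroup", "position", "ancestral", "derived")]
}

#' Packaged O-M175 haplogroup tree fixture
#'
#' All published subclade names plus the ancestors their nomenclature
#' implies, rooted under a two-branch outgroup scaffold. Every non-root node
#' carries one synthetic defining SNP; the nine haplogroups historically
#' determinable by an InDel additionally carry their (synthetically
#' positioned) InDel marker, and four named representative SNPs are included.
#'
#' @return an \code{hg_tree} with the marker index attached.
#' @export
om175_tree <- function() {
  t1 <- table1_indels()
  named <- om175_named_markers()
  base <- unique(c(t1$clade, named$haplogroup, "O1b1a2"))
  nodes <- character(0)
  for (nd in base) {
    cur <- nd
    while (cur != "O") {
      nodes <- c(nodes, cur)
      cur <- nomenclature_parent(cur)
    }
  }
  o_nodes <- sort(unique(c("O", nodes)), method = "radix")
  parent <- stats::setNames(nomenclature_parent(o_nodes), o_nodes)
  parent["O"] <- "NO"
  parent <- c(parent, N = "NO", NO = "Y", C = "Y")
  all_nodes <- c(names(parent), "Y")
  children <- lapply(all_nodes, function(nm)
    sort(names(parent)[parent == nm], method = "radix"))
  names(children) <- all_nodes
  emit <- function(nd) {
    kids <- children[[nd]]
    if (length(kids) == 0) return(nd)
    paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", nd)
  }
  newick <- paste0(emit("Y"), ";")

  syn_nodes <- sort(setdiff(all_nodes, "Y"), method = "radix")
  al <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  syn <- data.frame(name = paste0("SYN_", syn_nodes), haplogroup = syn_nodes,
                    position = 2000000L + 1000L * seq_along(syn_nodes),
                    ancestral = vapply(seq_along(syn_nodes),
                                       function(i) al[[1 + (i %% 4)]][1], character(1)),
                    derived = vapply(seq_along(syn_nodes),
                                     function(i) al[[1 + (i %% 4)]][2], character(1)),
                    stringsAsFactors = FALSE)
  parse_haplogroup_tree(newick, rbind(syn, named))
}

#' The nine known InDel markers of the packaged index
#'
#' The haplogroups already determinable by an existing Y-InDel in the
#' 2019-2020 tree; screen hits duplicating any of them are annotated
#' \code{duplicate_of:} and dropped from the novel list.
#'
#' @return marker index data.frame (9 rows; synthetic positions/alleles).
#' @export
om175_known_indels <- function() {
  named <- om175_named_markers()
  validate_marker_table(named[1:9, ])
}

#' Build the Table-1 replay cohort
#'
#' A synthetic cohort on the packaged O-M175 tree: three samples assigned
#' directly to every node of the O subtree (so every published subclade has
#' a census of at least three) plus twelve outgroup samples. Each of the 22
#' published candidate InDels is planted clade-perfect on its printed
#' subclade at its printed GRCh38 position; the nine known InDel markers are
#' planted clade-perfect on their nodes (screen hits must be annotated as
#' duplicates); and 23 seeded decoys span the incomplete, leaky, homoplasic,
#' outside-focal and SNP categories.
#'
#' @param seed integer seed driving decoy construction.
#' @return a \code{sim_cohort} (see \code{\link{simulate_cohort}}).
#' @export
table1_replay_fixture <- function(seed = 1) {
  set.seed(as.integer(seed))
  tree <- om175_tree()
  o_nodes <- sort(tree_descendants(tree, "O"), method = "radix")
  truth_nodes <- c(rep(o_nodes, each = 3L), rep(c("C", "N"), each = 6L))
  samples <- sprintf("S%04d", seq_along(truth_nodes))
  calls_truth <- data.frame(sample = samples, true_node = truth_nodes,
                            stringsAsFactors = FALSE)
  calls_like <- data.frame(sample = samples, haplogroup = truth_nodes,
                           stringsAsFactors = FALSE)
  censuses <- census_map(tree, calls_like)
  known <- om175_known_indels()

  rec <- sim_recorder(samples)
  mk <- tree$markers
  for (i in seq_len(nrow(mk))) {
    m <- mk[i, ]
    rec$add(m$position, m$name, m$ancestral, m$derived,
            alt_carriers = censuses[[m$haplogroup]],
            category = if (m$name %in% known$name) "duplicate_known" else "marker_backbone",
            intended_clade = m$haplogroup, derived_is = "ALT")
  }
  t1 <- table1_indels()
  for (i in seq_len(nrow(t1))) {
    al <- parse_mutation_event(t1$mutation[i])
    rec$add(t1$position[i], t1$rsid[i], al[["anc"]], al[["der"]],
            alt_carriers = censuses[[t1$clade[i]]],
            category = "clade_perfect", intended_clade = t1$clade[i],
            derived_is = "ALT")
  }
  pool <- sample(SIM_PLANT_BLOCK, 23)
  pi <- 0L
  next_pos <- function() { pi <<- pi + 1L; pool[pi] }
  focal_nodes <- tree_descendants(tree, "O")
  outgroup_samples <- calls_truth$sample[calls_truth$true_node %in% c("C", "N")]
  plant_incomplete(rec, 6, focal_nodes, censuses, samples, next_pos)
  plant_leaky(rec, 6, focal_nodes, censuses, samples, next_pos)
  plant_homoplasic(rec, 4, focal_nodes, censuses, samples, tree, next_pos)
  plant_outside_focal(rec, 2, c("C", "N"), censuses, outgroup_samples, next_pos)
  plant_snp_decoys(rec, 5, samples, next_pos)

  cfg <- sim_config(tree = tree, seed = as.integer(seed))
  finish_sim(rec, tree, known, calls_truth, cfg)
}
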