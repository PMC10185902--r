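# Haplogroup assignment by greedy descent on derived-state defining markers.
#
# For each sample, every defining marker is scored ancestral / derived /
# missing against the genotype matrix; assignment walks the tree from the
# root, descending into a child when its branch markers show a strict
# majority of derived calls (and at least one derived call), and stops when
# no child qualifies. This mirrors how tree-index callers such as yhaplo
# resolve a sample's terminal haplogroup.

#' Score one defining marker across all samples
#'
#' The marker is matched against the matrix by position plus allele-set
#' equality of \{ancestral, derived\} and \{REF, ALT\}. Both orientations are
#' supported: when the reference genome carries the derived allele, matrix
#' code 0 means derived. A site absent from the matrix yields \code{missing}
#' for every sample (with a warning); an allele-set mismatch at a matching
#' position skips the marker the same way, signalling index/reference
#' discordance.
#'
#' @param gm a \code{geno_matrix}.
#' @param marker one row of a marker index (list or data.frame row) with
#'   \code{name}, \code{position}, \code{ancestral}, \code{derived}.
#' @return named character vector (one per sample) over
#'   \code{"ancestral"}, \code{"derived"}, \code{"missing"}.
#' @export
genotype_marker <- function(gm, marker) {
  stopifnot(inherits(gm, "geno_matrix"))
  miss <- stats::setNames(rep("missing", length(gm$samples)), gm$samples)
  at <- which(gm$variants$pos == as.integer(marker$position))
  if (length(at) == 0) {
    warning(sprintf("marker %s: no record at position %s; all samples set missing",
                    marker$name, marker$position))
    return(miss)
  }
  straight <- at[gm$variants$ref[at] == marker$ancestral &
                   gm$variants$alt[at] == marker$derived]
  swapped <- at[gm$variants$ref[at] == marker$derived &
                  gm$variants$alt[at] == marker$ancestral]
  if (length(straight) == 0 && length(swapped) == 0) {
    warning(sprintf("marker %s: allele set mismatch at position %s; marker skipped",
                    marker$name, marker$position))
    return(miss)
  }
  i <- if (length(straight) > 0) straight[1] else swapped[1]
  derived_code <- if (length(straight) > 0) 1L else 0L
  v <- gm$calls[i, ]
  out <- ifelse(is.na(v), "missing",
                ifelse(v == derived_code, "derived", "ancestral"))
  stats::setNames(out, gm$samples)
}

# markers x samples matrix over {1 derived, 0 ancestral, NA missing}
marker_state_matrix <- function(gm, tree) {
  mk <- tree$markers
  S <- matrix(NA_integer_, nrow = nrow(mk), ncol = length(gm$samples),
              dimnames = list(mk$name, gm$samples))
  for (i in seq_len(nrow(mk))) {
    st <- genotype_marker(gm, mk[i, ])
    S[i, ] <- ifelse(st == "derived", 1L, ifelse(st == "ancestral", 0L, NA_integer_))
  }
  S
}

#' Assign one sample to a haplogroup
#'
#' Greedy descent: at each node the children (in lexicographic order) are
#' scored over their defining markers; a child with \code{d} derived and
#' \code{a} ancestral calls is eligible when \code{d >= 1} and
#' \code{d/(d+a) > min_support}. Descent follows the eligible child with the
#' largest support, ties broken by larger \code{d}, then by name, and stops
#' when no child is eligible. All-ancestral or all-missing samples are
#' returned at the root.
#'
#' @param states named integer vector (marker name -> 1 derived, 0 ancestral,
#'   NA missing) for one sample.
#' @param tree an \code{hg_tree} whose marker index the states cover.
#' @param min_support exclusive support threshold per branch (default 0.5:
#'   strict majority, so a single-marker branch needs its one marker derived).
#' @return list with \code{node}, root-to-node \code{path},
#'   \code{derived_support}, \code{conflicts} (ancestral calls on the accepted
#'   path) and \code{no_data}.
#' @export
assign_haplogroup <- function(states, tree, min_support = 0.5) {
  branch_counts <- function(node) {
    mk <- tree$node_markers[[node]]
    s <- states[mk]
    c(d = sum(s == 1L, na.rm = TRUE), a = sum(s == 0L, na.rm = TRUE))
  }
  cur <- tree$root
  path <- cur
  d_tot <- 0L; a_tot <- 0L
  repeat {
    kids <- tree$children[[cur]]
    if (length(kids) == 0) break
    sc <- vapply(kids, branch_counts, numeric(2))
    d <- sc["d", ]; a <- sc["a", ]
    sup <- ifelse(d + a > 0, d / (d + a), 0)
    ok <- d >= 1 & sup > min_support
    if (!any(ok)) break
    # deterministic choice: support, then derived count, then name (kids sorted)
    cand <- which(ok)
    cand <- cand[order(-sup[cand], -d[cand])]
    pick <- kids[cand[1]]
    d_tot <- d_tot + d[cand[1]]; a_tot <- a_tot + a[cand[1]]
    path <- c(path, pick)
    cur <- pick
  }
  list(node = cur, path = path,
       derived_support = as.integer(d_tot), conflicts = as.integer(a_tot),
       no_data = all(is.na(states)) || length(states) == 0)
}

#' Assign every sample in a genotype matrix
#'
#' @param gm a \code{geno_matrix} retaining at least the classes the marker
#'   index needs (SNPs, plus InDels if any markers are InDels).
#' @param tree an \code{hg_tree} with a non-empty marker index.
#' @param min_support see \code{\link{assign_haplogroup}}.
#' @return data.frame with one row per sample: \code{sample},
#'   \code{haplogroup}, pipe-separated \code{path}, \code{derived_support},
#'   \code{conflicts}, \code{no_data}.
#' @export
assign_all <- function(gm, tree, min_support = 0.5) {
  if (nrow(tree$markers) == 0)
    yis_config_error("tree carries no defining markers; cannot assign haplogroups")
  S <- withCallingHandlers(
    marker_state_matrix(gm, tree),
    warning = function(w) { yis_log("assign_all: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  calls <- lapply(gm$samples, function(s) {
    res <- assign_haplogroup(S[, s], tree, min_support)
    data.frame(sample = s, haplogroup = res$node,
               path = paste(res$path, collapse = "|"),
               derived_support = res$derived_support,
               conflicts = res$conflicts, no_data = res$no_data,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  tab <- sort(table(out$haplogroup), decreasing = TRUE)
  yis_log("assign_all: %d samples -> %d distinct nodes (top: %s)",
          nrow(out), length(tab),
          paste(utils::head(paste0(names(tab), "=", tab), 5), collapse = ", "))
  if (any(out$no_data))
    yis_log("assign_all: %d sample(s) with zero overlapping markers called at root (no-data)",
            sum(out$no_data))
  out
}

#' Write a haplogroup calls table
#'
#' @param calls data.frame from \code{\link{assign_all}}.
#' @param path output TSV.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
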