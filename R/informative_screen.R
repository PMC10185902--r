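# The clade-exactness screen.
#
# A variant is phylogenetically informative for a clade C when its derived
# allele is carried by every member of C (criterion 1) and by nobody outside
# C (criterion 2). The screen first restricts to variants polymorphic only
# inside a focal clade (one allele's carriers form a non-empty subset of the
# focal clade's samples — the clade-confined allele may be REF or ALT, since
# the reference chromosome need not belong to the focal haplogroup), proposes
# the clade as the LCA of the derived carriers' called nodes, verifies both
# criteria over called samples, and finally annotates candidates that
# duplicate markers already defining tree nodes.

#' Screen configuration
#'
#' @param focal_clade node name of the focal clade (default \code{"O"},
#'   the East-Asian O-M175 haplogroup).
#' @param min_call_fraction minimum fraction of samples callable at a variant
#'   for it to enter the screen (default 0.9; in (0, 1]).
#' @param strict_missing if \code{TRUE}, a missing call inside the proposed
#'   clade rejects the candidate as unverifiable instead of being ignored.
#' @return a \code{screen_config} list.
#' @export
screen_config <- function(focal_clade = "O", min_call_fraction = 0.9,
                          strict_missing = FALSE) {
  if (!is.numeric(min_call_fraction) || min_call_fraction <= 0 || min_call_fraction > 1)
    yis_config_error("min_call_fraction must lie in (0, 1]")
  structure(list(focal_clade = focal_clade,
                 min_call_fraction = min_call_fraction,
                 strict_missing = isTRUE(strict_missing)),
            class = "screen_config")
}

#' Samples belonging to a clade
#'
#' A sample belongs to clade \code{node} when its called haplogroup is
#' \code{node} or any descendant. Samples resolved only to an ancestor count
#' for that ancestor's clade, not for any subclade.
#'
#' @param tree an \code{hg_tree}.
#' @param calls calls table from \code{\link{assign_all}} (or a truth table
#'   with columns \code{sample}, \code{haplogroup}).
#' @param node clade root name.
#' @return character vector of sample ids.
#' @export
clade_samples <- function(tree, calls, node) {
  check_node(tree, node)
  bad <- setdiff(unique(calls$haplogroup), tree$nodes)
  if (length(bad) > 0)
    yis_contract_error("calls reference node(s) absent from tree: %s",
                       paste(bad, collapse = ", "))
  calls$sample[calls$haplogroup %in% tree_descendants(tree, node)]
}

# named list node -> member sample ids, computed once per screen
census_map <- function(tree, calls) {
  sapply(tree$nodes, function(n) clade_samples(tree, calls, n), simplify = FALSE)
}

#' Per-clade derived-allele frequencies by direct counting
#'
#' One row per (variant, clade) with at least one called clade member;
#' clades with no called member are omitted, not zero-filled. Counts follow
#' the ALT-coded convention of the matrix (orientation is resolved later, at
#' screening).
#'
#' @param gm a \code{geno_matrix}.
#' @param calls calls table (see \code{\link{clade_samples}}).
#' @param tree an \code{hg_tree}.
#' @return data.frame: \code{variant_key}, \code{clade}, \code{derived_count},
#'   \code{called_count}, \code{frequency}.
#' @export
clade_frequencies <- function(gm, calls, tree) {
  censuses <- census_map(tree, calls)
  rows <- lapply(tree$nodes, function(n) {
    members <- intersect(censuses[[n]], gm$samples)
    if (length(members) == 0) return(NULL)
    sub <- gm$calls[, members, drop = FALSE]
    der <- rowSums(sub == 1L, na.rm = TRUE)
    cal <- rowSums(!is.na(sub))
    keep <- cal > 0
    if (!any(keep)) return(NULL)
    data.frame(variant_key = gm$variants$key[keep], clade = n,
               derived_count = as.integer(der[keep]),
               called_count = as.integer(cal[keep]),
               frequency = der[keep] / cal[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_key = character(), clade = character(),
                      derived_count = integer(), called_count = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Focal-clade restriction for one variant
#'
#' Formalizes "polymorphic only in the focal clade": returns \code{"ALT"}
#' when the ALT-carrier set is non-empty and contained in the focal clade's
#' samples, \code{"REF"} when the REF-carrier set is, and \code{"NONE"}
#' otherwise (reason \code{"low-call"} when fewer than
#' \code{min_call_fraction} of samples are callable, else
#' \code{"not-focal"}).
#'
#' @param v integer vector of 0/1/NA calls for one variant, named by sample.
#' @param focal_members sample ids of the focal clade
#'   (\code{\link{clade_samples}} of the focal node).
#' @param min_call_fraction callability gate in (0, 1].
#' @return list(orientation, reason).
#' @export
focal_restricted <- function(v, focal_members, min_call_fraction = 0.9) {
  if (length(v) == 0 || mean(!is.na(v)) < min_call_fraction)
    return(list(orientation = "NONE", reason = "low-call"))
  alt_c <- names(v)[!is.na(v) & v == 1L]
  ref_c <- names(v)[!is.na(v) & v == 0L]
  if (length(alt_c) > 0 && all(alt_c %in% focal_members))
    return(list(orientation = "ALT", reason = NA_character_))
  if (length(ref_c) > 0 && all(ref_c %in% focal_members))
    return(list(orientation = "REF", reason = NA_character_))
  list(orientation = "NONE", reason = "not-focal")
}

#' Clade assignment and clade-exactness test for one variant
#'
#' The derived-carrier set \code{D} under the given orientation proposes the
#' clade \code{C* = lca(called nodes of D)}. The variant is accepted iff every
#' called sample of \code{C*}'s clade lies in \code{D} (criterion 1) and no
#' called sample outside the clade does (criterion 2 — automatic given the
#' LCA, but re-verified). With \code{strict_missing}, any missing call inside
#' the clade rejects as \code{"unverifiable"}.
#'
#' @param v named 0/1/NA call vector for one variant.
#' @param orientation \code{"REF"} or \code{"ALT"}: which allele is derived.
#' @param calls calls table.
#' @param tree an \code{hg_tree}.
#' @param config a \code{screen_config}.
#' @param censuses optional precomputed \code{census_map(tree, calls)}.
#' @return list(accepted, clade, carriers, clade_called, outside_derived,
#'   reason).
#' @export
assign_clade <- function(v, orientation, calls, tree, config = screen_config(),
                         censuses = NULL) {
  if (!orientation %in% c("REF", "ALT"))
    yis_contract_error("orientation must be REF or ALT")
  derived_code <- if (orientation == "ALT") 1L else 0L
  D <- names(v)[!is.na(v) & v == derived_code]
  if (length(D) == 0)
    yis_contract_error("empty derived-carrier set: focal_restricted must precede assign_clade")
  if (is.null(censuses)) censuses <- census_map(tree, calls)
  node_of <- stats::setNames(calls$haplogroup, calls$sample)
  cstar <- tree_lca(tree, unique(node_of[D]))
  members <- censuses[[cstar]]
  called_members <- members[!is.na(v[members])]
  outside_derived <- setdiff(D, members)          # empty by LCA construction
  rej <- function(reason) list(accepted = FALSE, clade = cstar, carriers = length(D),
                               clade_called = length(called_members),
                               outside_derived = length(outside_derived),
                               reason = reason)
  if (length(outside_derived) > 0) return(rej("criterion2"))
  if (!all(called_members %in% D)) return(rej("criterion1"))
  if (config$strict_missing && length(called_members) < length(members))
    return(rej("unverifiable"))
  list(accepted = TRUE, clade = cstar, carriers = length(D),
       clade_called = length(called_members), outside_derived = 0L,
       reason = NA_character_)
}

#' Annotate candidates duplicating known tree-defining markers
#'
#' A candidate matching a known marker on (position, allele set) gets status
#' \code{duplicate_of:<name>} and leaves the novel list; a position-only
#' match is kept as novel with a warning.
#'
#' @param candidates candidate data.frame (needs \code{position}, \code{ref},
#'   \code{alt}).
#' @param known marker index data.frame of known markers (anchored alleles).
#' @return the candidates with a \code{status} column
#'   (\code{"novel"} / \code{"duplicate_of:<name>"}).
#' @export
dedup_known <- function(candidates, known) {
  status <- rep("novel", nrow(candidates))
  if (!is.null(known) && nrow(known) > 0 && nrow(candidates) > 0) {
    for (i in seq_len(nrow(candidates))) {
      at <- which(as.integer(known$position) == candidates$position[i])
      if (length(at) == 0) next
      hit <- at[(known$ancestral[at] == candidates$ref[i] & known$derived[at] == candidates$alt[i]) |
                  (known$ancestral[at] == candidates$alt[i] & known$derived[at] == candidates$ref[i])]
      if (length(hit) > 0) {
        status[i] <- paste0("duplicate_of:", known$name[hit[1]])
      } else {
        warning(sprintf("candidate at position %d shares a position with known marker %s but not its alleles; kept as novel",
                        candidates$position[i], known$name[at[1]]))
      }
    }
  }
  candidates$status <- status
  candidates
}

# Table-1 style mutation notation from anchored REF/ALT
format_mutation <- function(ref, alt) {
  mapply(function(r, a) {
    if (nchar(r) > nchar(a) && startsWith(r, a))
      paste0(substr(r, nchar(a) + 1L, nchar(r)), " > -")
    else if (nchar(a) > nchar(r) && startsWith(a, r))
      paste0("- > ", substr(a, nchar(r) + 1L, nchar(a)))
    else paste(r, ">", a)
  }, ref, alt, USE.NAMES = FALSE)
}

#' Run the clade-exactness screen
#'
#' Applies, in order: callability gate, focal restriction, LCA clade
#' assignment with the two clade-exactness criteria, and deduplication
#' against known tree-defining markers. The bi-allelic-InDel restriction is
#' assumed done upstream in \code{\link{build_genotype_matrix}}.
#'
#' @param gm a \code{geno_matrix} of bi-allelic InDels.
#' @param calls calls table from \code{\link{assign_all}} covering the matrix
#'   samples.
#' @param tree an \code{hg_tree}.
#' @param config a \code{\link{screen_config}}.
#' @param known optional marker index data.frame for deduplication.
#' @return a \code{screen_result}: stage \code{counters}, full
#'   \code{candidates} table (novel + duplicates, sorted by clade depth then
#'   position), the \code{novel} subset, and per-variant \code{rejections}.
#' @export
screen_indels <- function(gm, calls, tree, config = screen_config(), known = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!config$focal_clade %in% tree$nodes)
    yis_config_error("focal clade '%s' absent from tree", config$focal_clade)
  censuses <- census_map(tree, calls)
  focal_members <- censuses[[config$focal_clade]]
  nv <- nrow(gm$variants)
  seen <- attr(gm, "counts")$seen
  if (is.null(seen)) seen <- nv

  cand_rows <- list(); rej_rows <- list()
  n_callable <- 0L; n_focal <- 0L
  for (i in seq_len(nv)) {
    key <- gm$variants$key[i]
    v <- gm$calls[i, ]
    fr <- focal_restricted(v, focal_members, config$min_call_fraction)
    if (fr$orientation == "NONE") {
      if (!identical(fr$reason, "low-call")) n_callable <- n_callable + 1L
      rej_rows[[length(rej_rows) + 1L]] <-
        data.frame(variant_key = key, stage = "focal_restricted",
                   reason = fr$reason, stringsAsFactors = FALSE)
      next
    }
    n_callable <- n_callable + 1L
    n_focal <- n_focal + 1L
    ac <- assign_clade(v, fr$orientation, calls, tree, config, censuses)
    if (!ac$accepted) {
      rej_rows[[length(rej_rows) + 1L]] <-
        data.frame(variant_key = key, stage = "assign_clade",
                   reason = ac$reason, stringsAsFactors = FALSE)
      next
    }
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      variant_key = key, rsid = gm$variants$id[i],
      position = gm$variants$pos[i],
      ref = gm$variants$ref[i], alt = gm$variants$alt[i],
      mutation = format_mutation(gm$variants$ref[i], gm$variants$alt[i]),
      assigned_clade = ac$clade, orientation = fr$orientation,
      carriers = ac$carriers, clade_called = ac$clade_called,
      outside_derived = ac$outside_derived, stringsAsFactors = FALSE)
  }

  candidates <- if (length(cand_rows) > 0) do.call(rbind, cand_rows) else
    data.frame(variant_key = character(), rsid = character(), position = integer(),
               ref = character(), alt = character(), mutation = character(),
               assigned_clade = character(), orientation = character(),
               carriers = integer(), clade_called = integer(),
               outside_derived = integer(), stringsAsFactors = FALSE)
  candidates <- dedup_known(candidates, known)
  if (nrow(candidates) > 0) {
    candidates <- candidates[order(tree$depth[candidates$assigned_clade],
                                   candidates$position), , drop = FALSE]
    rownames(candidates) <- NULL
    low <- candidates$clade_called < 3 & candidates$status == "novel"
    if (any(low))
      yis_log("screen: %d novel candidate(s) rest on a clade census < 3 (low evidence): %s",
              sum(low), paste(candidates$variant_key[low], collapse = ", "))
  }
  novel <- candidates[candidates$status == "novel", , drop = FALSE]
  rejections <- if (length(rej_rows) > 0) do.call(rbind, rej_rows) else
    data.frame(variant_key = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)

  counters <- c(records_seen = seen, biallelic_indels = nv,
                callable = n_callable, focal_restricted = n_focal,
                clade_exact = nrow(candidates), novel = nrow(novel))
  yis_log("screen: %s", paste(names(counters), counters, sep = "=", collapse = ", "))
  structure(list(config = config, counters = counters, candidates = candidates,
                 novel = novel, rejections = rejections),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n  ",
      paste(names(x$counters), x$counters, sep = " = ", collapse = "\n   "), "\n",
      sep = "")
  if (nrow(x$novel) > 0) {
    tab <- table(x$novel$assigned_clade)
    cat(sprintf("  novel candidates across %d clades\n", length(tab)))
  }
  invisible(x)
}
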