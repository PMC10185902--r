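# Haplogroup tree + marker index: the coordinate system for all clade logic.
#
# The tree is a rooted hierarchy of haplogroup labels (O -> O1 -> O1a ...) read
# from Newick with *labeled internal nodes*; branch lengths, if present, are
# ignored. Defining markers live in a separate tab-separated index and are
# attached to the node whose branch they define.

MARKER_COLS <- c("name", "haplogroup", "position", "ancestral", "derived")

#' Read a marker index table
#'
#' The index is a tab-separated file with header columns
#' \code{name}, \code{haplogroup}, \code{position}, \code{ancestral},
#' \code{derived}. Alleles are strings over \code{A,C,G,T} (multi-base for
#' InDels, anchored VCF style); \code{"."} is not a legal allele.
#'
#' @param path file path of the TSV.
#' @return data.frame with the five index columns plus \code{variant_class}
#'   (\code{"snp"} or \code{"indel"}).
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) yis_parse_error("marker table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  validate_marker_table(df)
}

#' @rdname read_marker_table
#' @param markers a data.frame carrying the five index columns.
#' @export
validate_marker_table <- function(markers) {
  missing_cols <- setdiff(MARKER_COLS, names(markers))
  if (length(missing_cols) > 0)
    yis_format_error("marker table lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  df <- as.data.frame(markers)[, MARKER_COLS]
  for (col in c("name", "haplogroup", "ancestral", "derived"))
    df[[col]] <- trimws(as.character(df[[col]]))
  df$position <- as.integer(df$position)
  if (anyNA(df$position) || any(df$position < 1))
    yis_validate_error("marker positions must be integers >= 1")
  bad_allele <- !grepl("^[ACGT]+$", df$ancestral) | !grepl("^[ACGT]+$", df$derived)
  if (any(bad_allele))
    yis_validate_error("marker alleles must be non-empty ACGT strings ('.' is not allowed): %s",
                       paste(df$name[bad_allele], collapse = ", "))
  same <- df$ancestral == df$derived
  if (any(same))
    yis_validate_error("ancestral and derived allele identical for marker(s): %s",
                       paste(df$name[same], collapse = ", "))
  if (anyDuplicated(df$name))
    yis_validate_error("duplicate marker name(s): %s",
                       paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  triple <- paste(df$position, df$ancestral, df$derived, sep = ":")
  if (anyDuplicated(triple))
    yis_validate_error("duplicate (position, ancestral, derived) triple(s): %s",
                       paste(unique(triple[duplicated(triple)]), collapse = ", "))
  df$variant_class <- ifelse(nchar(df$ancestral) != nchar(df$derived), "indel", "snp")
  rownames(df) <- NULL
  df
}

#' Parse and validate a haplogroup tree
#'
#' @param newick Newick text (or path to a file holding it) with labeled
#'   internal nodes; singleton (unary) internal nodes are allowed, which the
#'   deep unary chains of Y-haplogroup nomenclature require.
#' @param markers optional marker index: a data.frame or a TSV path
#'   (see \code{\link{read_marker_table}}). Every marker must name an existing
#'   node; orphan markers are fatal.
#' @return an object of class \code{hg_tree}: named \code{parent} vector
#'   (\code{NA} at the root), lexicographically sorted \code{children} lists,
#'   node \code{depth} (root = 0), the marker index and a per-node marker map.
#' @export
parse_haplogroup_tree <- function(newick, markers = NULL) {
  txt <- newick
  if (length(txt) == 1 && !grepl("[();]", txt) && file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  txt <- trimws(paste(txt, collapse = ""))
  check_newick_balance(txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) yis_parse_error("malformed Newick: %s", conditionMessage(e)))
  if (is.null(phy)) yis_parse_error("malformed Newick: no tree could be read")

  labels <- c(phy$tip.label, phy$node.label)
  labels <- trimws(labels)
  n_tip <- length(phy$tip.label)
  if (length(phy$node.label) != phy$Nnode || any(labels == ""))
    yis_validate_error("all internal nodes must carry a label")
  if (anyDuplicated(labels))
    yis_validate_error("duplicate node name(s): %s",
                       paste(unique(labels[duplicated(labels)]), collapse = ", "))

  parent <- rep(NA_character_, length(labels))
  names(parent) <- labels
  for (i in seq_len(nrow(phy$edge)))
    parent[labels[phy$edge[i, 2]]] <- labels[phy$edge[i, 1]]
  root <- labels[n_tip + 1L]
  if (sum(is.na(parent)) != 1L || is.na(parent[root]) == FALSE)
    yis_validate_error("tree must have exactly one root")

  children <- lapply(labels, function(nm) {
    kids <- names(parent)[!is.na(parent) & parent == nm]
    sort(kids, method = "radix")
  })
  names(children) <- labels

  depth <- rep(NA_integer_, length(labels)); names(depth) <- labels
  depth[root] <- 0L
  queue <- root
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    kids <- children[[cur]]
    depth[kids] <- depth[cur] + 1L
    queue <- c(queue, kids)
  }
  if (anyNA(depth)) yis_validate_error("tree contains disconnected node(s)")

  if (is.character(markers) && length(markers) == 1) markers <- read_marker_table(markers)
  if (is.null(markers)) {
    markers <- data.frame(name = character(), haplogroup = character(),
                          position = integer(), ancestral = character(),
                          derived = character(), variant_class = character(),
                          stringsAsFactors = FALSE)
  } else {
    markers <- validate_marker_table(markers)
    orphan <- setdiff(markers$haplogroup, labels)
    if (length(orphan) > 0)
      yis_validate_error("marker(s) reference unknown tree node(s): %s",
                         paste(markers$name[markers$haplogroup %in% orphan], collapse = ", "))
  }
  node_markers <- split(markers$name, factor(markers$haplogroup, levels = labels))

  structure(list(root = root, nodes = labels, parent = parent,
                 children = children, depth = depth,
                 markers = markers, node_markers = node_markers),
            class = "hg_tree")
}

check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  bal <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") bal <- bal + 1L
    if (chars[i] == ")") bal <- bal - 1L
    if (bal < 0L)
      yis_parse_error("malformed Newick: unmatched ')' at character %d", i)
  }
  if (bal != 0L)
    yis_parse_error("malformed Newick: %d unclosed '('", bal)
  if (!grepl(";\\s*$", txt))
    yis_parse_error("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

check_node <- function(tree, node) {
  if (!node %in% tree$nodes)
    yis_lookup_error("unknown tree node: %s", node)
  invisible(node)
}

#' Clade membership, ancestry and LCA primitives
#'
#' \code{tree_descendants} returns the clade below (and including) a node;
#' \code{tree_ancestors} the root-to-node path; \code{tree_lca} the deepest
#' node whose clade contains all inputs.
#'
#' @param tree an \code{hg_tree}.
#' @param node,nodes node name(s); must exist in the tree.
#' @return character vector of node names (\code{tree_lca}: a single name).
#' @export
tree_descendants <- function(tree, node) {
  check_node(tree, node)
  out <- character(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, cur)
    kids <- tree$children[[cur]]
    if (length(kids) > 0) stack <- c(stack, rev(kids))
  }
  out
}

#' @rdname tree_descendants
#' @export
tree_ancestors <- function(tree, node) {
  check_node(tree, node)
  path <- node
  while (!is.na(tree$parent[[path[1]]]))
    path <- c(tree$parent[[path[1]]], path)
  path
}

#' @rdname tree_descendants
#' @export
tree_lca <- function(tree, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 0)
    yis_contract_error("tree_lca() requires a non-empty node set")
  for (n in nodes) check_node(tree, n)
  common <- tree_ancestors(tree, nodes[1])
  for (n in nodes[-1]) common <- intersect(common, tree_ancestors(tree, n))
  common[which.max(tree$depth[common])]
}

#' Serialize an hg_tree back to Newick
#'
#' Children are emitted in their stored (lexicographic) order, so
#' parse/serialize/parse round-trips are stable.
#'
#' @param tree an \code{hg_tree}.
#' @return a single Newick string (no branch lengths).
#' @export
serialize_tree <- function(tree) {
  emit <- function(node) {
    kids <- tree$children[[node]]
    if (length(kids) == 0) return(node)
    paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", node)
  }
  paste0(emit(tree$root), ";")
}

#' @export
print.hg_tree <- function(x, ...) {
  n_ind <- sum(x$markers$variant_class == "indel")
  cat(sprintf("<hg_tree> %d nodes rooted at '%s'; %d markers (%d InDel)\n",
              length(x$nodes), x$root, nrow(x$markers), n_ind))
  invisible(x)
}
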