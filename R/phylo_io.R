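## Tree input/output and validation. Trees are ape "phylo" objects; tip
## labels are canonicalized the same way as trait-table species names.

#' Read a rooted tree from Newick or NEXUS
#'
#' @param path File containing a single rooted tree. NEXUS files are
#'   detected by their `#NEXUS` header.
#' @param resolve_polytomies If `TRUE`, polytomies are resolved with
#'   zero-length branches ([ape::multi2di()]); by default they are rejected.
#' @return A rooted `phylo` object with canonicalized tip labels.
#' @export
read_tree <- function(path, resolve_polytomies = FALSE) {
  first <- toupper(trimws(readLines(path, n = 1L)))
  tree <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path)
          else ape::read.tree(path)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse a tree from ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("file contains more than one tree", call. = FALSE)
    tree <- tree[[1L]]
  }
  if (!ape::is.rooted(tree))
    stop("tree is not rooted", call. = FALSE)
  if (!ape::is.binary(tree)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies (set resolve_polytomies = TRUE)",
           call. = FALSE)
    tree <- ape::multi2di(tree)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  tree$tip.label <- canonical_species(tree$tip.label)
  tree
}

#' Root-to-tip depths of all tips
#' @param tree A `phylo` object.
#' @return Named numeric vector of depths (tree time units).
#' @export
tip_depths <- function(tree) {
  nt <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  names(depth) <- tree$tip.label
  depth
}

#' Check whether a tree is ultrametric within tolerance
#'
#' Deviation is the maximum over tips of the absolute difference between the
#' root-to-tip depth and the mean depth. By default the tolerance is
#' `1e-6` times tree height; failing the check is reported, not fatal
#' (the Mk likelihood is defined for any branch lengths).
#'
#' @param tree A `phylo` object.
#' @param tolerance Absolute tolerance in branch-length units; default
#'   `1e-6 * max(depth)`.
#' @return List with `is_ultrametric`, `max_depth_deviation`, `tolerance`.
#' @export
check_ultrametric <- function(tree, tolerance = NULL) {
  d <- tip_depths(tree)
  if (is.null(tolerance)) tolerance <- 1e-6 * max(d)
  dev <- max(abs(d - mean(d)))
  structure(list(is_ultrametric = dev <= tolerance,
                 max_depth_deviation = dev,
                 tolerance = tolerance),
            class = "ultrametry_report")
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (canonicalized before lookup).
#' @return Internal node id (ape numbering); for a single tip, the tip id.
#' @export
mrca_node <- function(tree, tips) {
  tips <- canonical_species(tips)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

## stable content-based node key: sorted descendant tip labels, hashed short
node_tip_key <- function(tree, node) {
  nt <- ape::Ntip(tree)
  tips <- if (node <= nt) tree$tip.label[node]
          else ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = "|")
}

#' Write a NEXUS tree annotated with per-node state probabilities
#'
#' Each node carries a comment `[&states={p0,p1,p2}]`; probabilities are
#' preserved to at least 6 decimals and each triple must sum to 1 within
#' `1e-9`. A node-table data frame (see [node_probability_table()]) is the
#' machine-readable companion.
#'
#' @param tree A `phylo` object.
#' @param node_probs Numeric matrix, rows = all nodes in ape numbering
#'   (`1..Ntip+Nnode`), 3 columns of state probabilities.
#' @param path Output file.
#' @param state_labels Optional character(3) recorded in the file header.
#' @export
write_annotated_tree <- function(tree, node_probs, path, state_labels = NULL) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  if (!is.matrix(node_probs) || nrow(node_probs) != n_all ||
      ncol(node_probs) != 3L)
    stop("node_probs must be a (Ntip+Nnode) x 3 matrix", call. = FALSE)
  if (anyNA(node_probs))
    stop("node_probs contains missing entries", call. = FALSE)
  bad <- abs(rowSums(node_probs) - 1) > 1e-9
  if (any(bad))
    stop("node probability rows do not sum to 1: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  nwk <- annotated_newick(tree, node_probs)
  lines <- c("#NEXUS", "BEGIN TREES;")
  if (!is.null(state_labels))
    lines <- c(lines, paste0("[states: ", paste(state_labels, collapse = ","), "]"))
  lines <- c(lines, paste0("  TREE annotated = ", nwk), "END;")
  writeLines(lines, path)
  invisible(path)
}

annotated_newick <- function(tree, node_probs) {
  nt <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- numeric(nt + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  fmt <- function(p) sprintf("[&states={%.9f,%.9f,%.9f}]", p[1], p[2], p[3])
  rec <- function(node) {
    ann <- fmt(node_probs[node, ])
    if (node <= nt) {
      paste0(quote_label(tree$tip.label[node]), ann, ":",
             format(blen[node], digits = 15))
    } else {
      kids <- vapply(children[[as.character(node)]], rec, character(1))
      root <- node == nt + 1L
      paste0("(", paste(kids, collapse = ","), ")", ann,
             if (root) "" else paste0(":", format(blen[node], digits = 15)))
    }
  }
  paste0(rec(nt + 1L), ";")
}

quote_label <- function(x) {
  ifelse(grepl("[ (),:;\\[\\]]", x), paste0("'", x, "'"), x)
}

#' Read back a tree written by [write_annotated_tree()]
#'
#' @param path Annotated NEXUS file.
#' @return List with `tree` (`phylo`) and `node_probs` (matrix in ape node
#'   numbering of the returned tree).
#' @export
read_annotated_tree <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  m <- regmatches(txt, regexpr("TREE[^=]*=\\s*[^;]+;", txt))
  if (!length(m)) stop("no TREE statement found", call. = FALSE)
  nwk <- sub("TREE[^=]*=\\s*", "", m)
  anns <- regmatches(nwk, gregexpr("\\[&states=\\{[^}]*\\}\\]", nwk))[[1]]
  probs <- do.call(rbind, lapply(anns, function(a) {
    as.numeric(strsplit(gsub("\\[&states=\\{|\\}\\]", "", a), ",")[[1]])
  }))
  ## tag annotations with ordinal markers so they survive ape's parser
  nwk_tagged <- nwk
  for (i in seq_along(anns)) {
    nwk_tagged <- sub("\\[&states=\\{[^}]*\\}\\]",
                      paste0("@@", i, "@@"), nwk_tagged)
  }
  ## the marker ends up appended to the node label position
  nwk_clean <- gsub("@@(\\d+)@@", "", nwk_tagged)
  tree <- ape::read.tree(text = nwk_clean)
  ## recover node order: parse once more keeping markers as labels
  nwk_lab <- gsub("@@(\\d+)@@", "MARK\\1", nwk_tagged)
  tree_lab <- ape::read.tree(text = nwk_lab)
  ord <- integer(ape::Ntip(tree) + tree$Nnode)
  tiplab <- tree_lab$tip.label
  for (i in seq_along(tiplab)) {
    mk <- as.integer(sub(".*MARK(\\d+)$", "\\1", tiplab[i]))
    ord[i] <- mk
    tree$tip.label[i] <- sub("MARK\\d+$", "", tiplab[i])
  }
  nodelab <- tree_lab$node.label
  for (i in seq_along(nodelab)) {
    mk <- as.integer(sub(".*MARK(\\d+)$", "\\1", nodelab[i]))
    ord[ape::Ntip(tree) + i] <- mk
  }
  tree$node.label <- NULL
  list(tree = tree, node_probs = probs[ord, , drop = FALSE])
}

#' Per-node state-probability table
#'
#' @param tree A `phylo` object.
#' @param node_probs Matrix as in [write_annotated_tree()].
#' @param state_labels Optional column labels for the three states.
#' @return Data frame `node_id, child_tips_key, p_state0, p_state1, p_state2`
#'   (probability columns renamed when `state_labels` given).
#' @export
node_probability_table <- function(tree, node_probs, state_labels = NULL) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  keys <- vapply(seq_len(n_all), function(v) node_tip_key(tree, v), character(1))
  out <- data.frame(node_id = seq_len(n_all), child_tips_key = keys,
                    p_state0 = node_probs[, 1], p_state1 = node_probs[, 2],
                    p_state2 = node_probs[, 3], stringsAsFactors = FALSE)
  if (!is.null(state_labels))
    names(out)[3:5] <- paste0("p_", gsub("[ ]+", "_", state_labels))
  out
}

#' Bundled synthetic 64-tip blowfly tree
#'
#' A SYNTHETIC stand-in for the time-calibrated Calliphoridae phylogeny:
#' a Yule tree over the 61 ingroup species plus the 3 sarcophagid outgroup
#' species, rescaled to unit height. It reproduces only the taxon set, not
#' the published topology or divergence times.
#'
#' @return A rooted ultrametric `phylo` with 64 tips.
#' @export
blowfly_tree_synthetic <- function() {
  read_tree(system.file("extdata", "synthetic_blowfly_tree.nwk",
                        package = "rjmk", mustWork = TRUE))
}
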