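#' Classify one input tree against one supertree clade
#'
#' The clade is restricted to the input tree's leaves. The input tree is
#' \emph{irrelevant} when the restriction has fewer than 2 taxa or its
#' complement within the input tree is empty; it \emph{supports} the clade
#' when it displays exactly the restricted clade; it \emph{conflicts} when
#' the restricted clade is incompatible with the input tree (no refinement
#' of the input tree contains it); otherwise it \emph{permits} the clade
#' (compatible but not displayed, e.g. across a polytomy).
#'
#' @param input_tree rooted \code{phylo}.
#' @param clade character vector of supertree clade members.
#' @param full_taxa full supertree taxon set (the clade must be a proper
#'   subset).
#' @return one of \code{"supports"}, \code{"conflicts"}, \code{"permits"},
#'   \code{"irrelevant"}.
#' @export
classify_tree_vs_clade <- function(input_tree, clade, full_taxa) {
  stopifnot(all(clade %in% full_taxa), length(clade) < length(full_taxa))
  leaves <- input_tree$tip.label
  r <- intersect(clade, leaves)
  if (length(r) < 2L || length(setdiff(leaves, r)) < 1L) return("irrelevant")
  clusters <- tree_clusters(input_tree, include_root = FALSE)
  if (cluster_key(r) %in% names(clusters)) return("supports")
  compat <- all(vapply(clusters, sets_compatible, TRUE, b = r))
  if (compat) "permits" else "conflicts"
}

#' V and V+ nodal support for a supertree
#'
#' Scores every non-root supertree clade against the input tree set. For a
#' clade with s supporting, q conflicting and perm permitting input trees,
#' V = (s - q)/(s + q), running from -1 (all relevant trees conflict) to +1
#' (all support); V is undefined (NA, excluded from the tree mean) when
#' s + q = 0. V+ additionally credits permitting trees as supporting:
#' V+ = (s + perm - q)/(s + perm + q). Tree-level scores are unweighted
#' means over nodes.
#'
#' @param supertree a [majority_rule_plus()] consensus, or a rooted
#'   \code{phylo}.
#' @param trees a \code{"treeset"} of standardized input trees.
#' @return an object of class \code{"support_report"}: list with
#'   \code{per_node} (data frame: clade, s, q, perm, irrelevant, V,
#'   V_plus), \code{tree_V}, \code{tree_V_plus}.
#' @export
v_scores <- function(supertree, trees) {
  tree <- if (inherits(supertree, "consensus_tree")) supertree$tree
          else supertree
  full <- sort(tree$tip.label)
  clades <- tree_clusters(tree, include_root = FALSE)
  n_in <- length(trees$trees)
  rows <- lapply(clades, function(cl) {
    cls <- vapply(trees$trees, classify_tree_vs_clade, "",
                  clade = cl, full_taxa = full)
    s <- sum(cls == "supports")
    q <- sum(cls == "conflicts")
    perm <- sum(cls == "permits")
    irr <- sum(cls == "irrelevant")
    data.frame(
      clade = cluster_key(cl),
      s = s, q = q, perm = perm, irrelevant = irr,
      V = if (s + q > 0) (s - q) / (s + q) else NA_real_,
      V_plus = if (s + perm + q > 0) (s + perm - q) / (s + perm + q)
               else NA_real_,
      stringsAsFactors = FALSE)
  })
  per_node <- do.call(rbind, rows)
  rownames(per_node) <- NULL
  stopifnot(all(per_node$s + per_node$q + per_node$perm +
                  per_node$irrelevant == n_in))
  structure(list(per_node = per_node,
                 tree_V = mean(per_node$V, na.rm = TRUE),
                 tree_V_plus = mean(per_node$V_plus, na.rm = TRUE),
                 n_input_trees = n_in),
            class = "support_report")
}

#' @export
print.support_report <- function(x, ...) {
  cat(sprintf(
    "Support over %d input trees: tree V = %+.3f, tree V+ = %+.3f (%d nodes)\n",
    x$n_input_trees, x$tree_V, x$tree_V_plus, nrow(x$per_node)))
  invisible(x)
}

#' Write a support table
#'
#' Delimited text with one row per supertree clade: members, s, q, perm,
#' V, V+.
#'
#' @param report a [v_scores()] report.
#' @param path output file.
#' @export
write_support_table <- function(report, path) {
  utils::write.table(report$per_node, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Annotate a consensus tree with V scores as node labels
#'
#' @param consensus a [majority_rule_plus()] consensus.
#' @param report the matching [v_scores()] report.
#' @param path output newick file.
#' @export
write_v_annotated_newick <- function(consensus, report, path) {
  tree <- consensus$tree
  ntip <- length(tree$tip.label)
  desc <- node_tipsets(tree)
  v <- stats::setNames(report$per_node$V, report$per_node$clade)
  lab <- character(tree$Nnode)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    k <- cluster_key(tree$tip.label[desc[[nd]]])
    lab[nd - ntip] <- if (k %in% names(v) && !is.na(v[[k]]))
      format(round(v[[k]], 3)) else ""
  }
  tree$node.label <- lab
  writeLines(ape::write.tree(tree), path)
  invisible(path)
}
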