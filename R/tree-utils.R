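# Internal tree machinery shared by the supertree search, consensus and
# support scoring. Two representations are used:
#   * ape "phylo" objects at every public interface;
#   * a recursive nested-list form ("nl": a tip is a character scalar, an
#     internal node a list of >= 2 children) inside the search, where
#     prune/regraft surgery is simpler and cheaper than edge-matrix editing.

# ---- phylo helpers ---------------------------------------------------------

tree_root <- function(tree) {
  ntip <- length(tree$tip.label)
  unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])[1]
}

node_children <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

# tip indices under every node (tips included), postorder accumulation
node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]
    desc[[p]] <- c(desc[[p]], desc[[tr$edge[k, 2]]])
  }
  desc
}

# character-label clusters (leaf sets) of all internal nodes; names are
# canonical keys ("A|B|C", members sorted)
tree_clusters <- function(tree, include_root = TRUE) {
  ntip <- length(tree$tip.label)
  desc <- node_tipsets(tree)
  root <- tree_root(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  if (!include_root) nodes <- setdiff(nodes, root)
  out <- lapply(nodes, function(v) sort(tree$tip.label[desc[[v]]]))
  names(out) <- vapply(out, paste, "", collapse = "|")
  out
}

cluster_key <- function(members) paste(sort(members), collapse = "|")

# two clades (character vectors) are hierarchy-compatible iff nested/disjoint
sets_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

# ---- nested-list representation -------------------------------------------

phylo_to_nl <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- node_children(tree)
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    lapply(kids[[v]], rec)
  }
  rec(tree_root(tree))
}

nl_to_newick <- function(x) {
  if (is.character(x)) return(x)
  paste0("(", paste(vapply(x, nl_to_newick, ""), collapse = ","), ")")
}

nl_to_phylo <- function(x) {
  ape::read.tree(text = paste0(nl_to_newick(x), ";"))
}

# canonical newick: children ordered by their own canonical strings, so two
# topologically identical trees produce identical strings
nl_canonical <- function(x) {
  if (is.character(x)) return(x)
  paste0("(", paste(sort(vapply(x, nl_canonical, "")), collapse = ","), ")")
}

canonical_newick <- function(tree) {
  paste0(nl_canonical(phylo_to_nl(tree)), ";")
}

nl_tips <- function(x) {
  if (is.character(x)) return(x)
  unlist(lapply(x, nl_tips), use.names = FALSE)
}

# all proper subtree addresses (integer paths from the root); the root itself
# (empty path) is excluded
nl_addresses <- function(x) {
  out <- list()
  rec <- function(node, path) {
    if (length(path) > 0L) out[[length(out) + 1L]] <<- path
    if (!is.character(node)) {
      for (i in seq_along(node)) rec(node[[i]], c(path, i))
    }
  }
  rec(x, integer())
  out
}

nl_at <- function(x, path) {
  for (i in path) x <- x[[i]]
  x
}

# drop the subtree at `path`, promoting its sibling (binary nodes assumed)
nl_remove <- function(x, path) {
  if (length(path) == 1L) return(x[[3L - path[1L]]])
  x[[path[1L]]] <- nl_remove(x[[path[1L]]], path[-1L])
  x
}

# replace the node at `path` by (node, s); empty path grafts above the root
nl_insert <- function(x, path, s) {
  if (length(path) == 0L) return(list(x, s))
  if (length(path) == 1L) {
    x[[path[1L]]] <- list(x[[path[1L]]], s)
    return(x)
  }
  x[[path[1L]]] <- nl_insert(x[[path[1L]]], path[-1L], s)
  x
}

# rooted NNI neighbourhood: for every internal edge (u,v), swap one child of
# v with v's sibling; 2 neighbours per internal edge
nl_nni_neighbors <- function(x) {
  out <- list()
  rec <- function(node, path) {
    if (is.character(node)) return()
    for (i in seq_along(node)) {
      child <- node[[i]]
      if (!is.character(child)) {
        sib <- node[[3L - i]]
        for (j in 1:2) {
          n2 <- node
          n2[[3L - i]] <- child[[j]]
          ch2 <- child
          ch2[[j]] <- sib
          n2[[i]] <- ch2
          out[[length(out) + 1L]] <<- nl_replace(x, path, n2)
        }
      }
      rec(child, c(path, i))
    }
  }
  rec(x, integer())
  out
}

nl_replace <- function(x, path, value) {
  if (length(path) == 0L) return(value)
  x[[path[1L]]] <- nl_replace(x[[path[1L]]], path[-1L], value)
  x
}

# rooted SPR neighbourhood: prune every proper subtree and regraft on every
# edge of the backbone (including above the backbone root)
nl_spr_neighbors <- function(x) {
  out <- list()
  for (path in nl_addresses(x)) {
    s <- nl_at(x, path)
    backbone <- nl_remove(x, path)
    if (is.character(backbone) && is.character(s)) next
    regrow <- c(list(integer()), nl_addresses(backbone))
    for (rp in regrow) {
      out[[length(out) + 1L]] <- nl_insert(backbone, rp, s)
    }
  }
  out
}

# k uniformly chosen NNI moves (used by the synthetic input-tree generator);
# draws from the R RNG stream
nl_random_nni <- function(x, k) {
  for (i in seq_len(k)) {
    nb <- nl_nni_neighbors(x)
    if (length(nb) == 0L) break
    x <- nb[[sample.int(length(nb), 1L)]]
  }
  x
}

# ---- building a rooted tree from a compatible clade set --------------------

# tips: character vector; clades: list of character vectors, pairwise
# compatible, all proper non-singleton subsets of tips. Returns nested-list
# tree (polytomies allowed).
nl_from_clades <- function(tips, clades) {
  build <- function(members, sub) {
    if (length(members) == 1L) return(members)
    # maximal clades strictly inside `members`
    inside <- sub[vapply(sub, function(cl)
      length(cl) < length(members) && all(cl %in% members), TRUE)]
    used <- character()
    kids <- list()
    if (length(inside) > 0L) {
      ord <- order(-vapply(inside, length, 1L))
      for (cl in inside[ord]) {
        if (!any(cl %in% used)) {
          kids[[length(kids) + 1L]] <-
            build(cl, inside[vapply(inside, function(z) all(z %in% cl), TRUE)])
          used <- c(used, cl)
        }
      }
    }
    for (t in setdiff(members, used)) kids[[length(kids) + 1L]] <- t
    if (length(kids) == 1L) return(kids[[1L]])
    kids
  }
  build(sort(tips), clades)
}
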