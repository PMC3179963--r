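#' Encode a tree set as a binary matrix (Baum-Ragan coding)
#'
#' Every non-root internal node of every input tree becomes one binary
#' column: descendants of the node are 1, the remaining taxa of that tree
#' are 0, taxa absent from the tree are missing. A hypothetical all-zero
#' outgroup row is appended to columns from trees that do not contain the
#' outgroup, implementing the convention that the outgroup is sister to
#' everything else; trees that do contain it score it like any other
#' taxon.
#'
#' @param trees a \code{"treeset"} of standardized trees.
#' @param outgroup label of the outgroup family.
#' @return an object of class \code{"mrp_matrix"}: list with \code{taxa}
#'   (ordered labels, outgroup first), \code{mat} (taxa x columns integer
#'   matrix of 0/1/\code{NA}), \code{source} (source tree id per column) and
#'   an \code{outgroup} field.
#' @export
mrp_encode <- function(trees, outgroup) {
  taxa <- sort(unique(c(outgroup, trees$leaf_union)))
  taxa <- c(outgroup, setdiff(taxa, outgroup))
  cols <- list()
  src <- character()
  for (tr in trees$trees) {
    id <- attr(tr, "source_id") %||% "?"
    ntip <- length(tr$tip.label)
    root <- tree_root(tr)
    desc <- node_tipsets(tr)
    for (v in (ntip + 1L):(ntip + tr$Nnode)) {
      if (v == root) next
      members <- tr$tip.label[desc[[v]]]
      col <- rep(NA_integer_, length(taxa))
      names(col) <- taxa
      col[tr$tip.label] <- 0L
      col[members] <- 1L
      # hypothetical all-zero outgroup, appended to trees lacking it
      if (!outgroup %in% tr$tip.label) col[outgroup] <- 0L
      cols[[length(cols) + 1L]] <- col
      src <- c(src, id)
    }
  }
  mat <- if (length(cols) > 0) do.call(cbind, cols) else
    matrix(integer(), nrow = length(taxa), ncol = 0,
           dimnames = list(taxa, NULL))
  rownames(mat) <- taxa
  structure(list(taxa = taxa, mat = mat, source = src, outgroup = outgroup),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("MRP/MRC matrix:", length(x$taxa), "taxa x", ncol(x$mat),
      "columns from", length(unique(x$source)), "source trees; outgroup",
      x$outgroup, "\n")
  invisible(x)
}

# taxa x col matrix of state bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1} (missing)
matrix_codes <- function(matrix) {
  m <- matrix$mat
  codes <- m + 1L
  codes[is.na(codes)] <- 3L
  codes
}

# vectorised two-state Fitch over all columns on a nested-list tree;
# missing entries carry the full state set and so never add steps
fitch_nl <- function(x, codes) {
  if (is.character(x)) return(list(S = codes[x, ], st = 0L))
  a <- fitch_nl(x[[1L]], codes)
  b <- fitch_nl(x[[2L]], codes)
  s <- bitwAnd(a$S, b$S)
  z <- s == 0L
  if (any(z)) s[z] <- bitwOr(a$S[z], b$S[z])
  list(S = s, st = a$st + b$st + sum(z))
}

#' Parsimony length of a tree on an encoded matrix
#'
#' Sum over columns of the minimum number of binary state changes (Fitch
#' counting, missing entries treated as the full state set).
#'
#' @param tree rooted bifurcating \code{phylo} whose leaves include every
#'   taxon of the matrix.
#' @param matrix an [mrp_encode()] matrix.
#' @return integer parsimony length; lower is better.
#' @export
parsimony_length <- function(tree, matrix) {
  check_tree_covers(tree, matrix)
  if (!ape::is.binary(tree))
    stop("parsimony_length requires a bifurcating tree")
  codes <- matrix_codes(matrix)
  if (ncol(codes) == 0L) return(0L)
  fitch_nl(phylo_to_nl(tree), codes)$st
}

check_tree_covers <- function(tree, matrix) {
  miss <- setdiff(matrix$taxa, tree$tip.label)
  if (length(miss) > 0)
    stop("taxa in matrix absent from tree: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# per-column logical: do the 1-taxa form a clade of `x` restricted to the
# column's non-missing taxa?
compat_cols_nl <- function(x, codes) {
  ones_m <- codes == 2L
  rel_m <- codes != 3L
  tot1 <- colSums(ones_m)
  nc <- ncol(codes)
  ok <- logical(nc)
  rec <- function(node) {
    if (is.character(node)) {
      return(list(n1 = as.integer(ones_m[node, ]),
                  n0 = as.integer(rel_m[node, ] & !ones_m[node, ])))
    }
    acc <- rec(node[[1L]])
    for (i in seq_along(node)[-1L]) {
      b <- rec(node[[i]])
      acc$n1 <- acc$n1 + b$n1
      acc$n0 <- acc$n0 + b$n0
    }
    ok <<- ok | (acc$n1 == tot1 & acc$n0 == 0L)
    acc
  }
  rec(x)
  ok
}

#' Compatibility count of a tree on an encoded matrix
#'
#' Number of columns whose 1-taxa form a clade of the tree restricted to
#' that column's non-missing taxa.
#'
#' @inheritParams parsimony_length
#' @return integer count; higher is better.
#' @export
compatibility_count <- function(tree, matrix) {
  check_tree_covers(tree, matrix)
  codes <- matrix_codes(matrix)
  if (ncol(codes) == 0L) return(0L)
  sum(compat_cols_nl(phylo_to_nl(tree), codes))
}

# score an ingroup nested list (outgroup attached at the root) under a
# criterion; larger is always better internally
make_scorer <- function(matrix, criterion) {
  codes <- matrix_codes(matrix)
  og <- matrix$outgroup
  if (criterion == "mrp") {
    function(nl) -fitch_nl(list(og, nl), codes)$st
  } else {
    function(nl) sum(compat_cols_nl(list(og, nl), codes))
  }
}

#' Search for optimal supertrees
#'
#' Hill-climbing over NNI and SPR neighbourhoods from random-addition
#' starting trees, under parsimony (MRP, minimise length) or compatibility
#' (MRC, maximise compatible columns). The outgroup is constrained as
#' sister to all other taxa; rearrangements act on the ingroup subtree. All
#' distinct best-scoring topologies encountered anywhere in the search are
#' retained (capped at \code{max_optimal}). Deterministic given
#' \code{seed}.
#'
#' @param matrix an [mrp_encode()] matrix.
#' @param criterion \code{"mrp"} or \code{"mrc"}.
#' @param restarts number of random-addition starts (>= 1).
#' @param seed integer seed controlling addition orders.
#' @param max_optimal cap on the number of equally optimal trees kept.
#' @return an object of class \code{"search_result"}: list with
#'   \code{optimal_trees} (a \code{multiPhylo} of rooted bifurcating trees
#'   on the full taxon set), \code{score} (parsimony length for MRP,
#'   compatible-column count for MRC), \code{criterion}, \code{seed},
#'   \code{restarts}.
#' @export
supertree_search <- function(matrix, criterion = c("mrp", "mrc"),
                             restarts = 10, seed = 1, max_optimal = 1000) {
  criterion <- match.arg(criterion)
  stopifnot(restarts >= 1)
  og <- matrix$outgroup
  ingroup <- setdiff(matrix$taxa, og)
  if (length(ingroup) < 3)
    stop("need at least 3 ingroup taxa to search")
  scorer <- make_scorer(matrix, criterion)

  best <- new.env(parent = emptyenv())
  best$score <- -Inf
  best$set <- list()
  best$keys <- character()
  best$capped <- FALSE
  consider <- function(nl, sc) {
    if (sc > best$score) {
      best$score <- sc
      best$set <- list()
      best$keys <- character()
      best$capped <- FALSE
    }
    if (sc == best$score) {
      k <- nl_canonical(nl)
      if (!k %in% best$keys) {
        if (length(best$set) < max_optimal) {
          best$set[[length(best$set) + 1L]] <- nl
          best$keys <- c(best$keys, k)
        } else if (!best$capped) {
          best$capped <- TRUE
          message("equally optimal tree cap (", max_optimal, ") reached")
        }
      }
    }
    sc
  }

  set.seed(seed)
  for (r in seq_len(restarts)) {
    ord <- sample(ingroup)
    cur <- list(list(ord[1L], ord[2L]), ord[3L])
    for (tx in ord[-(1:3)]) {
      spots <- c(list(integer()), nl_addresses(cur))
      cand <- lapply(spots, function(p) nl_insert(cur, p, tx))
      scs <- vapply(cand, scorer, 0)
      cur <- cand[[which.max(scs)]]
    }
    cur_sc <- consider(cur, scorer(cur))
    repeat {
      moved <- FALSE
      for (nbf in list(nl_nni_neighbors, nl_spr_neighbors)) {
        nb <- nbf(cur)
        if (length(nb) == 0L) next
        scs <- vapply(nb, scorer, 0)
        for (i in seq_along(nb)) consider(nb[[i]], scs[i])
        if (max(scs) > cur_sc) {
          cur <- nb[[which.max(scs)]]
          cur_sc <- max(scs)
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
  }

  trees <- lapply(best$set, function(nl) nl_to_phylo(list(og, nl)))
  class(trees) <- "multiPhylo"
  score <- if (criterion == "mrp") -best$score else best$score
  structure(list(optimal_trees = trees, score = score,
                 criterion = toupper(criterion), seed = seed,
                 restarts = restarts, capped = best$capped),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(x$criterion, "search:", length(x$optimal_trees),
      "equally optimal trees, score", x$score,
      sprintf("(%d restarts, seed %d)\n", x$restarts, x$seed))
  invisible(x)
}

#' Majority-rule consensus with minority components
#'
#' Clades occurring in more than half of the equally optimal trees are
#' included; remaining resolution is added greedily in decreasing frequency
#' order, skipping clades incompatible with those already accepted, so that
#' below 50\% the relationship appearing more times than any other is
#' taken. Frequency ties break lexicographically on the sorted clade
#' labels. Any polytomies that survive (no frequency > 0 clade resolves
#' them) are resolved by a seeded random resolution, because downstream
#' diversification analysis needs a fully bifurcating tree.
#'
#' @param result a [supertree_search()] result.
#' @param seed seed for the residual polytomy resolution; defaults to the
#'   search seed.
#' @return an object of class \code{"consensus_tree"}: list with
#'   \code{tree} (rooted bifurcating \code{phylo}), \code{clade_freq}
#'   (named numeric, fraction of optimal trees containing each included
#'   clade; clades introduced by random resolution score 0) and
#'   \code{n_optimal}.
#' @export
majority_rule_plus <- function(result, seed = result$seed) {
  trees <- result$optimal_trees
  if (length(trees) == 0L) stop("empty set of optimal trees")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(leafsets, paste, "", collapse = "|"))) != 1L)
    stop("optimal trees are on differing leaf sets")
  taxa <- leafsets[[1L]]
  n <- length(trees)

  counts <- new.env(parent = emptyenv())
  for (t in trees) {
    cl <- tree_clusters(t, include_root = FALSE)
    for (k in names(cl)) {
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  keys <- keys[vapply(keys, function(k)
    length(strsplit(k, "|", fixed = TRUE)[[1L]]) < length(taxa), TRUE)]
  freq <- vapply(keys, function(k) counts[[k]] / n, 0)
  ord <- order(-freq, keys)
  keys <- keys[ord]
  freq <- freq[ord]

  accepted <- list()
  acc_freq <- numeric()
  for (i in seq_along(keys)) {
    cl <- strsplit(keys[i], "|", fixed = TRUE)[[1L]]
    if (all(vapply(accepted, sets_compatible, TRUE, b = cl))) {
      accepted[[length(accepted) + 1L]] <- cl
      acc_freq <- c(acc_freq, freq[i])
      names(acc_freq)[length(acc_freq)] <- keys[i]
    }
  }

  nl <- nl_from_clades(taxa, accepted)
  tree <- nl_to_phylo(nl)
  if (!ape::is.binary(tree)) {
    set.seed(seed %||% 0L)
    pre <- names(acc_freq)
    tree <- ape::multi2di(tree, random = TRUE)
    added <- setdiff(names(tree_clusters(tree, include_root = FALSE)), pre)
    added <- setdiff(added, vapply(as.list(taxa), identity, ""))
    extra <- stats::setNames(rep(0, length(added)), added)
    acc_freq <- c(acc_freq, extra)
  }
  structure(list(tree = tree, clade_freq = acc_freq, n_optimal = n,
                 criterion = result$criterion),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("Majority-rule (+minority) consensus of", x$n_optimal,
      x$criterion, "trees;", length(x$tree$tip.label), "taxa\n")
  invisible(x)
}

#' Write an encoded matrix as a NEXUS DATA block
#'
#' @param matrix an [mrp_encode()] matrix.
#' @param path output file.
#' @export
write_nexus_matrix <- function(matrix, path) {
  m <- matrix$mat
  rows <- apply(m, 1, function(z) {
    z <- as.character(z)
    z[is.na(z)] <- "?"
    paste(z, collapse = "")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    "  FORMAT SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX"), con)
  writeLines(sprintf("    %s %s", format(rownames(m)), rows), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Write consensus (or any) trees with clade frequencies as node labels
#'
#' @param consensus a [majority_rule_plus()] consensus.
#' @param path output file.
#' @export
write_consensus_newick <- function(consensus, path) {
  tree <- consensus$tree
  ntip <- length(tree$tip.label)
  cl <- tree_clusters(tree, include_root = TRUE)
  desc <- node_tipsets(tree)
  lab <- character(tree$Nnode)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    k <- cluster_key(tree$tip.label[desc[[v]]])
    f <- consensus$clade_freq[k]
    lab[v - ntip] <- if (is.na(f)) "" else format(round(f, 3))
  }
  tree$node.label <- lab
  writeLines(ape::write.tree(tree), path)
  invisible(path)
}
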