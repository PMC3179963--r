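# fixtures built in code: small trees, tree sets and matrices used across
# the module tests

tre <- function(txt, id = "t#1") {
  tr <- ape::read.tree(text = txt)
  attr(tr, "source_id") <- id
  tr
}

tset <- function(...) treeset(list(...))

# a random rooted bifurcating topology (no branch lengths)
rtopo <- function(n, labels = paste0("T", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = sample(labels, n))
  tr$edge.length <- NULL
  tr
}

# exhaustive best score over all rooted bifurcating trees on the matrix's
# ingroup taxa with the outgroup attached at the root (oracle for the
# heuristic search; feasible for <= 6 taxa)
exhaustive_best <- function(m, criterion) {
  ingroup <- setdiff(m$taxa, m$outgroup)
  all_tr <- phangorn::allTrees(length(ingroup), rooted = TRUE,
                               tip.label = ingroup)
  scores <- vapply(all_tr, function(t) {
    full <- ape::read.tree(text = sub(";",
      paste0(",", m$outgroup, ");"),
      sub("^\\(", "((", ape::write.tree(t))))
    if (criterion == "mrp") parsimony_length(full, m)
    else compatibility_count(full, m)
  }, 0)
  best <- if (criterion == "mrp") min(scores) else max(scores)
  list(score = best, n_best = sum(scores == best))
}

# equally spaced synthetic richness series (oldest first)
eq_series <- function(time_ma, richness, source = "synthetic") {
  structure(data.frame(time_ma = time_ma, richness = richness),
            source = source, class = c("richness_series", "data.frame"))
}

cluster_key_of <- function(x) paste(sort(x), collapse = "|")
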