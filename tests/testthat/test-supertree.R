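test_that("Baum-Ragan encoding produces one column per non-root internal node", {
  m <- mrp_encode(tset(tre("((A,B),(C,D));")), "OG")
  expect_equal(ncol(m$mat), 2)
  keys <- apply(m$mat, 2, function(z) paste(rownames(m$mat)[z == 1 & !is.na(z)],
                                            collapse = "|"))
  expect_setequal(keys, c("A|B", "C|D"))
  expect_true(all(m$mat["OG", ] == 0))

  # star tree: no non-root internal node, no columns
  m0 <- mrp_encode(tset(tre("(A,B,C);", id = "star")), "OG")
  expect_equal(ncol(m0$mat), 0)
})

test_that("taxa absent from a source tree are missing, then outgroup-coded 0", {
  m <- mrp_encode(tset(tre("((A,B),(C,D));", "s#1"),
                       tre("((A,B),C);", "s#2")), "OG")
  from2 <- which(m$source == "s#2")
  expect_length(from2, 1)
  col <- m$mat[, from2]
  expect_true(is.na(col[["D"]]))
  expect_equal(col[["OG"]], 0)
  expect_equal(col[["A"]], 1)
  # matrix invariant: every column informative, source trees fully scored
  expect_true(all(colSums(m$mat == 1, na.rm = TRUE) >= 1))
  expect_true(all(colSums(m$mat == 0, na.rm = TRUE) >= 1))
})

test_that("parsimony length matches hand values and the phangorn oracle", {
  m <- mrp_encode(tset(tre("((A,B),(C,D));")), "OG")
  expect_equal(parsimony_length(tre("(OG,((A,B),(C,D)));"), m), 2)
  expect_equal(parsimony_length(tre("(OG,((A,C),(B,D)));"), m), 4)

  # dual-route check on random matrices with missing data
  set.seed(7)
  for (i in 1:10) {
    src <- lapply(1:3, function(j) {
      tr <- rtopo(sample(4:6, 1), labels = sample(LETTERS[1:7]))
      attr(tr, "source_id") <- paste0("r#", j)
      tr
    })
    m <- mrp_encode(treeset(src), "OG")
    tr <- rtopo(length(m$taxa), labels = m$taxa)
    chr <- matrix(as.character(m$mat), nrow = nrow(m$mat),
                  dimnames = dimnames(m$mat))
    chr[is.na(chr)] <- "?"
    pd <- phangorn::phyDat(chr, type = "USER", levels = c("0", "1"),
                           ambiguity = "?")
    expect_equal(parsimony_length(tr, m),
                 as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("compatibility counts columns whose 1-set is a restricted clade", {
  m <- mrp_encode(tset(tre("((A,B),(C,D));")), "OG")
  expect_equal(compatibility_count(tre("(OG,((A,B),(C,D)));"), m), 2)
  expect_equal(compatibility_count(tre("(OG,((A,C),(B,D)));"), m), 0)
})

test_that("perfect-fit identity and score bounds hold on random trees", {
  set.seed(31)
  for (i in 1:10) {
    tr <- rtopo(6, labels = c(LETTERS[1:5], "OG"))
    attr(tr, "source_id") <- "self"
    m <- mrp_encode(treeset(list(tr)), "OG")
    expect_equal(parsimony_length(tr, m), ncol(m$mat))
    expect_equal(compatibility_count(tr, m), ncol(m$mat))
    other <- rtopo(6, labels = c(LETTERS[1:5], "OG"))
    expect_gte(parsimony_length(other, m), ncol(m$mat))
    expect_lte(compatibility_count(other, m), ncol(m$mat))
  }
})

test_that("search recovers a single input tree with a perfect score", {
  tr <- tre("((A,(B,C)),(D,E));")
  m <- mrp_encode(tset(tr), "OG")
  for (crit in c("mrp", "mrc")) {
    res <- supertree_search(m, crit, restarts = 5, seed = 2)
    expect_equal(res$score, ncol(m$mat))
    keys <- vapply(res$optimal_trees, macrophy:::canonical_newick, "")
    target <- macrophy:::canonical_newick(tre("(OG,((A,(B,C)),(D,E)));"))
    expect_true(target %in% keys)
  }
})

test_that("conflicting input trees yield multiple equally optimal trees", {
  m <- mrp_encode(tset(tre("((A,B),(C,D));", "x#1"),
                       tre("((A,C),(B,D));", "x#2")), "OG")
  res <- supertree_search(m, "mrp", restarts = 10, seed = 5)
  expect_gte(length(res$optimal_trees), 2)
})

test_that("search is deterministic given matrix, criterion, restarts, seed", {
  m <- mrp_encode(tset(tre("((A,B),(C,(D,E)));", "x#1"),
                       tre("(((A,C),B),(D,E));", "x#2")), "OG")
  r1 <- supertree_search(m, "mrp", restarts = 6, seed = 11)
  r2 <- supertree_search(m, "mrp", restarts = 6, seed = 11)
  expect_equal(r1$score, r2$score)
  expect_equal(sort(vapply(r1$optimal_trees, macrophy:::canonical_newick, "")),
               sort(vapply(r2$optimal_trees, macrophy:::canonical_newick, "")))
  c1 <- majority_rule_plus(r1)
  c2 <- majority_rule_plus(r2)
  expect_equal(macrophy:::canonical_newick(c1$tree),
               macrophy:::canonical_newick(c2$tree))
})

test_that("heuristic search matches exhaustive enumeration on small taxon sets", {
  set.seed(13)
  for (i in 1:3) {
    src <- lapply(1:2, function(j) {
      tr <- rtopo(4, labels = sample(LETTERS[1:5], 4))
      attr(tr, "source_id") <- paste0("e#", j)
      tr
    })
    m <- mrp_encode(treeset(src), "OG")
    for (crit in c("mrp", "mrc")) {
      res <- supertree_search(m, crit, restarts = 10, seed = i)
      oracle <- exhaustive_best(m, crit)
      expect_equal(res$score, oracle$score)
      expect_equal(length(res$optimal_trees), oracle$n_best)
    }
  }
})

test_that("consensus of one tree is that tree with all frequencies 1", {
  m <- mrp_encode(tset(tre("((A,(B,C)),(D,E));")), "OG")
  res <- supertree_search(m, "mrp", restarts = 3, seed = 1)
  res$optimal_trees <- res$optimal_trees[1]
  cons <- majority_rule_plus(res)
  expect_equal(macrophy:::canonical_newick(cons$tree),
               macrophy:::canonical_newick(res$optimal_trees[[1]]))
  expect_true(all(cons$clade_freq == 1))
})

test_that("majority clades enter by frequency; ties break lexicographically", {
  trees <- list(tre("(((A,B),C),D);"), tre("(((A,B),D),C);"),
                tre("(((A,C),B),D);"))
  fake <- structure(list(optimal_trees = structure(trees,
                                                  class = "multiPhylo"),
                         score = 0, criterion = "MRP", seed = 1,
                         restarts = 1), class = "search_result")
  cons <- majority_rule_plus(fake)
  expect_equal(unname(cons$clade_freq[["A|B"]]), 2 / 3)
  # among the 1/3-frequency clades compatible with {A,B}, A|B|C precedes
  # A|B|D lexicographically and is taken
  expect_true("A|B|C" %in% names(cons$clade_freq))
  expect_false("A|B|D" %in% names(cons$clade_freq))
  expect_true(ape::is.binary(cons$tree))
})

test_that("consensus contains every clade common to all optimal trees", {
  set.seed(23)
  m <- mrp_encode(tset(tre("((A,B),(C,(D,E)));", "x#1"),
                       tre("(((A,C),B),(D,E));", "x#2"),
                       tre("((A,B),((C,D),E));", "x#3")), "OG")
  res <- supertree_search(m, "mrp", restarts = 8, seed = 3)
  cons <- majority_rule_plus(res)
  common <- Reduce(intersect,
                   lapply(res$optimal_trees,
                          function(t) names(macrophy:::tree_clusters(t, FALSE))))
  expect_true(all(common %in% names(macrophy:::tree_clusters(cons$tree, TRUE))))
  expect_true(ape::is.binary(cons$tree))
  expect_error(majority_rule_plus(structure(list(optimal_trees = list()),
                                            class = "search_result")),
               "empty")
})

test_that("matrix round-trips through the NEXUS writer", {
  m <- mrp_encode(tset(tre("((A,B),(C,D));", "s#1"),
                       tre("((A,B),C);", "s#2")), "OG")
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(m, f)
  txt <- readLines(f)
  expect_true(any(grepl("NTAX=5 NCHAR=3", txt)))
  expect_true(any(grepl("\\?", txt)))   # missing D encoded as ?
})
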