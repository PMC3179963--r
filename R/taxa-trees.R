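#' Read a taxonomy table
#'
#' Reads a delimited text file mapping tip names used in published trees to
#' valid family names. The table has three columns: \code{name},
#' \code{valid_family} and \code{status} (one of \code{valid},
#' \code{synonym}, \code{member_genus}); rows with status \code{valid} must
#' have \code{name == valid_family}. The supertree outgroup is a fourth
#' ingredient, supplied either as an \code{outgroup} argument or as a line
#' \code{#outgroup: <family>} at the top of the file.
#'
#' @param path path to a tab- or comma-delimited file.
#' @param outgroup valid family name to use as the supertree outgroup;
#'   overrides any \code{#outgroup:} header line.
#' @return an object of class \code{"taxonomy"}: a data frame with columns
#'   \code{name}, \code{valid_family}, \code{status} and an
#'   \code{"outgroup"} attribute.
#' @seealso [taxonomy()], [apply_taxonomy()]
#' @export
read_taxonomy <- function(path, outgroup = NULL) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  og_line <- grep("^#\\s*outgroup:", lines, value = TRUE)
  if (is.null(outgroup) && length(og_line) > 0) {
    outgroup <- trimws(sub("^#\\s*outgroup:", "", og_line[1]))
  }
  lines <- lines[!grepl("^#", lines)]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  taxonomy(df, outgroup = outgroup)
}

#' Construct and validate a taxonomy
#'
#' @param entries data frame with columns \code{name}, \code{valid_family},
#'   \code{status}.
#' @param outgroup a valid family name.
#' @return a validated \code{"taxonomy"} object.
#' @export
taxonomy <- function(entries, outgroup) {
  need <- c("name", "valid_family", "status")
  if (!all(need %in% names(entries)))
    stop("taxonomy needs columns: ", paste(need, collapse = ", "))
  entries <- entries[need]
  bad_status <- setdiff(unique(entries$status),
                        c("valid", "synonym", "member_genus"))
  if (length(bad_status) > 0)
    stop("unknown taxonomy status: ", paste(bad_status, collapse = ", "))
  fam_per_name <- tapply(entries$valid_family, entries$name,
                         function(z) length(unique(z)))
  conflicting <- names(fam_per_name)[fam_per_name > 1]
  if (length(conflicting) > 0)
    stop("name mapped to two different valid families: ",
         paste(conflicting, collapse = ", "))
  valid <- unique(entries$valid_family[entries$status == "valid"])
  if (anyDuplicated(entries$valid_family[entries$status == "valid"]))
    stop("duplicated valid family rows")
  if (is.null(outgroup) || !outgroup %in% valid)
    stop("outgroup must be one of the valid families")
  structure(entries, outgroup = outgroup, class = c("taxonomy", "data.frame"))
}

#' Read input trees from newick or NEXUS files
#'
#' Parses one or more files of rooted input trees. Unrooted trees are
#' rejected: the downstream matrix encoding interprets every internal node
#' as a rooted clade. Each tree is assigned a source id
#' \code{<file>#<index>} kept through the pipeline.
#'
#' @param paths character vector of file paths.
#' @param format \code{"newick"} (one or more \code{;}-terminated trees) or
#'   \code{"nexus"} (a TREES block).
#' @return an object of class \code{"treeset"}: a list with elements
#'   \code{trees} (list of \code{phylo}, each carrying a \code{source_id}
#'   attribute) and \code{leaf_union}.
#' @export
parse_trees <- function(paths, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("tree file not found: ", p)
    got <- tryCatch(
      if (format == "newick") ape::read.tree(p) else ape::read.nexus(p),
      error = function(e) stop("parse error in ", p, ": ",
                               conditionMessage(e), call. = FALSE),
      warning = function(w) stop("parse error in ", p, ": ",
                                 conditionMessage(w), call. = FALSE))
    if (is.null(got)) stop("parse error in ", p, ": no trees read")
    if (inherits(got, "phylo")) got <- list(got)
    for (i in seq_along(got)) {
      tr <- got[[i]]
      id <- paste0(basename(p), "#", i)
      if (!ape::is.rooted(tr))
        stop("unrooted tree rejected: ", id)
      if (anyDuplicated(tr$tip.label))
        stop("duplicate leaf labels within tree ", id)
      attr(tr, "source_id") <- id
      trees[[length(trees) + 1L]] <- tr
    }
  }
  treeset(trees)
}

#' Bundle trees into a tree set
#'
#' @param trees list of rooted \code{phylo} objects (optionally carrying
#'   \code{source_id} attributes).
#' @return a \code{"treeset"} object.
#' @export
treeset <- function(trees) {
  for (i in seq_along(trees)) {
    if (is.null(attr(trees[[i]], "source_id")))
      attr(trees[[i]], "source_id") <- paste0("tree#", i)
  }
  structure(list(
    trees = trees,
    leaf_union = sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  ), class = "treeset")
}

#' @export
print.treeset <- function(x, ...) {
  cat("Tree set:", length(x$trees), "trees,",
      length(x$leaf_union), "distinct leaves\n")
  invisible(x)
}

#' Standardize leaf names against a taxonomy
#'
#' Renames every leaf to its valid family name, resolving synonyms and
#' genus-level tips. Duplicate family leaves are permitted at this stage;
#' [collapse_to_families()] resolves them.
#'
#' @param tree a rooted \code{phylo}.
#' @param tax a [taxonomy()] object.
#' @return the tree with leaves renamed.
#' @export
apply_taxonomy <- function(tree, tax) {
  map <- stats::setNames(tax$valid_family, tax$name)
  hit <- tree$tip.label %in% names(map)
  if (!all(hit)) {
    stop("unresolved leaf labels in tree ",
         attr(tree, "source_id") %||% "?", ": ",
         paste(tree$tip.label[!hit], collapse = ", "))
  }
  tree$tip.label <- unname(map[tree$tip.label])
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse same-family leaves and remove ambiguous families
#'
#' Reduces a tree whose leaves carry (possibly repeated) family names to at
#' most one leaf per family. A family whose placement is unambiguous --
#' reducing it to any single representative leaf yields the same
#' family-level topology -- is condensed to one leaf; this covers both
#' monophyletic and paraphyletic families (a paraphyletic grade has no
#' bearing on relationships among other families). A family whose
#' representatives imply different topologies (polyphyly) is removed
#' entirely on grounds of uncertain placement. Degree-2 nodes left by
#' removals are suppressed.
#'
#' @param tree rooted \code{phylo} with family-name leaves (duplicates
#'   allowed).
#' @return the collapsed \code{phylo}, or \code{NULL} (with a logged
#'   message) when fewer than 3 family leaves remain.
#' @export
collapse_to_families <- function(tree) {
  id <- attr(tree, "source_id") %||% "?"
  fams <- unique(tree$tip.label)
  multi <- fams[tabulate(factor(tree$tip.label, fams)) > 1]

  reduced_forms <- function(fam) {
    # one canonical topology per choice of representative
    idx <- which(tree$tip.label == fam)
    vapply(idx, function(keep) {
      drop <- setdiff(idx, keep)
      t2 <- ape::drop.tip(tree, drop, collapse.singles = TRUE)
      nl_canonical(phylo_to_nl(t2))
    }, "")
  }

  polyphyletic <- character()
  for (fam in multi) {
    forms <- reduced_forms(fam)
    if (length(unique(forms)) > 1L) polyphyletic <- c(polyphyletic, fam)
  }

  if (length(polyphyletic) > 0)
    message("tree ", id, ": removed polyphyletic families: ",
            paste(polyphyletic, collapse = ", "))
  keep_idx <- integer()
  seen <- character()
  for (i in seq_along(tree$tip.label)) {
    f <- tree$tip.label[i]
    if (f %in% polyphyletic) next
    if (f %in% seen) next
    keep_idx <- c(keep_idx, i)
    seen <- c(seen, f)
  }
  if (length(keep_idx) < 3L) {
    message("tree ", id, " discarded: reduced below 3 leaves (",
            length(keep_idx), " left)")
    return(NULL)
  }
  out <- ape::keep.tip(tree, keep_idx)
  out <- ape::collapse.singles(out)
  attr(out, "source_id") <- id
  out
}

#' Standardize a whole tree set
#'
#' Applies [apply_taxonomy()] and [collapse_to_families()] to every tree,
#' dropping (with a logged reason) trees that fall below 3 family leaves.
#'
#' @param ts a \code{"treeset"}.
#' @param tax a [taxonomy()] object.
#' @return a standardized \code{"treeset"} whose leaves are valid families,
#'   each appearing at most once per tree.
#' @export
standardize_trees <- function(ts, tax) {
  out <- list()
  for (tr in ts$trees) {
    tr2 <- apply_taxonomy(tr, tax)
    tr3 <- collapse_to_families(tr2)
    if (!is.null(tr3)) out[[length(out) + 1L]] <- tr3
  }
  treeset(out)
}

#' Write standardized trees as newick, one per line
#'
#' @param ts a \code{"treeset"}.
#' @param path output file.
#' @export
write_trees_newick <- function(ts, path) {
  hdr <- paste0("[ standardized family-level trees; sources: ",
                paste(vapply(ts$trees, function(t) attr(t, "source_id"), ""),
                      collapse = ", "), " ]")
  txt <- vapply(ts$trees, function(t) ape::write.tree(t), "")
  writeLines(c(hdr, txt), path)
  invisible(path)
}
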