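#' Read a fossil range table
#'
#' Delimited text with columns \code{family}, \code{fad}, \code{lad} (Ma,
#' or stage names resolvable against a timescale), \code{extant}
#' (TRUE/FALSE). Stage-named dates resolve conservatively: first
#' appearances to the stage base (oldest edge), last appearances to the
#' stage top.
#'
#' @param path file path.
#' @param timescale a [geo_timescale()] data frame, needed only when dates
#'   are stage names.
#' @return a \code{"fossil_ranges"} data frame with columns \code{family},
#'   \code{fad}, \code{lad}, \code{extant}, \code{in_tree} (initialised
#'   \code{NA}).
#' @export
read_fossil_ranges <- function(path, timescale = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  to_ma <- function(x, edge) {
    if (is.numeric(x)) return(as.numeric(x))
    out <- suppressWarnings(as.numeric(x))
    named <- is.na(out)            # entries that are stage names, not Ma
    if (any(named)) {
      if (is.null(timescale)) stop("stage-named dates need a timescale")
      i <- match(x[named], timescale$stage)
      if (anyNA(i))
        stop("unknown stage: ", paste(x[named][is.na(i)], collapse = ", "))
      out[named] <- timescale[[edge]][i]
    }
    out
  }
  fossil_ranges(df$family, to_ma(df$fad, "base"), to_ma(df$lad, "top"),
                as.logical(df$extant))
}

#' Construct and validate a fossil range table
#'
#' @param family family names.
#' @param fad first appearance datum, Ma before present.
#' @param lad last appearance datum, Ma (0 for extant families).
#' @param extant logical.
#' @return a \code{"fossil_ranges"} data frame.
#' @export
fossil_ranges <- function(family, fad, lad, extant) {
  lad[extant] <- 0
  if (any(fad < lad)) stop("fad must be >= lad (Ma before present)")
  if (any(fad < 0)) stop("negative ages")
  structure(data.frame(family = as.character(family), fad = fad, lad = lad,
                       extant = extant, in_tree = rep(NA, length(family)),
                       stringsAsFactors = FALSE),
            class = c("fossil_ranges", "data.frame"))
}

#' Oldest first appearance within a clade
#'
#' @param tree rooted \code{phylo} over families (polytomies allowed).
#' @param node node number (tip or internal).
#' @param ranges a [fossil_ranges()] table covering the leaves under
#'   \code{node}.
#' @return maximum fad (Ma) over the descendant leaves.
#' @export
clade_fad <- function(tree, node, ranges) {
  desc <- node_tipsets(tree)
  fams <- tree$tip.label[desc[[node]]]
  i <- match(fams, ranges$family)
  if (anyNA(i))
    stop("no range entry for: ", paste(fams[is.na(i)], collapse = ", "))
  max(ranges$fad[i])
}

#' Pull originations back to sister-implied divergences (ghost ranges)
#'
#' Assuming the tree is correct and the record incomplete, both daughters
#' of a node must have been present when they diverged, so each family
#' lineage's origination is set to the first appearance implied by its
#' parent node: adjusted_fad(f) = max over leaves under parent(f) of fad,
#' i.e. the older of its own record and its sister clade's oldest record.
#' Only the divergence from the immediate sister is used; older stem
#' segments belong to ancestral lineages, not to the family. Families
#' absent from the tree pass through unchanged. Extinction dates are never
#' altered.
#'
#' @param tree rooted \code{phylo} over families (leaves must all have
#'   range entries; polytomies allowed, the sibling union is used).
#' @param ranges a [fossil_ranges()] table.
#' @return the table with columns \code{adjusted_fad} and \code{in_tree}
#'   filled in.
#' @export
adjust_originations <- function(tree, ranges) {
  miss <- setdiff(tree$tip.label, ranges$family)
  if (length(miss) > 0)
    stop("tree leaves without range entries: ", paste(miss, collapse = ", "))
  desc <- node_tipsets(tree)
  fad_of <- stats::setNames(ranges$fad, ranges$family)
  clade_max <- vapply(desc, function(tt) max(fad_of[tree$tip.label[tt]]), 0)
  parent <- integer(length(desc))
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  out <- ranges
  out$adjusted_fad <- out$fad
  out$in_tree <- out$family %in% tree$tip.label
  ntip <- length(tree$tip.label)
  for (i in seq_len(ntip)) {
    fam <- tree$tip.label[i]
    j <- match(fam, out$family)
    out$adjusted_fad[j] <- max(out$fad[j], clade_max[parent[i]])
  }
  structure(out, class = c("fossil_ranges", "data.frame"))
}

#' Summarise range extensions implied by ghost ranges
#'
#' @param raw the unadjusted [fossil_ranges()] table.
#' @param adjusted the [adjust_originations()] output on the same families.
#' @return list with \code{per_family} (data frame family, fad,
#'   adjusted_fad, extension), \code{n_extended} (families with extension
#'   > 0), \code{max_extension} and \code{max_family}.
#' @export
extension_summary <- function(raw, adjusted) {
  if (!identical(sort(raw$family), sort(adjusted$family)))
    stop("tables cover different families")
  i <- match(raw$family, adjusted$family)
  ext <- adjusted$adjusted_fad[i] - raw$fad
  per <- data.frame(family = raw$family, fad = raw$fad,
                    adjusted_fad = adjusted$adjusted_fad[i],
                    extension = ext, stringsAsFactors = FALSE)
  k <- which.max(ext)
  list(per_family = per,
       n_extended = sum(ext > 0),
       max_extension = if (nrow(per) > 0) ext[k] else NA_real_,
       max_family = if (nrow(per) > 0 && ext[k] > 0) per$family[k]
                    else NA_character_)
}

#' Write raw and adjusted range tables
#'
#' @param ranges a [fossil_ranges()] table (with or without
#'   \code{adjusted_fad}).
#' @param path output file.
#' @export
write_fossil_ranges <- function(ranges, path) {
  utils::write.table(as.data.frame(ranges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
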