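#' Read a species-richness table
#'
#' Two-column delimited text: family, species_count.
#'
#' @param path file path.
#' @return named integer vector of described species counts per extant
#'   family.
#' @export
read_richness <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 2) df <- utils::read.table(path, header = TRUE, sep = ",",
                                            stringsAsFactors = FALSE)
  counts <- as.integer(df[[2]])
  if (any(is.na(counts) | counts < 1))
    stop("species counts must be positive integers")
  stats::setNames(counts, df[[1]])
}

#' Described species richness of extant odonate families
#'
#' The packaged richness table: described species counts per extant family
#' of Odonata, compiled from the World Odonata List.
#'
#' @return named integer vector (34 families).
#' @export
odonata_richness <- function() {
  read_richness(system.file("extdata", "odonata_richness.tsv",
                            package = "macrophy", mustWork = TRUE))
}

#' Prune a tree to its extant families
#'
#' Removes fossil-only leaves and suppresses the resulting degree-2 nodes.
#'
#' @param tree rooted bifurcating \code{phylo}.
#' @param extant character vector of extant family names.
#' @return rooted bifurcating \code{phylo} on the extant leaves.
#' @export
prune_to_extant <- function(tree, extant) {
  keep <- intersect(tree$tip.label, extant)
  if (length(keep) < 2) stop("fewer than 2 extant leaves after pruning")
  ape::keep.tip(tree, keep)
}

#' Slowinski-Guyer sister-clade imbalance probability
#'
#' Probability, under the equal-rates null in which every split of the
#' combined richness is equally likely, of a sister-pair split at least as
#' uneven as observed: 2 * n_small / (n_large + n_small - 1), capped at 1.
#' Arguments are ordered internally, so the function is symmetric.
#'
#' @param n_small,n_large species richness of the two sister clades
#'   (positive integers; order irrelevant).
#' @return probability in (0, 1].
#' @export
sg_probability <- function(n_small, n_large) {
  if (any(c(n_small, n_large) < 1) ||
      any(c(n_small, n_large) != round(c(n_small, n_large))))
    stop("richness values must be positive integers")
  ns <- min(n_small, n_large)
  nl <- max(n_small, n_large)
  min(1, 2 * ns / (nl + ns - 1))
}

#' Detect diversification-rate shifts across all extant sister clades
#'
#' Visits every internal node of a bifurcating extant-family tree from the
#' tips towards the root, comparing the two daughter-clade richness sums
#' with [sg_probability()]. To prevent the trickle-down effect -- a
#' genuine shift at one node dragging all of its ancestors over the
#' significance line -- a significant node contributes twice the poorer
#' daughter's sum to all deeper comparisons (the richer daughter's sum is
#' replaced by the poorer's), so each rootward test sees richness as if the
#' detected shift had not happened.
#'
#' Significance is symmetric between the two daughters; the reported
#' direction labels the daughter that deviates more, per family lineage,
#' from the node-wide average: an upshift in the richer clade or a
#' downshift in the poorer one.
#'
#' @param tree rooted, fully bifurcating \code{phylo} of extant families
#'   (polytomies are rejected).
#' @param richness named vector of species counts covering every leaf.
#' @param alpha significance level (default 0.05).
#' @param correct_trickle_down apply the richness-substitution correction
#'   (default TRUE); FALSE gives the raw tests at every node.
#' @return an object of class \code{"shift_report"}: data frame with one
#'   row per internal node: \code{clade_A}, \code{clade_B} (member lists),
#'   \code{n_A}, \code{n_B} (raw sums), \code{n_A_corrected},
#'   \code{n_B_corrected} (sums used in the test), \code{p},
#'   \code{significant}, \code{direction}.
#' @export
detect_shifts <- function(tree, richness, alpha = 0.05,
                          correct_trickle_down = TRUE) {
  if (!ape::is.binary(tree))
    stop("fully bifurcating trees are required for diversification analysis")
  miss <- setdiff(tree$tip.label, names(richness))
  if (length(miss) > 0)
    stop("no richness entry for: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  kids <- node_children(tree)
  desc <- node_tipsets(tree)
  nn <- ntip + tree$Nnode

  raw <- numeric(nn)      # uncorrected clade richness sums
  corr <- numeric(nn)     # sums after substitution at significant nodes
  for (i in seq_len(ntip)) raw[i] <- corr[i] <- richness[[tree$tip.label[i]]]

  ord <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  rows <- vector("list", length(ord))
  for (j in seq_along(ord)) {
    v <- ord[j]
    a <- kids[[v]][1L]
    b <- kids[[v]][2L]
    na <- corr[a]; nb <- corr[b]
    p <- sg_probability(min(na, nb), max(na, nb))
    sig <- p < alpha
    raw[v] <- raw[a] + raw[b]
    corr[v] <- if (sig && correct_trickle_down) 2 * min(na, nb) else na + nb
    direction <- NA_character_
    if (sig) {
      fa <- length(desc[[a]]); fb <- length(desc[[b]])
      mean_rate <- (na + nb) / (fa + fb)
      dev_a <- abs(log((na / fa) / mean_rate))
      dev_b <- abs(log((nb / fb) / mean_rate))
      rich_is_a <- na >= nb
      dev_rich <- if (rich_is_a) dev_a else dev_b
      dev_poor <- if (rich_is_a) dev_b else dev_a
      direction <- if (dev_rich > dev_poor) "upshift in richer clade"
                   else "downshift in poorer clade"
    }
    rows[[j]] <- data.frame(
      node = v,
      clade_A = paste(sort(tree$tip.label[desc[[a]]]), collapse = "|"),
      clade_B = paste(sort(tree$tip.label[desc[[b]]]), collapse = "|"),
      n_A = raw[a], n_B = raw[b],
      n_A_corrected = na, n_B_corrected = nb,
      p = p, significant = sig, direction = direction,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, alpha = alpha, class = c("shift_report", "data.frame"))
}

#' Write a sister-group comparison report
#'
#' @param report a [detect_shifts()] report.
#' @param path output file.
#' @export
write_shift_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
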