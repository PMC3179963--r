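#' Define a synthetic study scenario
#'
#' Bundles every parameter of the synthetic-data generators: a birth-death
#' model supertree, noisy input-tree sets, clade richness under
#' equal-rates splitting with an optional implanted diversification shift,
#' an incompletely preserved fossil record, and exponential/logistic
#' richness trajectories with AR(1) noise. All generators derive their
#' random streams deterministically from \code{seed}.
#'
#' Defaults emulate the empirical setting the pipeline was built for: an
#' insect clade of a few dozen extant families with a fossil record
#' spanning roughly 320 My, some 5000 described species, and about 30
#' partially overlapping published input trees.
#'
#' @param seed integer master seed.
#' @param n_families number of extant families the model tree is
#'   conditioned on (fossil lineages are added on top).
#' @param birth,death per-lineage rates (per My); death < birth.
#' @param shift_tips character vector of tip labels defining the clade
#'   carrying an implanted diversification shift (NULL for none).
#' @param shift_multiplier rate multiplier for the shifted clade.
#' @param preservation_rate expected fossil finds per lineage-My.
#' @param n_input_trees,taxon_subsample_fraction,nni_perturbations
#'   input-tree noise model: number of trees, fraction of leaves each
#'   retains, and number of random NNI moves applied to each.
#' @param species_pool total species allocated over extant families.
#' @param growth_mode list: \code{mode} ("exponential" or "logistic"),
#'   \code{r} (per My), \code{n0}, and \code{K} for logistic.
#' @param noise_sd stationary sd of the AR(1) noise on log richness.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param n_points,span_ma trajectory length and time span.
#' @param outgroup name of the outgroup family used in encodings.
#' @return a \code{"scenario"} list.
#' @export
scenario <- function(seed = 1, n_families = 24, birth = 0.03, death = 0.015,
                     shift_tips = NULL, shift_multiplier = 1,
                     preservation_rate = 0.02,
                     n_input_trees = 30, taxon_subsample_fraction = 0.5,
                     nni_perturbations = 2,
                     species_pool = 5000,
                     growth_mode = list(mode = "exponential", r = 0.0136,
                                        n0 = 1, K = 60),
                     noise_sd = 0.2, phi = 0.6,
                     n_points = 60, span_ma = 320,
                     outgroup = "Outgroupidae") {
  stopifnot(n_families >= 4, birth > 0, death >= 0, death < birth,
            taxon_subsample_fraction > 0, taxon_subsample_fraction <= 1,
            abs(phi) < 1, preservation_rate >= 0, shift_multiplier > 0)
  structure(list(seed = as.integer(seed), n_families = n_families,
                 birth = birth, death = death, shift_tips = shift_tips,
                 shift_multiplier = shift_multiplier,
                 preservation_rate = preservation_rate,
                 n_input_trees = n_input_trees,
                 taxon_subsample_fraction = taxon_subsample_fraction,
                 nni_perturbations = nni_perturbations,
                 species_pool = species_pool, growth_mode = growth_mode,
                 noise_sd = noise_sd, phi = phi, n_points = n_points,
                 span_ma = span_ma, outgroup = outgroup),
            class = "scenario")
}

# per-generator deterministic sub-seeds (kept well below 2^31)
sub_seed <- function(sc, k) (sc$seed %% 1000003L) * 1000L + k

#' Simulate the model supertree
#'
#' A birth-death tree conditioned on \code{n_families} extant tips, with
#' extinct (fossil) lineages retained. True ages are recorded: tip ages,
#' and each leaf lineage's true origination (its stem age, the divergence
#' from its sister).
#'
#' @param sc a [scenario()].
#' @return a rooted bifurcating \code{phylo} with attributes
#'   \code{tip_ages}, \code{stem_ages}, \code{extant} (named by tip) in Ma
#'   before present.
#' @export
gen_model_tree <- function(sc) {
  set.seed(sub_seed(sc, 1L))
  tr <- NULL
  for (try in 1:50) {
    tr <- tryCatch(ape::rphylo(sc$n_families, sc$birth, sc$death,
                               fossils = TRUE),
                   error = function(e) NULL)
    if (!is.null(tr)) break
  }
  if (is.null(tr)) stop("birth-death simulation failed repeatedly")
  tr$tip.label <- sprintf("Fam%02d", seq_along(tr$tip.label))
  depth <- ape::node.depth.edgelength(tr)
  total <- max(depth)
  age <- total - depth
  ntip <- length(tr$tip.label)
  parent <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  tip_ages <- stats::setNames(age[seq_len(ntip)], tr$tip.label)
  stem_ages <- stats::setNames(age[parent[seq_len(ntip)]], tr$tip.label)
  extant <- tip_ages < 1e-8
  tip_ages[extant] <- 0
  attr(tr, "tip_ages") <- tip_ages
  attr(tr, "stem_ages") <- stem_ages
  attr(tr, "extant") <- extant
  tr
}

#' Simulate a heterogeneous set of input trees
#'
#' Each input tree is a random leaf subsample of the model tree followed
#' by a fixed number of random NNI moves; branch lengths are discarded
#' (input trees are topologies).
#'
#' @param model_tree a [gen_model_tree()] tree.
#' @param sc the [scenario()].
#' @return a \code{"treeset"} with source ids \code{synth#i}.
#' @export
gen_input_trees <- function(model_tree, sc) {
  set.seed(sub_seed(sc, 2L))
  n <- length(model_tree$tip.label)
  k <- max(3L, ceiling(sc$taxon_subsample_fraction * n))
  out <- list()
  for (i in seq_len(sc$n_input_trees)) {
    tips <- if (k >= n) model_tree$tip.label
            else sample(model_tree$tip.label, k)
    sub <- ape::keep.tip(model_tree, tips)
    sub$edge.length <- NULL
    nl <- phylo_to_nl(sub)
    nl <- nl_random_nni(nl, sc$nni_perturbations)
    tr <- nl_to_phylo(nl)
    attr(tr, "source_id") <- paste0("synth#", i)
    out[[i]] <- tr
  }
  treeset(out)
}

#' Simulate extant-family species richness with an implanted shift
#'
#' Species are allocated over the extant families of the model tree by a
#' linear-rate urn: every family starts with one species and each further
#' species joins family i with probability proportional to rate_i *
#' n_i. With equal rates this is the equal-rates Markov (Yule) allocation
#' -- the Slowinski-Guyer null, under which every sister split of the pool
#' is uniform -- and families in the shifted clade have their rate
#' multiplied by \code{shift_multiplier}.
#'
#' @param model_tree a [gen_model_tree()] tree.
#' @param sc the [scenario()]; \code{sc$shift_tips} (labels; the shifted
#'   clade is their extant union) and \code{sc$shift_multiplier} define
#'   the implant.
#' @return named integer vector of richness per extant family, with
#'   attribute \code{shift_tips} (the ground-truth shifted families).
#' @export
gen_richness <- function(model_tree, sc) {
  set.seed(sub_seed(sc, 3L))
  extant <- names(which(attr(model_tree, "extant")))
  if (length(extant) < 2) stop("model tree has fewer than 2 extant tips")
  shifted <- intersect(sc$shift_tips %||% character(), extant)
  rate <- ifelse(extant %in% shifted, sc$shift_multiplier, 1)
  n <- rep(1L, length(extant))
  extra <- sc$species_pool - length(extant)
  for (s in seq_len(max(0, extra))) {
    i <- sample.int(length(extant), 1L, prob = rate * n)
    n[i] <- n[i] + 1L
  }
  structure(stats::setNames(n, extant), shift_tips = shifted)
}

#' Simulate an incompletely preserved fossil record
#'
#' For each lineage of the model tree, fossil finds fall as a Poisson
#' process (rate \code{preservation_rate} per My) over its true duration,
#' from its stem origination to its extinction (or the present). The
#' first appearance is the oldest find. Extinct lineages with no finds
#' are unobservable and excluded with a message; extant lineages with no
#' finds are still observed today and enter with fad = 0. True
#' originations are kept for recovery tests.
#'
#' @param model_tree a [gen_model_tree()] tree.
#' @param sc the [scenario()].
#' @return a [fossil_ranges()] table with attribute \code{true_origin}
#'   (named vector of stem ages for the included families).
#' @export
gen_fossil_record <- function(model_tree, sc) {
  stopifnot(sc$preservation_rate > 0)
  set.seed(sub_seed(sc, 4L))
  stem <- attr(model_tree, "stem_ages")
  tipage <- attr(model_tree, "tip_ages")
  extant <- attr(model_tree, "extant")
  fam <- character(); fad <- numeric(); lad <- numeric(); ext <- logical()
  truth <- numeric()
  unsampled <- character()
  for (f in names(stem)) {
    dur <- stem[[f]] - tipage[[f]]
    k <- stats::rpois(1, min(sc$preservation_rate, 1e6) * dur)
    if (k == 0 && !extant[[f]]) { unsampled <- c(unsampled, f); next }
    # an extant lineage with no fossil finds is still observed today (fad 0)
    finds <- if (k > 0) stats::runif(k, tipage[[f]], stem[[f]]) else 0
    fam <- c(fam, f)
    fad <- c(fad, max(finds))
    lad <- c(lad, if (extant[[f]]) 0 else min(finds))
    ext <- c(ext, extant[[f]])
    truth <- c(truth, stem[[f]])
  }
  if (length(unsampled) > 0)
    message("unsampled extinct lineages excluded: ",
            paste(unsampled, collapse = ", "))
  out <- fossil_ranges(fam, fad, lad, ext)
  attr(out, "true_origin") <- stats::setNames(truth, fam)
  out
}

#' Simulate a richness trajectory with AR(1) noise
#'
#' Mean richness follows an exponential or logistic
#' (K / (1 + c e^(-r x))) curve of elapsed time x; the exponential mode
#' is parameterised so that mean log(richness + 1) is exactly linear,
#' giving the growth test an exact null. Observed log(richness + 1) adds
#' stationary AR(1) noise. Sampling times mimic geological
#' stages: interval lengths are drawn from the packaged stage-duration
#' distribution and rescaled to the scenario span.
#'
#' @param sc a [scenario()].
#' @return a \code{"richness_series"} data frame (time_ma, richness) with
#'   attribute \code{truth} (the growth-mode list).
#' @export
gen_trajectory <- function(sc) {
  set.seed(sub_seed(sc, 5L))
  gm <- sc$growth_mode
  durs <- sample(stage_durations(), sc$n_points, replace = TRUE)
  bounds <- sc$span_ma - cumsum(durs) / sum(durs) * sc$span_ma
  upper <- c(sc$span_ma, bounds[-length(bounds)])
  time_ma <- (upper + bounds) / 2
  x <- sc$span_ma - time_ma
  # exponential mode is defined on the analysis scale -- log(richness + 1)
  # exactly linear in time -- so growth-test calibration has a true null
  mean_n <- switch(gm$mode,
    exponential = (gm$n0 + 1) * exp(gm$r * x) - 1,
    logistic = {
      c0 <- (gm$K - gm$n0) / gm$n0
      gm$K / (1 + c0 * exp(-gm$r * x))
    },
    stop("unknown growth mode: ", gm$mode))
  n <- length(x)
  noise <- if (sc$noise_sd == 0) {
    rep(0, n)
  } else if (sc$phi == 0) {
    stats::rnorm(n, 0, sc$noise_sd)
  } else {
    as.numeric(stats::arima.sim(list(ar = sc$phi), n,
                                sd = sc$noise_sd * sqrt(1 - sc$phi^2)))
  }
  rich <- pmax(0, exp(log(mean_n + 1) + noise) - 1)
  structure(data.frame(time_ma = time_ma, richness = rich),
            source = "synthetic", truth = gm,
            class = c("richness_series", "data.frame"))
}

stage_durations <- function() {
  ts <- geo_timescale()
  ts$base - ts$top
}

#' Write a complete scenario directory
#'
#' Emits every input the analysis modules read: input trees (newick),
#' taxonomy, richness, fossil ranges, the timescale, a synthetic
#' trajectory, and a ground-truth table (model tree, true originations,
#' shifted families).
#'
#' @param sc a [scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- gen_model_tree(sc)
  ts <- gen_input_trees(model, sc)
  rich <- gen_richness(model, sc)
  rec <- gen_fossil_record(model, sc)
  traj <- gen_trajectory(sc)

  write_trees_newick(ts, file.path(dir, "input_trees.nwk"))
  fams <- sort(unique(c(model$tip.label, sc$outgroup)))
  tax <- data.frame(name = fams, valid_family = fams, status = "valid")
  writeLines(c(paste0("#outgroup: ", sc$outgroup),
               "name\tvalid_family\tstatus",
               sprintf("%s\t%s\t%s", tax$name, tax$valid_family, tax$status)),
             file.path(dir, "taxonomy.tsv"))
  utils::write.table(data.frame(family = names(rich), species_count = rich),
                     file.path(dir, "richness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fossil_ranges(rec, file.path(dir, "ranges.tsv"))
  file.copy(system.file("extdata", "geological_stages.tsv",
                        package = "macrophy", mustWork = TRUE),
            file.path(dir, "timescale.tsv"), overwrite = TRUE)
  utils::write.table(as.data.frame(traj), file.path(dir, "trajectory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ape::write.tree(model), file.path(dir, "model_tree.nwk"))
  truth <- data.frame(family = model$tip.label,
                      true_origin = attr(model, "stem_ages")[model$tip.label],
                      tip_age = attr(model, "tip_ages")[model$tip.label],
                      extant = attr(model, "extant")[model$tip.label],
                      shifted = model$tip.label %in%
                        (attr(rich, "shift_tips") %||% character()))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(model = model, trees = ts, richness = rich,
                 ranges = rec, trajectory = traj))
}
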