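test_that("all generators are deterministic given the scenario seed", {
  sc <- scenario(seed = 12, n_families = 8, n_input_trees = 4)
  m1 <- gen_model_tree(sc)
  m2 <- gen_model_tree(sc)
  expect_equal(ape::write.tree(m1), ape::write.tree(m2))
  expect_equal(attr(m1, "stem_ages"), attr(m2, "stem_ages"))
  t1 <- gen_input_trees(m1, sc)
  t2 <- gen_input_trees(m1, sc)
  expect_equal(lapply(t1$trees, ape::write.tree),
               lapply(t2$trees, ape::write.tree))
  expect_equal(gen_richness(m1, sc), gen_richness(m1, sc))
  expect_equal(suppressMessages(gen_fossil_record(m1, sc)),
               suppressMessages(gen_fossil_record(m1, sc)))
  expect_equal(gen_trajectory(sc), gen_trajectory(sc))
})

test_that("zero extinction gives an all-extant model tree with true ages", {
  sc <- scenario(seed = 2, n_families = 12, death = 0)
  mt <- gen_model_tree(sc)
  expect_true(all(attr(mt, "extant")))
  expect_equal(length(mt$tip.label), 12)
  # stem age = age of the parent node >= tip age
  expect_true(all(attr(mt, "stem_ages") >= attr(mt, "tip_ages")))
})

test_that("input-tree noise model controls subsampling and perturbation", {
  sc0 <- scenario(seed = 6, n_families = 10, death = 0, n_input_trees = 5,
                  taxon_subsample_fraction = 1, nni_perturbations = 0)
  mt <- gen_model_tree(sc0)
  ts0 <- gen_input_trees(mt, sc0)
  for (tr in ts0$trees)
    expect_equal(phangorn::RF.dist(tr, mt), 0)

  sc_half <- scenario(seed = 6, n_families = 10, death = 0,
                      n_input_trees = 5, taxon_subsample_fraction = 0.5,
                      nni_perturbations = 0)
  ts_half <- gen_input_trees(mt, sc_half)
  for (tr in ts_half$trees)
    expect_equal(length(tr$tip.label), 5)

  # NNI perturbation moves trees away from the model, more with more moves
  rf_at <- function(k) {
    sc <- scenario(seed = 6, n_families = 10, death = 0, n_input_trees = 20,
                   taxon_subsample_fraction = 1, nni_perturbations = k)
    mean(vapply(gen_input_trees(mt, sc)$trees,
                function(tr) phangorn::RF.dist(tr, mt), 0))
  }
  expect_gt(rf_at(2), 0)
  expect_gte(rf_at(5), rf_at(2))
})

test_that("richness allocation is a linear-rate urn honouring the shift", {
  sc <- scenario(seed = 9, n_families = 8, death = 0, species_pool = 500)
  mt <- gen_model_tree(sc)
  rich <- gen_richness(mt, sc)
  expect_equal(sum(rich), 500)
  expect_true(all(rich >= 1))
  expect_length(rich, 8)

  shifted <- mt$tip.label[1:2]
  sc20 <- scenario(seed = 9, n_families = 8, death = 0, species_pool = 500,
                   shift_tips = shifted, shift_multiplier = 20)
  rich20 <- gen_richness(mt, sc20)
  expect_equal(attr(rich20, "shift_tips"), shifted)
  expect_gt(sum(rich20[shifted]), sum(rich20) / 2)
})

test_that("fossil preservation behaves at its limits", {
  sc_hi <- scenario(seed = 5, n_families = 10, preservation_rate = 1e5)
  mt <- gen_model_tree(sc_hi)
  rec <- suppressMessages(gen_fossil_record(mt, sc_hi))
  # near-perfect preservation: first find is at the true origination
  expect_equal(rec$fad, unname(attr(rec, "true_origin")[rec$family]),
               tolerance = 1e-3)
  # extinct lineages have lad > 0
  expect_true(all(rec$lad[!rec$extant] > 0))
  expect_true(all(rec$lad[rec$extant] == 0))

  sc_lo <- scenario(seed = 5, n_families = 10, preservation_rate = 0.01)
  rec_lo <- suppressMessages(gen_fossil_record(mt, sc_lo))
  # sparse sampling leaves positive ghost ranges on average
  gaps <- attr(rec_lo, "true_origin")[rec_lo$family] - rec_lo$fad
  expect_gt(mean(gaps), 0)
  # but every extant family is present even without finds
  extant_tips <- names(which(attr(mt, "extant")))
  expect_true(all(extant_tips %in% rec_lo$family))
})

test_that("trajectories honour their growth mode and noise model", {
  sc <- scenario(seed = 7, noise_sd = 0,
                 growth_mode = list(mode = "exponential", r = 0.015, n0 = 1))
  traj <- gen_trajectory(sc)
  lg <- log(traj$richness + 1)
  x <- sc$span_ma - traj$time_ma
  fit <- lm(lg ~ x)
  expect_lt(max(abs(residuals(fit))), 1e-10)   # exactly linear
  expect_equal(unname(coef(fit)[2]), 0.015, tolerance = 1e-10)

  # positive AR(1) autocorrelation depresses the Durbin-Watson statistic
  dws <- vapply(1:20, function(i) {
    sc_i <- scenario(seed = i, phi = 0.6, noise_sd = 0.3, n_points = 80)
    tr <- gen_trajectory(sc_i)
    x <- sc_i$span_ma - tr$time_ma
    durbin_watson(residuals(lm(log(tr$richness + 1) ~ x)))
  }, 0)
  expect_lt(mean(dws), 2)
})

test_that("a noise-free scenario is recovered end to end", {
  sc <- scenario(seed = 8, n_families = 10, death = 0, n_input_trees = 6,
                 taxon_subsample_fraction = 1, nni_perturbations = 0,
                 preservation_rate = 1e5)
  mt <- gen_model_tree(sc)
  ts <- gen_input_trees(mt, sc)
  m <- mrp_encode(ts, sc$outgroup)
  res <- supertree_search(m, "mrp", restarts = 5, seed = 1)
  cons <- majority_rule_plus(res)
  expect_equal(phangorn::RF.dist(ape::drop.tip(cons$tree, sc$outgroup), mt), 0)
  # every model clade fully supported
  rep <- v_scores(cons, ts)
  expect_true(all(rep$per_node$V[!is.na(rep$per_node$V)] == 1))
  # balanced richness: no shifts anywhere
  rich <- stats::setNames(rep(10L, 10), mt$tip.label)
  expect_false(any(detect_shifts(mt, rich)$significant))
  # near-perfect preservation: ghost-range extensions vanish
  rec <- suppressMessages(gen_fossil_record(mt, sc))
  adj <- adjust_originations(mt, rec)
  expect_lt(extension_summary(rec, adj)$max_extension, 1e-3)
  # noiseless exponential trajectory classifies as exponential
  sc_e <- scenario(seed = 8, noise_sd = 0)
  rs <- akima_resample(gen_trajectory(sc_e))
  cls <- classify_growth(fit_gls_ar1(rs, "linear"),
                         fit_gls_ar1(rs, "quadratic"))
  expect_equal(cls, "exponential_consistent")
})

test_that("write_scenario emits a complete, re-readable directory", {
  d <- withr::local_tempdir()
  sc <- scenario(seed = 10, n_families = 8, n_input_trees = 4,
                 species_pool = 200)
  objs <- suppressMessages(write_scenario(sc, d))
  expect_true(all(file.exists(file.path(d,
    c("input_trees.nwk", "taxonomy.tsv", "richness.tsv", "ranges.tsv",
      "timescale.tsv", "trajectory.tsv", "model_tree.nwk", "truth.tsv")))))
  tax <- read_taxonomy(file.path(d, "taxonomy.tsv"))
  expect_equal(attr(tax, "outgroup"), sc$outgroup)
  rich <- read_richness(file.path(d, "richness.tsv"))
  expect_equal(sum(rich), 200)
  rg <- read_fossil_ranges(file.path(d, "ranges.tsv"))
  expect_s3_class(rg, "fossil_ranges")
  ts <- read_timescale(file.path(d, "timescale.tsv"))
  expect_s3_class(ts, "timescale")
})
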