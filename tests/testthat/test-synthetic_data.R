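test_that("generation is deterministic given the seed", {
  cfg <- small_config(seed = 3)
  t1 <- generate_study(cfg)
  t2 <- generate_study(cfg)
  expect_identical(t1$chemicals, t2$chemicals)
  expect_identical(t1$studies[[1]]$values, t2$studies[[1]]$values)
  expect_identical(t1$bioassay, t2$bioassay)
  t3 <- generate_study(small_config(seed = 4))
  expect_false(identical(t1$studies[[1]]$values, t3$studies[[1]]$values))
})

test_that("pathway databases have termini, full panels, and clean orthology", {
  cfg <- small_config(seed = 5)
  db <- generate_pathway_db(cfg)
  expect_length(db$panel, cfg$n_pathways)
  for (net in db$collections$mouse) {
    outdeg <- table(factor(net$edges[, 1], levels = net$nodes))
    expect_gte(sum(outdeg == 0), 1)
  }
  # same topology across species: identical edge counts pathway by pathway
  for (pid in db$panel) {
    expect_equal(nrow(db$collections$rat[[pid]]$edges),
                 nrow(db$collections$mouse[[pid]]$edges))
  }
  expect_s3_class(db$orthology, "orthology_map")
})

test_that("zero ortholog noise gives identical cross-species topology and genes", {
  cfg <- small_config(seed = 6, ortholog_noise = 0)
  db <- generate_pathway_db(cfg)
  for (pid in db$panel) {
    m <- db$collections$mouse[[pid]]
    r <- db$collections$rat[[pid]]
    expect_setequal(paste0("rat_", m$nodes), r$nodes)
  }
  # no species-private genes in the orthology map
  orth_rat <- db$orthology[db$orthology$species == "rat", ]
  expect_false(any(grepl("_x", orth_rat$gene)))
})

test_that("bioassay records satisfy their invariants without clamping", {
  truth <- generate_study(small_config(seed = 7))
  for (rec in truth$bioassay) {
    expect_s3_class(rec, "bioassay_record")
    expect_gt(rec$n_treat, 0)
    expect_gte(rec$p_treat, 0); expect_lte(rec$p_treat, 1)
    expect_gte(rec$p_cont, 0); expect_lte(rec$p_cont, 1)
    # early tumor-free deaths shave weight off the nominal arm size
    expect_lte(rec$n_treat, small_config()$bioassay_n)
  }
})

test_that("carcinogen expression shifts recover the nominal effect size", {
  cfg <- generator_config(seed = 8, n_genes = 800, n_pathways = 30,
                          pathway_size_range = c(10, 30), n_chemicals = 6,
                          n_causal_pathways = 3, species = "mouse")
  truth <- generate_study(cfg)
  causal_genes <- unique(unlist(lapply(
    truth$causal_pathways,
    function(p) truth$db$collections$mouse[[p]]$nodes)))
  for (i in which(truth$chemicals$carcinogen)) {
    st <- truth$studies[[i]]
    est <- mean(rowMeans(st$values[causal_genes, st$groups == "treated"]) -
                  rowMeans(st$values[causal_genes, st$groups == "control"]))
    nominal <- truth$chemicals$m[i]
    expect_lt(abs(est - nominal), 0.2 * cfg$delta + 0.1)
  }
  # non-carcinogens have no systematic causal-gene shift
  for (i in which(!truth$chemicals$carcinogen)) {
    st <- truth$studies[[i]]
    est <- mean(rowMeans(st$values[causal_genes, st$groups == "treated"]) -
                  rowMeans(st$values[causal_genes, st$groups == "control"]))
    expect_lt(abs(est), 0.15)
  }
})

test_that("with zero tumor gain the poly-3 statistics center on zero", {
  cfg <- small_config(seed = 9, gamma = 0, n_chemicals = 26)
  truth <- generate_study(cfg)
  z <- vapply(truth$bioassay, poly3_z, numeric(1))
  expect_lt(abs(mean(z)), 2 / sqrt(length(z)) + 0.3)
})

test_that("cross-species panels map the causal shift through orthology", {
  cfg <- small_config(seed = 10, sigma = 0.05, ortholog_noise = 0)
  truth <- generate_study(cfg)
  panel <- generate_cross_species_panel(truth, "rat")
  i <- which(truth$chemicals$carcinogen)[1]
  ref <- truth$studies[[i]]
  sp <- panel$studies[[i]]
  shift_ref <- rowMeans(ref$values[, ref$groups == "treated"]) -
    rowMeans(ref$values[, ref$groups == "control"])
  shift_sp <- rowMeans(sp$values[, sp$groups == "treated"]) -
    rowMeans(sp$values[, sp$groups == "control"])
  names(shift_sp) <- sub("^rat_", "", names(shift_sp))
  common <- intersect(names(shift_ref), names(shift_sp))
  # with negligible noise and intact orthology the shift profiles coincide
  expect_gt(stats::cor(shift_ref[common], shift_sp[common]), 0.95)
  expect_identical(unname(panel$labels),
                   ifelse(truth$chemicals$carcinogen, "positive", "negative"))
  expect_error(generate_cross_species_panel(truth, "dog"), "unknown species")
})

test_that("dose series scale the causal shift with dose fraction", {
  cfg <- small_config(seed = 11, sigma = 0.1)
  truth <- generate_study(cfg)
  carc <- truth$chemicals$chemical_id[truth$chemicals$carcinogen][1]
  series <- generate_dose_series(truth, carc, dose_fracs = c(0.2, 0.6, 1))
  causal_genes <- unique(unlist(lapply(
    truth$causal_pathways,
    function(p) truth$db$collections$mouse[[p]]$nodes)))
  shifts <- vapply(series[[carc]]$studies, function(st) {
    mean(rowMeans(st$values[causal_genes, st$groups == "treated"]) -
           rowMeans(st$values[causal_genes, st$groups == "control"]))
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
  i <- match(carc, truth$chemicals$chemical_id)
  expect_equal(unname(shifts[3] / shifts[1]), 5, tolerance = 0.25)
})
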