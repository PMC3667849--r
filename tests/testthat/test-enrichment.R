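test_that("quantile normalization equalizes column value multisets", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  ident <- cbind(a = c(2, 1, 5), b = c(2, 1, 5))
  rownames(ident) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(ident), ident)

  set.seed(5)
  big <- matrix(rnorm(100), 20, 5,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:5)))
  qn <- quantile_normalize(big)
  sorted <- apply(qn, 2L, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1L])

  single <- big[, 1L, drop = FALSE]
  expect_warning(out1 <- quantile_normalize(single), ">= 2 samples")
  expect_identical(out1, single)
})

test_that("gene scores are absolute pooled-variance t statistics", {
  study <- toy_study(n_genes = 50, a = 4, seed = 9)
  gs <- gene_scores(study)
  xt <- study$values[, study$groups == "treated"]
  xc <- study$values[, study$groups == "control"]
  for (g in rownames(study$values)) {
    expect_equal(gs$scores[[g]], abs(pooled_t_oracle(xt[g, ], xc[g, ])))
  }
})

test_that("degenerate genes follow the stated conventions", {
  vals <- rbind(gA = c(0, 0, 0, 2, 2, 2),   # zero variance, unequal means
                gB = c(1, 1, 1, 1, 1, 1),   # zero variance, equal means
                gC = c(0, 1, 0, 4, 5, 6))   # regular gene
  study <- expression_study(vals, rep(c("control", "treated"), each = 3))
  gs <- gene_scores(study)
  expect_equal(gs$scores[["gB"]], 0)
  expect_equal(gs$scores[["gA"]], max(gs$scores[["gC"]], 0))

  same <- expression_study(rbind(g1 = c(1, 2, 3, 1, 2, 3)),
                           rep(c("control", "treated"), each = 3))
  expect_equal(unname(gene_scores(same)$scores), 0)

  bad <- expression_study(rbind(g1 = c(1, 2, 3)),
                          c("control", "control", "control"))
  expect_error(gene_scores(bad), "treated")
})

test_that("network enrichment score matches plug-in values and the oracle", {
  pair <- pathway_network("P1", "mouse", c("A", "B"), rbind(c("A", "B")))
  w <- node_weights(pair); d <- pairwise_distances(pair)
  s <- gene_score_table(c(A = 0.3, B = 0.3))
  # equal scores c at distance 1: first bracket c, second 1 + 1/2
  expect_equal(sepea_score(pair, w, d, s), 1.5 * 0.3)

  solo <- gene_score_table(c(A = 0.7), universe = c("A", "Z"))
  expect_equal(sepea_score(pair, w, d, solo), {
    ww <- w$weights
    ww[["A"]] * 0.7 / ww[["A"]]  # only A measured: weighted mean of one
  })

  set.seed(21)
  for (rep in 1:30) {
    net <- random_pathway(6, p_edge = 0.3)
    ww <- node_weights(net); dd <- pairwise_distances(net)
    sc <- stats::setNames(stats::rexp(6), net$nodes)
    got <- sepea_score(net, ww, dd, gene_score_table(sc))
    want <- sepea_direct_oracle(net, ww$weights, dd$distances, sc)
    expect_equal(got, want)
  }
})

test_that("gene-set (NT3) scoring is the indicator special case", {
  chain <- pathway_network("P1", "mouse", c("A", "B", "C"),
                           rbind(c("A", "B"), c("B", "C")))
  w <- node_weights(chain); d <- pairwise_distances(chain)
  # full coverage: first bracket 1, pairs {AB:1, AC:2, BC:1}
  expect_equal(sepea_nt3_score(chain, w, d, c("A", "B", "C"),
                               c("A", "B", "C")),
               1 * (1 + (1 / 2 + 1 / 3 + 1 / 2) / 3))
  expect_true(is.na(sepea_nt3_score(chain, w, d, c("X", "Y"),
                                    c("A", "B", "C", "X", "Y"))))
  # singleton overlap reduces to the weight-normalized indicator
  expect_equal(sepea_nt3_score(chain, w, d, "C", c("A", "B", "C")),
               w$weights[["C"]] / sum(w$weights))
})

test_that("p-to-z conversion is the upper-tail normal quantile with clamping", {
  expect_identical(p_to_z(0.5), 0)
  expect_equal(p_to_z(1 - stats::pnorm(2)), 2)
  expect_equal(p_to_z(1, n_perm = 999), stats::qnorm(0.001))
  expect_error(p_to_z(0), "\\(0, 1\\]")
  expect_error(p_to_z(1.2), "\\(0, 1\\]")
  # strictly decreasing in p
  p <- c(0.9, 0.5, 0.2, 0.01)
  expect_true(all(diff(p_to_z(p)) > 0))
})

test_that("permutation p-values are deterministic, bounded, and scale-invariant", {
  set.seed(2)
  net <- random_pathway(8, p_edge = 0.3)
  w <- node_weights(net); d <- pairwise_distances(net)
  universe <- c(net$nodes, paste0("u", 1:40))
  sc <- stats::setNames(stats::rexp(length(universe)), universe)
  tab <- gene_score_table(sc)

  r1 <- permutation_pvalue(net, w, d, tab, K = 200, seed = 31)
  r2 <- permutation_pvalue(net, w, d, tab, K = 200, seed = 31)
  expect_equal(r1, r2)
  expect_gte(r1$p_value, 1 / 201)
  expect_lte(r1$p_value, 1)
  expect_equal(r1$z, p_to_z(r1$p_value, n_perm = 200))

  # common rescaling of all gene scores preserves every >= comparison
  r3 <- permutation_pvalue(net, w, d, gene_score_table(sc * 3.7),
                           K = 200, seed = 31)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$score, r1$score * 3.7)
})

test_that("strong coherent perturbation of a pathway yields a small p", {
  set.seed(4)
  net <- random_pathway(10, p_edge = 0.35, id = "Phit")
  universe <- c(net$nodes, paste0("u", 1:200))
  sc <- stats::setNames(abs(stats::rnorm(length(universe), 0, 0.2)), universe)
  sc[net$nodes] <- sc[net$nodes] + 5
  res <- permutation_pvalue(net, node_weights(net), pairwise_distances(net),
                            gene_score_table(sc), K = 999, seed = 8)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$z, 3)
})

test_that("moving score mass toward the terminus raises the score", {
  chain <- pathway_network("P1", "mouse", c("A", "B", "C"),
                           rbind(c("A", "B"), c("B", "C")))
  w <- node_weights(chain); d <- pairwise_distances(chain)
  upstream <- gene_score_table(c(A = 2, B = 1, C = 0.5))
  terminal <- gene_score_table(c(A = 0.5, B = 1, C = 2))
  expect_gt(sepea_score(chain, w, d, terminal),
            sepea_score(chain, w, d, upstream))
})

test_that("feature vectors follow panel order with zero imputation for skips", {
  res <- data.frame(pathway_id = c("P2", "P1"), score = c(1, NA),
                    p_value = c(0.1, NA), z = c(1.2, NA),
                    n_perm = 100, skipped = c(FALSE, TRUE))
  expect_equal(feature_vector(c("P1", "P2"), res), c(P1 = 0, P2 = 1.2))
  expect_length(feature_vector(character(), res), 0L)
  expect_error(feature_vector(c("P1", "P3"), res), "P3")
})
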