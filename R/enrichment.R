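#' Treated-vs-control expression study container
#'
#' @param values numeric matrix, genes x samples, log2 intensity scale;
#'   rownames are gene identifiers (unique), colnames sample identifiers.
#' @param groups character vector (or named vector matching colnames) with
#'   one of `"treated"`, `"control"` per sample.
#' @return object of class `expression_study`.
#' @export
expression_study <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("groups must have one label per sample")
  }
  if (!all(groups %in% c("treated", "control"))) {
    stop("group labels must be 'treated' or 'control'")
  }
  structure(list(values = values, groups = groups), class = "expression_study")
}

#' Quantile normalization of an expression matrix
#'
#' Classic quantile normalization: within each sample, values are replaced by
#' the mean across samples of the sorted values at the same rank; ties within
#' a sample receive the mean reference value over their tied rank span.
#' After normalization every column has the same value multiset.
#'
#' @param x numeric matrix (genes x samples) or an [expression_study()].
#' @return the same type of object with normalized values. A single-sample
#'   input is returned unchanged with a warning.
#' @export
quantile_normalize <- function(x) {
  study <- inherits(x, "expression_study")
  m <- if (study) x$values else x
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (study) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Per-gene perturbation scores from a treated-vs-control study
#'
#' The gene-level statistic is the absolute two-sample t statistic with
#' pooled variance on log2 values. Degenerate genes: zero pooled variance
#' with equal group means scores 0; zero pooled variance with unequal means
#' scores the maximum finite score in the table (assigned after all regular
#' scores are computed).
#'
#' @param study an [expression_study()] with at least two samples per group.
#' @return object of class `gene_score_table`: list with named numeric
#'   `scores` (non-negative, finite) and character `universe`.
#' @export
gene_scores <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  for (grp in c("treated", "control")) {
    if (sum(study$groups == grp) < 2L) {
      stop("need >= 2 samples in group '", grp, "'")
    }
  }
  xt <- study$values[, study$groups == "treated", drop = FALSE]
  xc <- study$values[, study$groups == "control", drop = FALSE]
  n1 <- ncol(xt); n0 <- ncol(xc)
  m1 <- rowMeans(xt); m0 <- rowMeans(xc)
  v1 <- apply(xt, 1L, stats::var); v0 <- apply(xc, 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t_abs <- abs(m1 - m0) / se
  degenerate <- se == 0
  t_abs[degenerate & m1 == m0] <- 0
  bad <- degenerate & m1 != m0
  if (any(bad)) {
    mx <- suppressWarnings(max(t_abs[is.finite(t_abs)], 0))
    t_abs[bad] <- mx
  }
  structure(list(scores = t_abs, universe = rownames(study$values)),
            class = "gene_score_table")
}

#' Gene score table from explicit scores
#'
#' @param scores named non-negative numeric vector (gene -> perturbation
#'   magnitude); every scored gene must be in `universe`.
#' @param universe character vector of all measured genes (defaults to the
#'   scored genes).
#' @return a `gene_score_table`.
#' @export
gene_score_table <- function(scores, universe = names(scores)) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (any(!is.finite(scores)) || any(scores < 0)) {
    stop("scores must be finite and non-negative")
  }
  universe <- unique(as.character(universe))
  if (!all(names(scores) %in% universe)) {
    stop("every scored gene must be in the universe")
  }
  full <- rep(0, length(universe))
  names(full) <- universe
  full[names(scores)] <- scores
  structure(list(scores = full, universe = universe),
            class = "gene_score_table")
}

# Proximity kernel on network distance: kappa(d) = 1/(1+d), disconnection -> 0.
proximity_kernel <- function(d) {
  k <- 1 / (1 + d)
  k[!is.finite(d)] <- 0
  k
}

# Internal workhorse: score from a weight vector, kernel matrix (zero
# diagonal) and score vector over the measured pathway nodes. The first
# bracket is the weight-normalized mean perturbation; the second rewards
# pairs of perturbed genes that sit close on the network.
sepea_core <- function(w, kmat, s) {
  first <- sum(w * s) / sum(w)
  m <- length(s)
  if (m < 2L) return(first)
  q <- (sum(s)^2 - sum(s^2)) / 2
  if (q == 0) return(first)
  p <- as.numeric(crossprod(s, kmat %*% s)) / 2
  first * (1 + p / q)
}

# Measured pathway nodes and the pieces sepea_core needs; NULL when the
# pathway has no measured node (skip condition).
sepea_parts <- function(net, weights, dist, universe) {
  v <- intersect(net$nodes, universe)
  if (length(v) == 0L) return(NULL)
  w <- weights$weights[v]
  kmat <- proximity_kernel(dist$distances[v, v, drop = FALSE])
  diag(kmat) <- 0
  list(v = v, w = w, kmat = kmat)
}

#' Network-structured pathway enrichment score (continuous gene scores)
#'
#' For measured pathway nodes `V` with gene scores `s`, topological weights
#' `w` and undirected network distances `d`, the score is
#' `[sum(w s)/sum(w)] * [1 + sum_{u<v} s_u s_v k(d_uv) / sum_{u<v} s_u s_v]`
#' with proximity kernel `k(d) = 1/(1+d)` and `k(Inf) = 0`. The second
#' bracket is 1 when fewer than two nodes are measured or all pairwise score
#' products vanish. Pathway nodes absent from the measured universe are
#' dropped from both terms.
#'
#' @param net a [pathway_network()].
#' @param weights matching [node_weights()].
#' @param dist matching [pairwise_distances()].
#' @param scores a `gene_score_table`.
#' @return scalar score, or `NA_real_` when no pathway node is measured
#'   (the pathway is then skipped upstream and recorded in a skip report).
#' @export
sepea_score <- function(net, weights, dist, scores) {
  stopifnot(inherits(scores, "gene_score_table"))
  parts <- sepea_parts(net, weights, dist, scores$universe)
  if (is.null(parts)) return(NA_real_)
  sepea_core(parts$w, parts$kmat, scores$scores[parts$v])
}

#' Network-structured enrichment score for a gene set
#'
#' Identical to [sepea_score()] with indicator scores: `s(v) = 1` when `v`
#' is in `gene_set`, else 0. Used for gene-polymorphism panels where only
#' set membership, not a continuous perturbation magnitude, is known.
#'
#' @inheritParams sepea_score
#' @param gene_set character vector of genes in the set.
#' @param universe character vector of all candidate genes.
#' @return scalar score; `NA_real_` when the set does not intersect the
#'   measured pathway nodes (skip).
#' @export
sepea_nt3_score <- function(net, weights, dist, gene_set, universe) {
  gene_set <- intersect(gene_set, universe)
  if (length(intersect(gene_set, net$nodes)) == 0L) return(NA_real_)
  s <- as.numeric(universe %in% gene_set)
  names(s) <- universe
  sepea_score(net, weights, dist,
              gene_score_table(s, universe))
}

#' Convert a permutation p-value to a z-score feature
#'
#' `z = qnorm(1 - p)`: smaller p-values give larger z, so pathways more
#' strongly perturbed than their permutation null get elevated features.
#' When `n_perm` is supplied, p is clamped to at most `1 - 1/(n_perm + 1)`
#' so a p of exactly 1 maps to the finite lower bound attainable on the
#' permutation grid rather than `-Inf`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param n_perm optional permutation count used to clamp `p = 1`.
#' @return numeric vector of z-scores.
#' @export
p_to_z <- function(p, n_perm = NULL) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]")
  }
  if (!is.null(n_perm)) p <- pmin(p, 1 - 1 / (n_perm + 1))
  stats::qnorm(1 - p)
}

#' Permutation p-value and z feature for one pathway
#'
#' The null reassigns the observed gene-score multiset at random over the
#' measured universe (equivalently: the pathway's nodes receive scores drawn
#' without replacement from the full score vector), recomputing the pathway
#' score each time. `p = (1 + #\{null >= observed\}) / (K + 1)` (add-one
#' estimator, so `p` lies on `[1/(K+1), 1]`), and `z` is [p_to_z()] of the
#' clamped p. For a gene-set (NT3) analysis pass the indicator score table
#' built by [gene_score_table()]; drawing node scores from the indicator
#' vector without replacement is exactly a uniform redraw of the set.
#'
#' @inheritParams sepea_score
#' @param K number of permutations (>= 100).
#' @param seed integer seed; results are deterministic given the seed.
#' @return one-row data frame (class `enrichment_result`): `pathway_id`,
#'   `score`, `p_value`, `z`, `n_perm`, `skipped`.
#' @export
permutation_pvalue <- function(net, weights, dist, scores, K = 50000L,
                               seed = 1L) {
  stopifnot(K >= 100L)
  res <- enrich_pathways(list(net), list(weights), list(dist), scores,
                         K = K, seed = seed)
  res
}

#' Permutation enrichment across a pathway collection
#'
#' Batch version of [permutation_pvalue()]: one shared set of `K` random
#' reassignments of the score multiset over the universe is evaluated on
#' every pathway, which keeps large `K` tractable across hundreds of
#' pathways. Pathways with no measured node are skipped and flagged.
#'
#' @param nets list of [pathway_network()] objects.
#' @param weights list of matching [node_weights()] (same order).
#' @param dists list of matching [pairwise_distances()] (same order).
#' @param scores a `gene_score_table`.
#' @param K number of permutations (>= 100). The headline analysis default
#'   is `5e4`; simulation studies in this package use 1000-2000.
#' @param seed integer seed.
#' @return data frame with one row per pathway: `pathway_id`, `score`,
#'   `p_value`, `z`, `n_perm`, `skipped`.
#' @export
enrich_pathways <- function(nets, weights, dists, scores, K = 50000L,
                            seed = 1L) {
  stopifnot(inherits(scores, "gene_score_table"), K >= 100L,
            length(nets) == length(weights), length(nets) == length(dists))
  universe <- scores$universe
  svec <- scores$scores[universe]
  n <- length(svec)
  K <- as.integer(K)

  out <- local_seed(seed, {
    # K global permutations of universe positions, shared by all pathways
    perm <- matrix(0L, nrow = n, ncol = K)
    for (j in seq_len(K)) perm[, j] <- sample.int(n)
    rows <- vector("list", length(nets))
    for (i in seq_along(nets)) {
      net <- nets[[i]]
      pr <- sepea_parts(net, weights[[i]], dists[[i]], universe)
      if (is.null(pr)) {
        rows[[i]] <- data.frame(pathway_id = net$pathway_id, score = NA_real_,
                                p_value = NA_real_, z = NA_real_,
                                n_perm = K, skipped = TRUE,
                                stringsAsFactors = FALSE)
        next
      }
      pos <- match(pr$v, universe)
      s_obs <- svec[pos]
      obs <- sepea_core(pr$w, pr$kmat, s_obs)
      m <- length(pos)
      S <- matrix(svec[perm[pos, , drop = FALSE]], nrow = m, ncol = K)
      first <- colSums(pr$w * S) / sum(pr$w)
      if (m < 2L) {
        null_scores <- first
      } else {
        cs <- colSums(S)
        cs2 <- colSums(S * S)
        q <- (cs^2 - cs2) / 2
        p2 <- colSums(S * (pr$kmat %*% S)) / 2
        bracket <- ifelse(q == 0, 1, 1 + p2 / q)
        null_scores <- first * bracket
      }
      p <- (1 + sum(null_scores >= obs)) / (K + 1)
      rows[[i]] <- data.frame(pathway_id = net$pathway_id, score = obs,
                              p_value = p, z = p_to_z(p, n_perm = K),
                              n_perm = K, skipped = FALSE,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Pathway z feature vector in panel order
#'
#' @param panel ordered character vector of pathway ids (the shared panel).
#' @param results an enrichment result data frame covering every panel
#'   pathway (either scored or flagged skipped).
#' @return named numeric vector of z features in panel order; skipped
#'   pathways are imputed with `z = 0`, the null-median feature value, so
#'   feature columns stay aligned across species.
#' @export
feature_vector <- function(panel, results) {
  if (length(panel) == 0L) return(stats::setNames(numeric(0), character(0)))
  idx <- match(panel, results$pathway_id)
  if (anyNA(idx)) {
    stop("panel pathways without an enrichment result or skip record: ",
         paste(panel[is.na(idx)], collapse = ", "))
  }
  z <- results$z[idx]
  z[results$skipped[idx]] <- 0
  z[is.na(z)] <- 0
  stats::setNames(z, panel)
}
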