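# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths
# (igraph, matrix algebra, rank tricks) so they can adjudicate them.

# Breadth-first search shortest paths on the undirected skeleton.
bfs_dist_oracle <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      u <- queue[[1L]]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (!is.finite(d[s, v])) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}

# Pairwise AUC by O(n^2) pair counting with ties at 1/2.
auc_pair_oracle <- function(score, label) {
  pos <- score[label == "positive"]
  neg <- score[label == "negative"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct double-loop evaluation of the network enrichment score.
sepea_direct_oracle <- function(net, w, dmat, s) {
  v <- names(s)
  first <- sum(w[v] * s) / sum(w[v])
  if (length(v) < 2L) return(first)
  num <- 0; den <- 0
  for (i in seq_along(v)) for (j in seq_along(v)) {
    if (i < j) {
      d <- dmat[v[i], v[j]]
      k <- if (is.finite(d)) 1 / (1 + d) else 0
      num <- num + s[[i]] * s[[j]] * k
      den <- den + s[[i]] * s[[j]]
    }
  }
  if (den == 0) first else first * (1 + num / den)
}

# Textbook pooled-variance two-sample t statistic, one gene at a time.
pooled_t_oracle <- function(x_treat, x_cont) {
  n1 <- length(x_treat); n0 <- length(x_cont)
  sp2 <- ((n1 - 1) * stats::var(x_treat) + (n0 - 1) * stats::var(x_cont)) /
    (n1 + n0 - 2)
  (mean(x_treat) - mean(x_cont)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# Random directed graph (no self-loops) as a pathway network.
random_pathway <- function(n, p_edge = 0.3, id = "P1", species = "mouse") {
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(a = nodes, b = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- as.matrix(pairs[keep, , drop = FALSE])
  dimnames(edges) <- NULL
  pathway_network(id, species, nodes, edges)
}

# A small expression study with given group means per gene.
toy_study <- function(n_genes = 20, a = 3, shift = NULL, sigma = 1,
                      seed = 1) {
  genes <- paste0("g", seq_len(n_genes))
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 2 * a, mean = 7, sd = sigma),
                 nrow = n_genes, dimnames = list(genes, NULL))
  groups <- rep(c("control", "treated"), each = a)
  if (!is.null(shift)) {
    vals[names(shift), groups == "treated"] <-
      vals[names(shift), groups == "treated"] + shift
  }
  expression_study(vals, groups)
}

# Tiny generator config so synthetic-data unit tests stay fast.
small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_genes = 300, n_pathways = 20,
                   pathway_size_range = c(5, 15), n_chemicals = 10,
                   n_causal_pathways = 3, species = c("mouse", "rat"),
                   bioassay_n = 40)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Mean-predicting learner with a known oracle risk.
learner_mean <- function() {
  learner_spec("mean", function(X, y, seed) {
    m <- mean(y)
    function(newX) rep(m, nrow(newX))
  })
}

# Ordinary least squares on all features (used where an exact linear
# relationship must be recovered).
learner_ols1 <- function(name = "ols1") {
  learner_spec(name, function(X, y, seed) {
    df <- data.frame(y = y, x = X[, 1L])
    fit <- stats::lm(y ~ x, data = df)
    function(newX) unname(stats::predict(fit, data.frame(x = newX[, 1L])))
  })
}
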