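#' Construct a pathway network
#'
#' A pathway is represented as a directed graph over gene identifiers.
#' Undirected interactions are stored as two ordered pairs, so a node's
#' out-degree is zero only if every incident interaction points into it.
#'
#' @param pathway_id single character token identifying the pathway.
#' @param species single character token (e.g. `"mouse"`).
#' @param nodes character vector of gene identifiers (non-empty, unique).
#' @param edges two-column character matrix of ordered (source, target)
#'   pairs; may have zero rows. Duplicate rows are collapsed; self-loops are
#'   rejected.
#' @param category optional broad pathway category label.
#' @return an object of class `pathway_network`.
#' @export
pathway_network <- function(pathway_id, species, nodes, edges = NULL,
                            category = NA_character_) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            is.character(species), length(species) == 1L)
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0L) stop("pathway '", pathway_id, "': nodes is empty")
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  edges <- matrix(as.character(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("pathway '", pathway_id, "': self-loop edges are not allowed")
    }
    missing <- setdiff(c(edges), nodes)
    if (length(missing) > 0L) {
      stop("pathway '", pathway_id, "': edge endpoints not in nodes: ",
           paste(missing, collapse = ", "))
    }
    edges <- unique(edges)
  }
  structure(
    list(pathway_id = pathway_id, species = species, nodes = nodes,
         edges = edges, category = category),
    class = "pathway_network"
  )
}

#' @exportS3Method print pathway_network
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network> %s [%s]: %d nodes, %d directed edges\n",
              x$pathway_id, x$species, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net, directed = TRUE) {
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, t(net$edges))
  }
  g
}

#' Load pathway networks from an edge-list file
#'
#' Reads a tab-separated edge list with columns `pathway_id`, `source_gene`,
#' `target_gene`, `direction` (`directed` or `undirected`) and returns one
#' [pathway_network()] per distinct pathway id. Undirected rows expand to two
#' ordered pairs; duplicate rows collapse. Rows whose source equals their
#' target are dropped with a warning and counted in the load report
#' (attribute `"load_report"`).
#'
#' @param path path to the TSV file (header row required).
#' @param species species token attached to every network.
#' @return named list of `pathway_network` objects, with a `load_report`
#'   attribute (`n_rows`, `n_self_loops_dropped`).
#' @export
load_pathways <- function(path, species) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty pathway file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("pathway_id", "source_gene", "target_gene", "direction")
  if (!identical(header[seq_along(need)], need)) {
    stop("pathway file must have header columns: ", paste(need, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_self <- 0L
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    line_no <- i + 1L
    if (length(p) != 4L) {
      stop("malformed row at line ", line_no, ": expected 4 fields, got ",
           length(p))
    }
    if (!p[[4L]] %in% c("directed", "undirected")) {
      stop("malformed row at line ", line_no, ": direction must be ",
           "'directed' or 'undirected', got '", p[[4L]], "'")
    }
    if (p[[2L]] == p[[3L]]) {
      warning("self-loop row at line ", line_no, " dropped (", p[[1L]], ": ",
              p[[2L]], ")")
      n_self <- n_self + 1L
      next
    }
    rows[[i]] <- p
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("no usable rows in pathway file: ", path)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- need
  nets <- lapply(split(df, df$pathway_id), function(d) {
    e <- as.matrix(d[, c("source_gene", "target_gene")])
    undir <- d$direction == "undirected"
    if (any(undir)) e <- rbind(e, e[undir, c(2L, 1L), drop = FALSE])
    dimnames(e) <- NULL
    pathway_network(d$pathway_id[[1L]], species,
                    nodes = unique(c(e)), edges = e)
  })
  nets <- nets[order(names(nets))]
  attr(nets, "load_report") <- list(n_rows = length(parts),
                                    n_self_loops_dropped = n_self)
  nets
}

terminus_nodes <- function(net) {
  if (nrow(net$edges) == 0L) return(net$nodes)
  outdeg <- table(factor(net$edges[, 1L], levels = net$nodes))
  net$nodes[outdeg == 0L]
}

#' Directed distance from each node to the nearest terminus
#'
#' Shortest directed-path length from every node to the closest node of
#' out-degree zero. `Inf` where no terminus is reachable; zero-length result
#' semantics follow [node_weights()].
#'
#' @param net a [pathway_network()].
#' @return named numeric vector (possibly `Inf`), one entry per node.
#' @export
terminus_distance <- function(net) {
  term <- terminus_nodes(net)
  d <- rep(Inf, length(net$nodes))
  names(d) <- net$nodes
  if (length(term) == 0L) return(d)
  g <- as_igraph(net, directed = TRUE)
  dm <- igraph::distances(g, v = net$nodes, to = term, mode = "out")
  d[] <- apply(dm, 1L, min)
  d
}

#' Topological node weights for a pathway
#'
#' Genes near the terminating (transcription-signalling) end of a pathway
#' receive more weight. With `T` the set of terminus nodes (out-degree 0),
#' `d_T(v)` the shortest directed distance from `v` to `T`, and `D` the
#' largest finite `d_T`, the weight is `1 + lambda * (1 - d_T(v)/D)`, so a
#' terminus weighs `1 + lambda` and the most upstream node weighs 1.
#' Conventions: unreachable nodes weigh 1; if `T` is empty all weights are 1;
#' if `D = 0` terminus nodes weigh `1 + lambda` and all others 1.
#'
#' @param net a [pathway_network()].
#' @param lambda positive scalar controlling the terminus emphasis (default 1).
#' @return object of class `node_weighting`: list with `pathway_id` and a
#'   named numeric `weights` vector (all `>= 1`).
#' @export
node_weights <- function(net, lambda = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  d <- terminus_distance(net)
  w <- rep(1, length(d))
  names(w) <- names(d)
  fin <- is.finite(d)
  if (any(fin)) {
    D <- max(d[fin])
    if (D == 0) {
      w[fin & d == 0] <- 1 + lambda
    } else {
      w[fin] <- 1 + lambda * (1 - d[fin] / D)
    }
  }
  structure(list(pathway_id = net$pathway_id, weights = w),
            class = "node_weighting")
}

#' Pairwise node distances on the undirected pathway skeleton
#'
#' Unweighted shortest-path lengths with edge direction ignored (proximity of
#' perturbed genes is a symmetric notion on these maps). Disconnected pairs
#' are `Inf`, never a sentinel, so downstream proximity kernels can map
#' disconnection to zero.
#'
#' @param net a [pathway_network()].
#' @return object of class `distance_table`: list with `pathway_id` and a
#'   symmetric numeric `distances` matrix (zero diagonal, `Inf` allowed).
#' @export
pairwise_distances <- function(net) {
  g <- as_igraph(net, directed = TRUE)
  dm <- igraph::distances(g, mode = "all")
  dm <- dm[net$nodes, net$nodes, drop = FALSE]
  structure(list(pathway_id = net$pathway_id, distances = dm),
            class = "distance_table")
}

#' Orthology map constructor
#'
#' @param df data frame with columns `species`, `gene`, `canonical`; each
#'   (species, gene) pair must map to exactly one canonical ortholog token.
#' @return the validated data frame with class `orthology_map`.
#' @export
orthology_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("species", "gene", "canonical") %in% names(df)))
  key <- paste(df$species, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop("orthology map is not a function: duplicate (species, gene) pairs")
  }
  class(df) <- c("orthology_map", class(df))
  df
}

#' Shared orthologous pathway panel
#'
#' Intersects the pathway ids present in every species' collection and
#' returns them in lexicographic order. This order fixes the feature-column
#' order used everywhere downstream.
#'
#' @param collections named list (one element per species) of pathway
#'   collections as returned by [load_pathways()].
#' @param orthology optional [orthology_map()] (carried for provenance; the
#'   panel itself is an id intersection).
#' @return character vector of pathway ids, sorted.
#' @export
shared_panel <- function(collections, orthology = NULL) {
  stopifnot(is.list(collections), length(collections) >= 1L)
  ids <- lapply(collections, names)
  panel <- Reduce(intersect, ids)
  if (length(panel) == 0L) {
    stop("empty pathway panel: no pathway id is present in all species")
  }
  sort(panel)
}
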