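#' Write pathway networks as an edge-list TSV
#'
#' The inverse of [load_pathways()]: directed edges only (an undirected
#' interaction that was expanded to two ordered pairs round-trips as two
#' directed rows, which load back to the same graph).
#'
#' @param collection named list of [pathway_network()]s.
#' @param path output file.
#' @export
write_pathways <- function(collection, path) {
  rows <- do.call(rbind, lapply(collection, function(net) {
    if (nrow(net$edges) == 0L) return(NULL)
    data.frame(pathway_id = net$pathway_id, source_gene = net$edges[, 1L],
               target_gene = net$edges[, 2L], direction = "directed",
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set id, description, then member genes, tab-separated. Also
#' accepted by the pathway side as an edge-free fallback: a GMT set loads
#' as a pathway with uniform node weights and no finite pairwise distances.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1L)) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line(s) (need id, description, >=1 gene): line ",
         paste(bad, collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1L), 2L), names(sets))
  sets
}

#' Pathway networks from a GMT file (edge-free fallback)
#'
#' @param path GMT file path.
#' @param species species token.
#' @return named list of edge-free [pathway_network()]s: every node weight
#'   is 1 and all pairwise distances are infinite.
#' @export
load_pathways_gmt <- function(path, species) {
  sets <- read_gmt(path)
  stats::setNames(lapply(names(sets), function(id) {
    pathway_network(id, species, nodes = sets[[id]])
  }), names(sets))
}

#' Read an expression study from TSV files
#'
#' @param expr_path TSV with gene ids in the first column and one column
#'   per sample (header row of sample ids).
#' @param groups_path two-column TSV (`sample`, `group`) mapping sample ids
#'   to `treated`/`control`.
#' @return an [expression_study()].
#' @export
read_expression_study <- function(expr_path, groups_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g))) {
    stop("group file needs columns 'sample' and 'group'")
  }
  idx <- match(colnames(m), g$sample)
  if (anyNA(idx)) {
    stop("samples without a group label: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  }
  expression_study(m, g$group[idx])
}

#' Write an expression study to TSV files
#'
#' @param study an [expression_study()].
#' @param expr_path,groups_path output paths (see
#'   [read_expression_study()]).
#' @export
write_expression_study <- function(study, expr_path, groups_path) {
  df <- data.frame(gene = rownames(study$values), study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(study$values),
                                group = study$groups),
                     groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

#' Read survival-adjusted bioassay records from TSV
#'
#' @param path TSV with columns `chemical_id`, `n_treat`, `p_treat`,
#'   `n_cont`, `p_cont`.
#' @return named list of [bioassay_record()]s.
#' @export
read_bioassay <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chemical_id", "n_treat", "p_treat", "n_cont", "p_cont")
  if (!all(need %in% names(df))) {
    stop("bioassay file needs columns: ", paste(need, collapse = ", "))
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    bioassay_record(df$chemical_id[i], df$n_treat[i], df$p_treat[i],
                    df$n_cont[i], df$p_cont[i])
  })
  stats::setNames(recs, df$chemical_id)
}

#' Write bioassay records (with derived statistics) to TSV
#'
#' @param records named list of [bioassay_record()]s.
#' @param path output file.
#' @return invisibly, the data frame written (record fields plus `z_raw`,
#'   `z_capped`, `p_one_sided`, `call`).
#' @export
write_bioassay <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    cbind(data.frame(chemical_id = r$chemical_id, n_treat = r$n_treat,
                     p_treat = r$p_treat, n_cont = r$n_cont,
                     p_cont = r$p_cont, stringsAsFactors = FALSE),
          binary_call(r)[, -1L])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a two-column-per-species orthology TSV
#'
#' @param path TSV with columns `species`, `gene`, `canonical`.
#' @return an [orthology_map()].
#' @export
read_orthology <- function(path) {
  orthology_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write an enrichment result table to TSV
#'
#' @param results data frame from [enrich_pathways()].
#' @param path output file.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
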