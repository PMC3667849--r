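#' Precompute topological inputs for a pathway collection
#'
#' @param collection named list of [pathway_network()]s.
#' @param lambda terminus-weight emphasis passed to [node_weights()].
#' @return list with parallel named lists `nets`, `weights`, `dists`.
#' @export
pathway_inputs <- function(collection, lambda = 1) {
  list(nets = collection,
       weights = lapply(collection, node_weights, lambda = lambda),
       dists = lapply(collection, pairwise_distances))
}

#' Pathway z features for one treated-vs-control study
#'
#' Runs the gene-level scoring and the permutation enrichment over a whole
#' collection and returns the z feature vector in panel order.
#'
#' @param inputs result of [pathway_inputs()].
#' @param study an [expression_study()].
#' @param panel ordered pathway ids.
#' @param K permutations per pathway.
#' @param seed integer seed.
#' @return named numeric feature vector (see [feature_vector()]).
#' @export
study_features <- function(inputs, study, panel, K = 1000L, seed = 1L) {
  scores <- gene_scores(study)
  res <- enrich_pathways(inputs$nets, inputs$weights, inputs$dists, scores,
                         K = K, seed = seed)
  feature_vector(panel, res)
}

#' Feature matrix over a set of studies
#'
#' @param inputs result of [pathway_inputs()] for the relevant species.
#' @param studies named list of [expression_study()]s (one per chemical or
#'   data set).
#' @param panel ordered pathway ids fixing column order.
#' @param K permutations per pathway.
#' @param seed master seed; study `i` uses `seed + i`.
#' @return numeric matrix, studies x pathways.
#' @export
build_feature_matrix <- function(inputs, studies, panel, K = 1000L,
                                 seed = 1L) {
  rows <- lapply(seq_along(studies), function(i) {
    study_features(inputs, studies[[i]], panel, K = K, seed = seed + i)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- names(studies)
  X
}

#' End-to-end synthetic pipeline run
#'
#' Generates a synthetic multi-species study, computes pathway features for
#' the reference species, derives the capped poly-3 targets and binary
#' calls from the simulated bioassay, obtains honest nested-CV predictions,
#' fits the final random forest, and (optionally) extrapolates to another
#' species' panel. This is the package's main computation.
#'
#' @param config a [generator_config()].
#' @param K permutations per pathway (default 1000 for simulation studies).
#' @param method super-learner path for honest predictions.
#' @param library learner library (default [default_learner_library()]).
#' @param cross_species optional species token to extrapolate to.
#' @return list: `truth`, `features`, `targets` (capped z), `calls` (data
#'   frame from [binary_call()]), `folds`, `honest` (see
#'   [honest_predictions()]), `auc` (honest predictions vs bioassay calls),
#'   `model` ([fit_final()]), and when requested `cross` with `features`,
#'   `predictions`, `labels`, `auc`.
#' @export
run_pipeline <- function(config, K = 1000L, method = "discrete",
                         library = default_learner_library(),
                         cross_species = NULL) {
  truth <- generate_study(config)
  db <- truth$db
  inputs <- pathway_inputs(db$collections[[db$reference]])
  X <- build_feature_matrix(inputs, truth$studies, db$panel, K = K,
                            seed = config$seed + 10L)
  calls <- do.call(rbind, lapply(truth$bioassay, binary_call))
  targets <- stats::setNames(calls$z_capped, calls$chemical_id)[rownames(X)]
  folds <- make_folds(targets, n_folds = 5L, seed = config$seed + 2L)
  honest <- honest_predictions(library, X, targets, folds,
                               seed = config$seed + 3L, method = method)
  auc <- if (length(unique(calls$call)) == 2L) {
    roc_auc(labeled_scores(calls$chemical_id,
                           honest$predictions[calls$chemical_id],
                           calls$call))
  } else NA_real_
  model <- fit_final(X, targets, seed = config$seed + 4L)
  out <- list(truth = truth, features = X, targets = targets, calls = calls,
              folds = folds, honest = honest, auc = auc, model = model)
  if (!is.null(cross_species)) {
    panel_sp <- generate_cross_species_panel(truth, cross_species)
    inputs_sp <- pathway_inputs(panel_sp$collection)
    X_sp <- build_feature_matrix(inputs_sp, panel_sp$studies, db$panel,
                                 K = K, seed = config$seed + 500L)
    preds_sp <- predict_panel(model, X_sp)
    out$cross <- list(species = cross_species, features = X_sp,
                      predictions = preds_sp, labels = panel_sp$labels,
                      auc = roc_auc(labeled_scores(names(preds_sp), preds_sp,
                                                   panel_sp$labels[names(preds_sp)])))
  }
  out
}
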