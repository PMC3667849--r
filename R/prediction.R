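#' Learner specification
#'
#' A learner is a name plus a `fit(X, y, seed)` function returning a
#' prediction function `function(newX) -> numeric`. All learners consume a
#' chemicals x pathways feature matrix and a continuous carcinogenicity
#' target.
#'
#' @param name character name (unique within a library).
#' @param fit function of `(X, y, seed)` returning a predictor closure.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(name, fit) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fit))
  structure(list(name = name, fit = fit), class = "learner_spec")
}

#' Random-forest regression learner
#'
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(ncol(X)))`.
#' @return a [learner_spec()].
#' @export
learner_random_forest <- function(ntree = 500L, mtry = NULL) {
  learner_spec("random_forest", function(X, y, seed) {
    m <- local_seed(seed, randomForest::randomForest(
      x = X, y = y, ntree = ntree,
      mtry = mtry %||% max(1L, floor(sqrt(ncol(X))))))
    function(newX) unname(stats::predict(m, newX))
  })
}

#' Support-vector regression learner (radial kernel, eps-regression)
#'
#' @param cost,epsilon `e1071::svm` hyperparameters.
#' @return a [learner_spec()].
#' @export
learner_svr <- function(cost = 1, epsilon = 0.1) {
  learner_spec("svr", function(X, y, seed) {
    m <- e1071::svm(x = X, y = y, type = "eps-regression",
                    kernel = "radial", cost = cost, epsilon = epsilon)
    function(newX) unname(stats::predict(m, newX))
  })
}

#' Ridge (L2-penalized linear) regression learner
#'
#' The penalty is chosen by an internal seeded cross-validation over the
#' default glmnet lambda path.
#'
#' @return a [learner_spec()].
#' @export
learner_ridge <- function() {
  learner_spec("ridge", function(X, y, seed) {
    m <- local_seed(seed, glmnet::cv.glmnet(
      x = X, y = y, alpha = 0, nfolds = min(5L, length(y))))
    function(newX) as.numeric(stats::predict(m, newX, s = "lambda.min"))
  })
}

#' Default learner library
#'
#' Random forest, support-vector regression and ridge regression. The forest
#' is the learner the final model path relies on; the others exist so the
#' super learner has a genuine selection to make.
#'
#' @param rf_ntree trees for the random-forest member.
#' @return list of [learner_spec()] objects.
#' @export
default_learner_library <- function(rf_ntree = 500L) {
  list(learner_random_forest(ntree = rf_ntree), learner_svr(), learner_ridge())
}

#' Target-balanced cross-validation folds
#'
#' Chemicals are sorted by target value (ties broken by a seeded random
#' order) and dealt into folds serpentine-style (1..k, k..1, 1..k, ...), so
#' every fold receives a comparable mix of high and low carcinogenicity
#' values — the serpentine reversal pairs each stratum's top values with the
#' previous stratum's bottom values. Fold sizes differ by at most one, and
#' the assignment is deterministic given the seed.
#'
#' @param targets named numeric vector (chemical id -> target value).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed (randomizes only tie order).
#' @return named integer vector mapping chemical id to fold index.
#' @export
make_folds <- function(targets, n_folds = 5L, seed = 1L) {
  stopifnot(is.numeric(targets), !is.null(names(targets)))
  n <- length(targets)
  if (n < n_folds) stop("fewer chemicals (", n, ") than folds (", n_folds, ")")
  ord <- local_seed(seed, order(-targets, sample.int(n)))
  ids <- names(targets)[ord]
  serp <- rep_len(c(seq_len(n_folds), rev(seq_len(n_folds))), n)
  stats::setNames(serp, ids)[names(targets)]
}

#' Cross-validated risk of each learner
#'
#' For every learner, fits on each fold's complement and scores the
#' out-of-fold predictions; the risk is the mean squared error over all
#' chemicals. A learner that fails on any fold is marked failed, excluded
#' from selection, and logged.
#'
#' @param library list of [learner_spec()]s.
#' @param X feature matrix (rownames = chemical ids).
#' @param y named numeric targets matching `X` rows.
#' @param folds fold assignment from [make_folds()].
#' @param seed integer seed for learner fits.
#' @return list: `risks` (named, `NA` for failed learners), `oof` (matrix of
#'   out-of-fold predictions, chemicals x learners), `failed` (character),
#'   `failures` (named list of error messages).
#' @export
cv_risk <- function(library, X, y, folds, seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X),
            identical(names(folds), rownames(X)) || setequal(names(folds), rownames(X)))
  folds <- folds[rownames(X)]
  lnames <- vapply(library, function(l) l$name, character(1L))
  oof <- matrix(NA_real_, nrow = nrow(X), ncol = length(library),
                dimnames = list(rownames(X), lnames))
  failures <- list()
  for (j in seq_along(library)) {
    ok <- TRUE
    for (f in sort(unique(folds))) {
      test <- folds == f
      pred <- tryCatch(
        library[[j]]$fit(X[!test, , drop = FALSE], y[!test],
                         seed = seed + f)(X[test, , drop = FALSE]),
        error = function(e) e)
      if (inherits(pred, "error")) {
        failures[[lnames[j]]] <- conditionMessage(pred)
        ok <- FALSE
        break
      }
      oof[test, j] <- pred
    }
    if (!ok) oof[, j] <- NA_real_
  }
  risks <- apply(oof, 2L, function(p) mean((p - y)^2))
  failed <- lnames[is.na(risks)]
  if (length(failed) > 0L) {
    message("learners failed and were excluded: ", paste(failed, collapse = ", "))
  }
  list(risks = risks, oof = oof, failed = failed, failures = failures)
}

#' Discrete super learner: pick the minimum-risk learner
#'
#' @param risks named numeric vector of cross-validated risks (`NA` =
#'   failed). Ties break in library (vector) order.
#' @return the selected learner name.
#' @export
discrete_super_learner <- function(risks) {
  ok <- which(!is.na(risks))
  if (length(ok) == 0L) stop("all learners failed; nothing to select")
  names(risks)[ok[which.min(risks[ok])]]
}

#' Continuous super learner: non-negative ensemble weights
#'
#' Finds non-negative weights minimizing the squared error of the weighted
#' combination of out-of-fold predictions, then normalizes them to sum to 1.
#' Zero-weight learners drop out of the final ensemble. If the problem is
#' degenerate (no variation to fit, or the NNLS solution is identically
#' zero), uniform weights are returned with a warning.
#'
#' @param oof matrix of out-of-fold predictions (chemicals x learners).
#' @param y numeric targets.
#' @return named weight vector (non-negative, sums to 1).
#' @export
continuous_super_learner <- function(oof, y) {
  stopifnot(is.matrix(oof), nrow(oof) == length(y))
  keep <- !apply(oof, 2L, anyNA)
  if (!any(keep)) stop("all learners failed; no ensemble possible")
  A <- oof[, keep, drop = FALSE]
  w <- rep(0, ncol(oof))
  names(w) <- colnames(oof)
  degenerate <- all(apply(A, 2L, stats::sd) == 0)
  if (!degenerate) {
    sol <- tryCatch(pracma::lsqnonneg(A, as.numeric(y))$x,
                    error = function(e) NULL)
    if (!is.null(sol) && sum(sol) > 0) {
      w[keep] <- sol / sum(sol)
      return(w)
    }
  }
  warning("degenerate ensemble problem; returning uniform weights")
  w[keep] <- 1 / sum(keep)
  w
}

refit_selection <- function(library, X, y, selection, seed) {
  lnames <- vapply(library, function(l) l$name, character(1L))
  if (is.character(selection)) {
    pred <- library[[match(selection, lnames)]]$fit(X, y, seed)
    return(pred)
  }
  # selection is a weight vector over library names
  active <- names(selection)[selection > 0]
  preds <- lapply(active, function(nm) library[[match(nm, lnames)]]$fit(X, y, seed))
  wts <- selection[active]
  function(newX) {
    p <- vapply(preds, function(f) f(newX), numeric(nrow(newX)))
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    as.numeric(p %*% wts)
  }
}

#' Honest (nested cross-validated) predictions
#'
#' Two levels of cross-validation: for each outer fold, an inner
#' cross-validation on the complement selects the learner (discrete path) or
#' the ensemble weights (continuous path); the selection is then refit on
#' the full complement and used to predict the held-out fold. A chemical's
#' own row — features or target — never enters any fit that predicts it.
#'
#' @param library list of [learner_spec()]s.
#' @param X feature matrix.
#' @param y named numeric targets.
#' @param folds outer fold assignment (fixed, from [make_folds()]).
#' @param seed master seed; inner folds and fits use seeds derived from it.
#' @param method `"discrete"` (default) or `"continuous"` super learner.
#' @return list: `predictions` (named numeric, all chemicals), `selected`
#'   (per outer fold: learner name or weight vector), `inner_risks` (per
#'   outer fold named risk vectors).
#' @export
honest_predictions <- function(library, X, y, folds, seed = 1L,
                               method = c("discrete", "continuous")) {
  method <- match.arg(method)
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (is.null(names(y))) names(y) <- rownames(X)
  folds <- folds[rownames(X)]
  preds <- stats::setNames(rep(NA_real_, nrow(X)), rownames(X))
  selected <- list()
  inner_risks <- list()
  for (f in sort(unique(folds))) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    inner_seed <- seed + 101L * f
    inner_folds <- make_folds(ytr, n_folds = min(5L, length(ytr)),
                              seed = inner_seed)
    cv <- cv_risk(library, Xtr, ytr, inner_folds, seed = inner_seed)
    sel <- if (method == "discrete") {
      discrete_super_learner(cv$risks)
    } else {
      continuous_super_learner(cv$oof, ytr)
    }
    predictor <- refit_selection(library, Xtr, ytr, sel, seed = inner_seed)
    preds[test] <- predictor(X[test, , drop = FALSE])
    selected[[as.character(f)]] <- sel
    inner_risks[[as.character(f)]] <- cv$risks
  }
  list(predictions = preds, selected = selected, inner_risks = inner_risks)
}

#' Fit the final random-forest model with pathway importances
#'
#' Fits a random forest on all chemicals and reports permutation importance
#' per pathway: the mean increase in out-of-bag squared error when the
#' feature column is permuted (unscaled).
#'
#' @param X feature matrix (chemicals x pathways).
#' @param y named numeric targets.
#' @param ntree trees (default 500).
#' @param mtry default `floor(sqrt(ncol(X)))`.
#' @param seed integer seed.
#' @return object of class `carcinopath_model`: list with `forest`, `panel`
#'   (training column order), `importance` (data frame sorted descending),
#'   `seed`.
#' @export
fit_final <- function(X, y, ntree = 500L, mtry = NULL, seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  forest <- local_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = ntree,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(X)))),
    importance = TRUE))
  imp <- randomForest::importance(forest, type = 1L, scale = FALSE)[, 1L]
  imp_df <- data.frame(pathway_id = names(imp), importance = unname(imp),
                       stringsAsFactors = FALSE)
  imp_df <- imp_df[order(-imp_df$importance, imp_df$pathway_id), ]
  imp_df$rank <- seq_len(nrow(imp_df))
  rownames(imp_df) <- NULL
  structure(list(forest = forest, panel = colnames(X),
                 importance = imp_df, seed = seed),
            class = "carcinopath_model")
}

#' Predict a (possibly cross-species) feature panel
#'
#' @param model a `carcinopath_model` from [fit_final()].
#' @param X_new feature matrix whose columns are the training pathway panel.
#'   A column-set mismatch is an error listing missing and extra pathways.
#' @return named numeric predictions, proxies for the continuous
#'   carcinogenicity statistic.
#' @export
predict_panel <- function(model, X_new) {
  stopifnot(inherits(model, "carcinopath_model"), is.matrix(X_new))
  missing <- setdiff(model$panel, colnames(X_new))
  extra <- setdiff(colnames(X_new), model$panel)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop("feature columns do not match the training panel; missing: [",
         paste(missing, collapse = ", "), "]; extra: [",
         paste(extra, collapse = ", "), "]")
  }
  X_new <- X_new[, model$panel, drop = FALSE]
  stats::setNames(as.numeric(stats::predict(model$forest, X_new)),
                  rownames(X_new))
}
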