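test_that("folds are balanced, sized correctly, and deterministic", {
  targets26 <- stats::setNames(stats::rnorm(26), sprintf("c%02d", 1:26))
  f <- make_folds(targets26, 5, seed = 4)
  expect_equal(as.integer(sort(table(f))), c(5L, 5L, 5L, 5L, 6L))
  expect_true(all((26L - table(f)) %in% c(20L, 21L)))
  expect_identical(f, make_folds(targets26, 5, seed = 4))

  targets10 <- stats::setNames(as.numeric(1:10), paste0("c", 1:10))
  f10 <- make_folds(targets10, 5, seed = 1)
  means <- tapply(targets10, f10, mean)
  expect_true(all(abs(means - mean(targets10)) <= 1.5))

  expect_error(make_folds(targets10[1:3], 5), "fewer chemicals")
})

test_that("cross-validated risk matches a hand-computed fold-mean oracle", {
  set.seed(8)
  X <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(paste0("c", 1:20), paste0("P", 1:4)))
  y <- stats::setNames(rnorm(20), rownames(X))
  folds <- make_folds(y, 5, seed = 2)
  cv <- cv_risk(list(learner_mean()), X, y, folds)
  want <- mean(vapply(seq_len(20), function(i) {
    (mean(y[folds != folds[i]]) - y[i])^2
  }, numeric(1)))
  expect_equal(unname(cv$risks["mean"]), want)
})

test_that("a linear learner wins on exactly linear targets", {
  set.seed(12)
  X <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(paste0("c", 1:20), paste0("P", 1:3)))
  y <- stats::setNames(2 * X[, 1L] + 1, rownames(X))
  folds <- make_folds(y, 5, seed = 3)
  cv <- cv_risk(list(learner_mean(), learner_ols1()), X, y, folds)
  expect_lt(cv$risks[["ols1"]], 1e-20)
  expect_equal(discrete_super_learner(cv$risks), "ols1")

  # duplicate learner entries give identical risks under identical seeds
  cv2 <- cv_risk(list(learner_ols1("a"), learner_ols1("b")), X, y, folds)
  expect_equal(unname(cv2$risks["a"]), unname(cv2$risks["b"]))
})

test_that("failing learners are excluded and logged", {
  X <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(paste0("c", 1:10), NULL))
  y <- stats::setNames(rnorm(10), rownames(X))
  folds <- make_folds(y, 5, seed = 1)
  boom <- learner_spec("boom", function(X, y, seed) stop("nope"))
  expect_message(cv <- cv_risk(list(boom, learner_mean()), X, y, folds),
                 "excluded: boom")
  expect_true(is.na(cv$risks[["boom"]]))
  expect_equal(discrete_super_learner(cv$risks), "mean")
  expect_error(discrete_super_learner(c(a = NA_real_)), "all learners failed")
})

test_that("discrete selection takes the minimum with library-order ties", {
  expect_equal(discrete_super_learner(c(A = 1.0, B = 0.5)), "B")
  expect_equal(discrete_super_learner(c(A = 0.5, B = 0.5)), "A")
  expect_equal(discrete_super_learner(c(only = 2)), "only")
})

test_that("continuous super-learner weights are a simplex NNLS solution", {
  set.seed(30)
  y <- rnorm(15)
  noise <- rnorm(15)
  oof <- cbind(exact = y, junk = noise)
  w <- continuous_super_learner(oof, y)
  expect_equal(unname(w["exact"]), 1, tolerance = 1e-6)

  # symmetric equal-magnitude opposite errors: 0.5/0.5 recovers y exactly
  e <- stats::residuals(stats::lm(noise ~ y))  # orthogonal to y
  oof2 <- cbind(up = y + e, down = y - e)
  w2 <- continuous_super_learner(oof2, y)
  expect_equal(unname(w2), c(0.5, 0.5), tolerance = 1e-6)

  for (rep in 1:10) {
    oofr <- matrix(rnorm(30), 10, 3)
    wr <- suppressWarnings(continuous_super_learner(oofr, rnorm(10)))
    expect_true(all(wr >= 0))
    expect_equal(sum(wr), 1)
  }

  expect_warning(wu <- continuous_super_learner(
    cbind(a = rep(1, 5), b = rep(2, 5)), rnorm(5)), "uniform")
  expect_equal(unname(wu), c(0.5, 0.5))
})

test_that("honest predictions never see the held-out chemical's target", {
  set.seed(44)
  X <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(paste0("c", 1:15), paste0("P", 1:6)))
  y <- stats::setNames(rnorm(15), rownames(X))
  folds <- make_folds(y, 5, seed = 6)
  lib <- list(learner_mean(), learner_ols1())
  base <- honest_predictions(lib, X, y, folds, seed = 9)

  for (f in 1:5) {
    y2 <- y
    y2[folds == f] <- y2[folds == f] + 100  # wreck the held-out targets
    pert <- honest_predictions(lib, X, y2, folds, seed = 9)
    expect_identical(pert$predictions[folds == f],
                     base$predictions[folds == f])
  }

  # continuous path obeys the same honesty property (uniform-weight
  # fallback warnings on noise targets are expected and irrelevant here)
  base_c <- suppressWarnings(honest_predictions(lib, X, y, folds, seed = 9,
                                                method = "continuous"))
  y3 <- y; y3[folds == 2] <- -50
  pert_c <- suppressWarnings(honest_predictions(lib, X, y3, folds, seed = 9,
                                                method = "continuous"))
  expect_identical(pert_c$predictions[folds == 2],
                   base_c$predictions[folds == 2])
})

test_that("final forest importance singles out the driving pathway", {
  set.seed(17)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("c", 1:30), paste0("P", 1:8)))
  X[, 3L] <- X[, 3L] * 2
  y <- stats::setNames(X[, 3L], rownames(X))
  fit <- fit_final(X, y, ntree = 300, seed = 5)
  expect_equal(fit$importance$pathway_id[1L], "P3")

  Xc <- X; Xc[, 5L] <- 1  # constant feature carries no information
  fitc <- fit_final(Xc, y, ntree = 300, seed = 5)
  imp5 <- fitc$importance$importance[fitc$importance$pathway_id == "P5"]
  expect_lt(abs(imp5), 1e-8)

  fit2 <- fit_final(X, y, ntree = 300, seed = 5)
  expect_equal(fit$importance, fit2$importance)
})

test_that("panel prediction enforces column identity and permutes with rows", {
  set.seed(23)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(paste0("c", 1:20), paste0("P", 1:5)))
  y <- stats::setNames(X[, 1L] + rnorm(20, sd = 0.1), rownames(X))
  fit <- fit_final(X, y, ntree = 200, seed = 2)

  preds <- predict_panel(fit, X)
  expect_gt(stats::cor(preds, y), 0.5)

  perm <- sample(nrow(X))
  expect_equal(unname(predict_panel(fit, X[perm, ])), unname(preds[perm]))

  Xbad <- X[, -2L]
  expect_error(predict_panel(fit, Xbad), "missing: \\[P2\\]")
  Xextra <- cbind(X, P9 = rnorm(20))
  expect_error(predict_panel(fit, Xextra), "extra: \\[P9\\]")

  # columns in a different order are accepted and realigned
  expect_equal(predict_panel(fit, X[, c(3, 1, 2, 5, 4)]), preds)
})

test_that("discrete selection risk is never worse than the worst learner", {
  set.seed(61)
  X <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(paste0("c", 1:20), paste0("P", 1:4)))
  y <- stats::setNames(X[, 2L] + rnorm(20, sd = 0.5), rownames(X))
  folds <- make_folds(y, 5, seed = 7)
  cv <- cv_risk(list(learner_mean(), learner_ols1(), learner_ridge()),
                X, y, folds, seed = 3)
  sel <- discrete_super_learner(cv$risks)
  expect_lte(cv$risks[[sel]], max(cv$risks, na.rm = TRUE))
  # continuous combination: in-sample combined risk <= best single oof risk
  w <- continuous_super_learner(cv$oof, y)
  comb <- as.numeric(cv$oof %*% w)
  expect_lte(mean((comb - y)^2), min(cv$risks, na.rm = TRUE) + 1e-12)
})
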