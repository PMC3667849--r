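#!/usr/bin/env Rscript

# Step 4: evaluate. Within-species ROC/AUC of the honest predictions
# against the bioassay calls, cross-species extrapolation to the rat panel,
# operating points in the 56-75% specificity window with confusion lists,
# and dose-response slopes for a small dose series. Also verifies the
# published-table arithmetic (mouse and human operating points).

suppressPackageStartupMessages(library(carcinopath))

seed <- 1L
out <- "results"

cfg <- generator_config(seed = seed)
truth <- generate_study(cfg)
db <- truth$db

bio <- utils::read.delim(file.path(out, "simulated", "bioassay.tsv"))
hp_df <- utils::read.delim(file.path(out, "honest_predictions.tsv"))
preds <- stats::setNames(hp_df$predicted_z, hp_df$chemical_id)

## within-species ROC ------------------------------------------------------
ls_m <- labeled_scores(bio$chemical_id, preds[bio$chemical_id], bio$call)
auc_m <- roc_auc(ls_m)
op <- operating_point(ls_m, spec_range = c(0.56, 0.75))
cat(sprintf("Within-species honest AUC: %.3f\n", auc_m))
cat(sprintf("Operating point: sens %.2f, spec %.2f (%d FP, %d FN)\n",
            op$sensitivity, op$specificity,
            length(op$false_positive_ids), length(op$false_negative_ids)))
utils::write.table(roc_points(ls_m), file.path(out, "roc_mouse.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## cross-species extrapolation ---------------------------------------------
Xdf <- utils::read.delim(file.path(out, "feature_matrix_mouse.tsv"),
                         check.names = FALSE)
X <- as.matrix(Xdf[, -1L]); rownames(X) <- Xdf$chemical_id
targets <- stats::setNames(bio$z_capped, bio$chemical_id)[rownames(X)]
model <- fit_final(X, targets, seed = seed + 4L)

rat <- generate_cross_species_panel(truth, "rat")
inputs_rat <- pathway_inputs(rat$collection)
X_rat <- build_feature_matrix(inputs_rat, rat$studies, db$panel,
                              K = 1000L, seed = seed + 500L)
preds_rat <- predict_panel(model, X_rat)
auc_rat <- roc_auc(labeled_scores(names(preds_rat), preds_rat,
                                  rat$labels[names(preds_rat)]))
cat(sprintf("Cross-species (rat) AUC: %.3f\n", auc_rat))
utils::write.table(data.frame(chemical_id = names(preds_rat),
                              predicted_z = preds_rat,
                              label = rat$labels[names(preds_rat)]),
                   file.path(out, "predictions_rat.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## published-table operating points ----------------------------------------
cl <- reference_confusion_lists()
op_pub <- operating_point(confusion_fixture_scores(
  mouse_chemical_labels(),
  cl$id[cl$species == "mouse" & cl$type == "false_positive"],
  cl$id[cl$species == "mouse" & cl$type == "false_negative"]))
hp <- human_risk_panel()
op_hum <- operating_point(confusion_fixture_scores(
  stats::setNames(hp$label, hp$id),
  cl$id[cl$species == "human" & cl$type == "false_positive"],
  cl$id[cl$species == "human" & cl$type == "false_negative"]))
cat(sprintf("Published mouse row reproduced: sens %.2f, spec %.2f\n",
            op_pub$sensitivity, op_pub$specificity))
cat(sprintf("Published human row reproduced: sens %.2f, spec %.2f\n",
            op_hum$sensitivity, op_hum$specificity))

## dose-response slopes -----------------------------------------------------
series <- generate_dose_series(truth)
inputs <- pathway_inputs(db$collections[[db$reference]])
slopes <- do.call(rbind, lapply(names(series), function(cid) {
  st <- series[[cid]]
  Xd <- build_feature_matrix(inputs, st$studies, db$panel, K = 1000L,
                             seed = seed + 700L + match(cid, names(series)))
  zd <- predict_panel(model, Xd)
  sl <- dose_slope(st$doses, zd)
  data.frame(chemical_id = cid,
             carcinogen = truth$chemicals$carcinogen[
               match(cid, truth$chemicals$chemical_id)],
             slope = sl$slope, p_one_sided = sl$p_one_sided)
}))
utils::write.table(slopes, file.path(out, "dose_response_slopes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Dose-response slopes (predicted z per unit MTD fraction):\n")
print(slopes, row.names = FALSE)
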