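#!/usr/bin/env Rscript
# Step 6: track cells, call fates, and fit the logistic fate model.
#
# Links per-frame cell records into tracks (optimal centroid matching),
# applies the >=6-consecutive-frame quality filter, calls terminal fate
# by Sytox co-localization with the extended cell region, extracts each
# cell's OxD 40 min post treatment, and fits the logistic model whose
# 50%-probability boundary is the OxD death threshold.

suppressMessages(library(redoxtrack))

stack <- read_image_stack("scratch/imaging/timelapse.tif")
calib <- read_calibration("results/calibration_imaging.yaml")
an <- analyze_stack(stack, calib)
tr <- track_cells(an)

write_event_table(tr$tracks, "results/tracks.csv")
cat(sprintf("%d tracks (%d resolved, %d unresolved)\n",
            nrow(tr$tracks), sum(tr$tracks$resolved),
            sum(!tr$tracks$resolved)))
print(table(fate = tr$tracks$fate))

# single-field fate model (the acceptance script pools 13 such fields
# to reach the N >= 250 cells used for the headline numbers)
truth <- read_ground_truth("results/imaging_truth_cells.csv")
cat(sprintf("\nGround truth: %d dead of %d cells\n",
            sum(truth$dead), nrow(truth)))
if (nrow(tr$fates) >= 20 && length(unique(tr$fates$died)) == 2) {
  model <- fit_logistic(tr$fates$decision_oxd, tr$fates$died)
  print(model)
  score <- classify_and_score(model, tr$fates$decision_oxd, tr$fates$died)
  cat(sprintf("accuracy %.1f%%, FP %.1f%%, FN %.1f%% (of %d cells)\n",
              100 * score$accuracy, 100 * score$fp_rate,
              100 * score$fn_rate, score$n))
  jsonlite::write_json(
    list(beta0 = model$beta0, beta1 = model$beta1,
         threshold_oxd = model$threshold_oxd,
         separation = model$separation,
         accuracy = score$accuracy, fp_rate = score$fp_rate,
         fn_rate = score$fn_rate, n = score$n),
    "results/fate_model.json", auto_unbox = TRUE, digits = NA)
} else {
  cat("too few resolved cells in one field for a stable fit;",
      "see scripts/acceptance.R for the pooled multi-field model\n")
}
write_event_table(tr$fates, "results/fates.csv")
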