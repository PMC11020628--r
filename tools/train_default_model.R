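# Regenerates the packaged merge model (inst/extdata/merge_model.json).
# Run from the repository root: Rscript tools/train_default_model.R
# The training world: several LTR families at 6-15% divergence with a low
# indel rate (indels fragment score stretches, which is exactly what the
# classifier must learn to repair), on semi-synthetic genomes whose
# inter-element regions are shuffled.

library(ltrscout)

train_world <- function(seed) {
  specs <- list(
    plant_spec("A", ltr_length = 600, internal_length = 3000,
               ltr_divergence = 0.10, family_divergence = 0.12,
               copy_number = 4, indel_rate = 0.003),
    plant_spec("B", ltr_length = 350, internal_length = 1800,
               ltr_divergence = 0.15, family_divergence = 0.10,
               copy_number = 4, indel_rate = 0.003, sequential_run = 2),
    plant_spec("C", ltr_length = 1200, internal_length = 4000,
               ltr_divergence = 0.06, family_divergence = 0.08,
               copy_number = 3, indel_rate = 0.002, solo_count = 1),
    plant_spec("D", ltr_length = 250, internal_length = 2500,
               ltr_divergence = 0.12, family_divergence = 0.15,
               copy_number = 4, indel_rate = 0.004),
    # low-divergence layouts with nearby same-family copies: these produce
    # consecutive stretch pairs separated by a whole internal part (the 3'
    # LTR pointing onward to a solo or the next element), i.e. the
    # must-not-merge negatives
    plant_spec("E", ltr_length = 500, internal_length = 2000,
               ltr_divergence = 0.02, family_divergence = 0.05,
               copy_number = 3, solo_count = 2),
    plant_spec("F", ltr_length = 400, internal_length = 1500,
               ltr_divergence = 0.03, family_divergence = 0.05,
               copy_number = 4, sequential_run = 4))
  ts <- generate_genome(specs, 8e5, seed = seed,
                        sequence_id = paste0("train", seed))
  ss <- make_semisynthetic(ts$genome, ts$annotations, seed = seed)
  merge_training_data(list(genome = ss, annotations = ts$annotations))
}

feats <- NULL; labs <- logical(0)
for (seed in 11:18) {
  td <- train_world(seed)
  feats <- rbind(feats, td$features)
  labs <- c(labs, td$labels)
  message(sprintf("seed %d: %d pairs (%d positive)", seed,
                  nrow(td$features), sum(td$labels)))
}
message(sprintf("total: %d pairs, %.1f%% positive", length(labs),
                100 * mean(labs)))

model <- train_merge_model(feats, labs, seed = 7, n_iter = 60)
print(model$hyperparameters)
message(sprintf("cv F1 %.3f | validation F1 %.3f | test R %.3f P %.3f F1 %.3f",
                model$cv_f1, model$validation_f1,
                model$test_metrics["recall"], model$test_metrics["precision"],
                model$test_metrics["f1"]))
write_merge_model(model, "inst/extdata/merge_model.json")
message("wrote inst/extdata/merge_model.json")
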