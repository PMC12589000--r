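#!/usr/bin/env Rscript
# Stage 4 — train the 5'UTR mean-ribosome-load CNN and screen candidates.
#
# The regressor (three 1D conv layers, the last single-channel, then two
# fully-connected layers) is trained on the synthetic library with an 8:2
# train/validation split and best-epoch selection on validation R^2. The
# trained model then scores the 222-sequence candidate pool (212
# literature-style + 8 Kozak variants + alpha-globin + BNT162b2-type) and
# the top-10 table is written with uAUG/uORF annotation.

library(mevax)

seed <- 20260930L
lib <- read_mrl_csv("results/mrl_library.csv")
lib <- split_mrl_dataset(lib, ratio = c(0.8, 0.2), seed = seed)

config <- mrl_model_config(filters = 64L, kernel_size = 8L,
                           fc_hidden = 128L, epochs = 30L,
                           batch_size = 128L, learning_rate = 1e-3,
                           seed = seed)
model <- train_mrl_model(lib, config, embedding_spec(max_length = 75L),
                         verbose = TRUE)
message(sprintf("best epoch %d: validation R2 %.3f, MSE %.3f, MAE %.3f, RMSE %.3f",
                model$best_epoch, model$best_metrics$r2,
                model$best_metrics$mse, model$best_metrics$mae,
                model$best_metrics$rmse))
write.csv(model$history, "results/mrl_training_history.csv",
          row.names = FALSE)

pool <- build_candidate_pool(reference_pool_sources(seed = seed + 1L))
pool <- predict_mrl(model, pool)
top <- rank_candidates(pool, 10L)
scan <- lapply(top$sequence, scan_uaug_uorf)
top$uaug_count <- vapply(scan, `[[`, integer(1), "uaug_count")
top$uorf_count <- vapply(scan, `[[`, integer(1), "uorf_count")
write.table(top, "results/utr_top10.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message(sprintf("pool of %d screened; winner %s (predicted MRL %.3f, %d uAUG)",
                nrow(pool), top$id[1], top$predicted_mrl[1],
                top$uaug_count[1]))
writeLines(top$sequence[1], "results/utr_selected.txt")
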