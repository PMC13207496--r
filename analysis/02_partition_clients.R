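#!/usr/bin/env Rscript
# Partition the training split across eight simulated clients, under IID
# and under the composed non-IID scheme (Dirichlet label skew, log-normal
# quantity skew, per-client feature skew). Writes manifests and summaries
# under results/partition, plus the packaged reference client table.

suppressMessages(library(fldpsim))
out_dir <- "results/partition"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

prof <- desk_profile(seed = 1)
samples <- generate_dataset(prof$dataset)
split <- split_dataset(samples, seed = derive_seed(1, "split"))
samples <- apply_split(samples, split)
tags <- vapply(samples, function(s) s$split_tag, character(1))
train <- samples[tags == "train"]
ids <- vapply(train, function(s) s$sample_id, character(1))
labels <- sample_labels(train)

for (mode in c("iid", "noniid")) {
  pc <- prof$partition
  pc$mode <- mode
  m <- partition_clients(ids, labels, pc)
  sm <- summarize_partition(m, stats::setNames(labels, ids))
  write_manifests(m, file.path(out_dir, mode))
  write.csv(sm, file.path(out_dir, paste0("summary_", mode, ".csv")),
            row.names = FALSE)
  message("\n", mode, " partition of ", length(ids), " training samples:")
  print(sm, row.names = FALSE)
}

# reference realization of the emulated full-size non-IID federation
fx <- fixture_client_table()
sm_fx <- summarize_partition(fx$manifests, fx$labels)
write.csv(sm_fx, file.path(out_dir, "summary_reference_cohort.csv"),
          row.names = FALSE)
message("\nreference full-cohort client table (sizes ",
        min(fx$counts$total), "-", max(fx$counts$total), ", total ",
        sum(fx$counts$total), "):")
print(sm_fx, row.names = FALSE)
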