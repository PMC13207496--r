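#!/usr/bin/env Rscript
# Generate the desk-scale phantom cohort, derive the three classification
# tasks, and apply the image-level 80/10/10 split. Writes the dataset
# manifest, the spec, and a task/split summary under results/data.

suppressMessages(library(fldpsim))
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

prof <- desk_profile(seed = 1)
message("generating ", prof$dataset$n_normal + prof$dataset$n_benign +
          prof$dataset$n_malignant, " phantoms at ",
        prof$dataset$image_size, "x", prof$dataset$image_size, " ...")
samples <- generate_dataset(prof$dataset)
split <- split_dataset(samples, seed = derive_seed(1, "split"))
samples <- apply_split(samples, split)

write_dataset(samples, out_dir)
write_dataset_spec(prof$dataset, file.path(out_dir, "dataset_spec.yaml"))

tags <- vapply(samples, function(s) s$split_tag, character(1))
task_rows <- lapply(c("screen", "diagnose", "threeclass"), function(task) {
  v <- construct_task(samples, task)
  data.frame(task = task, n_samples = length(v$labels),
             classes = paste(sprintf("%s=%d", names(table(v$labels)),
                                     table(v$labels)), collapse = " "))
})
summary <- do.call(rbind, task_rows)
write.csv(summary, file.path(out_dir, "task_summary.csv"), row.names = FALSE)

message("split sizes: ", paste(names(table(tags)), table(tags),
                               sep = "=", collapse = " "))
message("task views:")
print(summary)

# the emulated full-size cohort arithmetic, for reference
message("full-cohort screen arithmetic: normal=5283, abnormal=",
        6847 + 3717, ", total=", 5283 + 6847 + 3717)
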