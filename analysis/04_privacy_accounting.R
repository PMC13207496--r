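#!/usr/bin/env Rscript
# Closed-form privacy accounting and the communication-cost model: the
# budget table over the studied noise multipliers (basic and sublinear
# composition over the nominal 12,500 per-client steps) and the per-round
# cost of the seven reference architectures at K = 8 clients.

suppressMessages(library(fldpsim))
out_dir <- "results/accounting"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

budget <- budget_table(c(0.5, 1.0, 1.5, 2.0, 3.0),
                       dp = dp_config(C = 1.5, delta = 1e-5),
                       R = 100, E = 5, batches = 25)
write.csv(budget, file.path(out_dir, "budget_table.csv"), row.names = FALSE)
message("privacy budgets over T = ", steps_count(100, 5, 25),
        " steps (delta = 1e-5, C = 1.5):")
print(transform(budget, eps_step = round(eps_step, 4),
                eps_basic = round(eps_basic),
                eps_sublinear = round(eps_sublinear, 1)), row.names = FALSE)

# manifest-derived step counts for the reference client sizes
fx <- fixture_client_table()
steps <- data.frame(
  client = fx$counts$client, n_k = fx$counts$total,
  batches = batches_per_epoch(fx$counts$total, 32),
  T_steps = steps_count(100, 5, pmax(1, batches_per_epoch(fx$counts$total, 32))))
write.csv(steps, file.path(out_dir, "per_client_steps.csv"), row.names = FALSE)
message("\nper-client step counts at B = 32 (vs the nominal 25 batches/epoch):")
print(steps, row.names = FALSE)

arch <- architecture_meta()
arch$comm_cost_mb <- comm_cost_mb(arch$params_millions, K = 8)
write.csv(arch, file.path(out_dir, "comm_cost_table.csv"), row.names = FALSE)
message("\nper-round communication cost at K = 8 clients:")
print(arch, row.names = FALSE)
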