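#!/usr/bin/env Rscript
# Generate the synthetic 26-kinase panel screen used by the downstream
# analyses: 24 compounds (promiscuous/selective/inactive mix), single-point
# profile at 100 uM, follow-up dose-response curves, with ground truth.

library(fragscreen)

out <- "results/synthetic_screen"
cfg <- sim_config(seed = 20180715, n_compounds = 24)
bundle <- run_simulate(cfg, out, force = TRUE)

cat("Synthetic screen written to", out, "\n")
cat(sprintf("  %d compounds x %d kinases; %d missing cells in the profile\n",
            nrow(bundle$truth$true_pki), ncol(bundle$truth$true_pki),
            sum(is.na(bundle$profile$inhibition))))
cat(sprintf("  archetypes: %s\n",
            paste(sprintf("%s=%d", names(table(bundle$truth$archetype)),
                          table(bundle$truth$archetype)), collapse = ", ")))
cat(sprintf("  %d dose-response curves (8-pt half-log, triplicate)\n",
            nrow(unique(bundle$curves[c("compound_id", "kinase_id")]))))
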