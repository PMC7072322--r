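#!/usr/bin/env Rscript
# Stage 7: replicate-level calibration studies of the whole stack --
# filter fidelity, background-rate recovery, false-discovery control
# under the null, spiked-driver power, and spectrum composition.
# Replicate counts here are deliberately moderate; the test suite runs
# the full-size versions.
source("analysis/00_config.R")

ff <- experiment_filter_fidelity(sim_config(seed = 20301L))
rr <- experiment_rate_recovery(sim_config(seed = 20302L, n_samples = 10L),
                               nrep = 50L)
fdr <- experiment_fdr_null(sim_config(seed = 20303L, n_samples = 20L),
                           nrep = 50L)
pw <- experiment_driver_power(
  sim_config(seed = 20304L, n_samples = 30L, gene_cds_length = 999L,
             driver_genes = c(G001 = 50)), nrep = 50L)
sp <- experiment_spectrum_modal(sim_config(seed = 20305L,
                                           chromosome_length = 1e5),
                                n_seeds = 5L)

out <- data.frame(
  quantity = c("filter_sensitivity", "filter_artifact_label_exact",
               "rate_recovery_max_abs_z", "fdr_null_zero_fraction",
               "driver_power", "pooled_spectrum_ct_share"),
  value = c(ff$sensitivity, ff$label_exact, max(abs(rr$z)),
            fdr$fraction_zero, pw$power, sp$pooled_ct_fraction))
write.table(out, file.path(RESULTS, "experiments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(out, row.names = FALSE)
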