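# Shared configuration for the analysis scripts. Everything downstream
# of 01_simulate.R is driven by the files under results/, so the whole
# workflow reruns byte-identically from this one seed.
library(earlygc)

RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
COHORT_CONFIG <- sim_config(
  seed = 20260L,
  n_samples = 19L   # discovery-cohort size; remaining parameters are
)                   # the package defaults (see ?sim_config)
MSI_MARKER_PROB <- c(0.35, 0.35, 0.15, 0.15, 0.15)
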