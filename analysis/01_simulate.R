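#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs -- a toy reference with
# gene models, one tumor/normal VCF per patient (true somatic events
# plus labelled filter-failing artifacts), the simulation truth table,
# and a 5-marker Bethesda MSI profile per patient.
source("analysis/00_config.R")

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

gen <- generate_reference(COHORT_CONFIG)
write_reference(gen$reference, file.path(DATA_DIR, "reference.fa"))
write_genes(gen$genes, file.path(DATA_DIR, "genes.gff3"))
write_genes(gen$genes, file.path(DATA_DIR, "genes.tsv"), format = "tsv")

cohort <- simulate_cohort(gen$reference, gen$genes, COHORT_CONFIG)
write_cohort_vcfs(cohort$calls, file.path(DATA_DIR, "vcf"))
write.table(cohort$truth, file.path(DATA_DIR, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

msi <- simulate_msi_profiles(COHORT_CONFIG$n_samples, MSI_MARKER_PROB,
                             seed = COHORT_CONFIG$seed + 77L)
write.table(msi, file.path(DATA_DIR, "msi_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d samples: %d call records (%d true, %d artifacts)",
                COHORT_CONFIG$n_samples, nrow(cohort$calls),
                sum(cohort$truth$class == "true"),
                sum(cohort$truth$class == "artifact")))
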