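#!/usr/bin/env Rscript
# Stage 5: classify each patient's Bethesda 5-marker instability
# profile as MSI-H / MSI-L / MSS.
source("analysis/00_config.R")

prof <- read.delim(file.path(DATA_DIR, "msi_profiles.tsv"))
cls <- classify_msi_panel(prof)
write.table(cls, file.path(RESULTS, "msi.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("MSI classes: %s",
                paste(names(table(cls$msi_class)), table(cls$msi_class),
                      sep = "=", collapse = ", ")))
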