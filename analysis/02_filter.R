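#!/usr/bin/env Rscript
# Stage 2: apply the exome-stage somatic filter to the cohort VCFs and
# audit the rejections against the simulation truth table.
source("analysis/00_config.R")

calls <- read_cohort_vcfs(file.path(DATA_DIR, "vcf"))
report <- filter_exome(calls)
print(report)

dir.create(file.path(RESULTS, "filtered"), showWarnings = FALSE)
write.table(report$kept, file.path(RESULTS, "filtered", "calls_kept.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_filter_sidecar(report, file.path(RESULTS, "filtered",
                                       "calls_rejected.tsv"))

truth <- read.delim(file.path(DATA_DIR, "truth.tsv"))
key <- function(d) paste(d$sample_id, d$chrom, d$pos)
sens <- mean(key(truth[truth$class == "true", ]) %in% key(report$kept))
spec <- mean(key(truth[truth$class == "artifact", ]) %in% key(report$rejected))
message(sprintf("truth sensitivity %.1f%%, artifact rejection %.1f%%",
                100 * sens, 100 * spec))
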