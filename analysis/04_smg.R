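#!/usr/bin/env Rscript
# Stage 4: estimate CpG-aware background mutation rates from the
# non-coding mutations and test every gene for an excess of
# protein-altering mutations (one-sided exact test, BH-adjusted).
source("analysis/00_config.R")

ref <- read_reference(file.path(DATA_DIR, "reference.fa"))
genes <- read_genes(file.path(DATA_DIR, "genes.gff3"), ref = ref)
ann <- read.delim(file.path(RESULTS, "annotated.tsv"))

res <- run_smg(ann, ref, genes, COHORT_CONFIG$n_samples)
write.table(res, file.path(RESULTS, "smg_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(attr(res, "rates")$bins, file.path(RESULTS, "background_bins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(attr(res, "rates"))
message(sprintf("%d of %d genes reach q < %.2f; smallest q = %.3g (%s)",
                sum(res$significant), nrow(res), attr(res, "q_cutoff"),
                res$q_value[1], res$gene_id[1]))
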