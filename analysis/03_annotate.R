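#!/usr/bin/env Rscript
# Stage 3: annotate the filter-passing calls with gene assignment,
# coding effect, CpG status and trinucleotide context; tabulate the
# mutation spectrum and export the 4-column variant list.
source("analysis/00_config.R")

ref <- read_reference(file.path(DATA_DIR, "reference.fa"))
genes <- read_genes(file.path(DATA_DIR, "genes.gff3"), ref = ref)
kept <- read.delim(file.path(RESULTS, "filtered", "calls_kept.tsv"))

ann <- annotate_variants(kept, genes, ref)
write.table(ann, file.path(RESULTS, "annotated.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
export_4col(ann, file.path(RESULTS, "variants_4col.tsv"))

spec <- spectrum_summary(ann)
write.table(data.frame(class = names(spec$class6), count = spec$class6),
            file.path(RESULTS, "spectrum6.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(context = names(spec$class96), count = spec$class96),
            file.path(RESULTS, "spectrum96.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("effects: %s", paste(names(table(ann$effect)),
                                     table(ann$effect), collapse = ", ")))
message(sprintf("modal substitution class: %s (%d of %d SNVs)",
                spec$modal_class, spec$modal_count, sum(spec$class6)))
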