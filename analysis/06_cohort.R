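#!/usr/bin/env Rscript
# Stage 6: cohort-level statistics -- the sample-by-gene mutation
# matrix, per-gene frequencies, recurrence selection, a mutual-
# exclusivity scan of the most frequently mutated genes, and the
# published CagA x LRP1 contingency analyses.
source("analysis/00_config.R")

ref <- read_reference(file.path(DATA_DIR, "reference.fa"))
genes <- read_genes(file.path(DATA_DIR, "genes.gff3"), ref = ref)
ann <- read.delim(file.path(RESULTS, "annotated.tsv"))

ids <- unique(genes$gene_id)
m <- build_matrix(ann, ids,
                  sample_ids = sprintf("S%02d", seq_len(COHORT_CONFIG$n_samples)))
write.table(cbind(sample_id = rownames(m), as.data.frame(m)),
            file.path(RESULTS, "mutation_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(oncoprint_long(m), file.path(RESULTS, "oncoprint_long.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

freq <- gene_frequencies(m)
write.table(freq[order(-freq$frequency_pct), ],
            file.path(RESULTS, "gene_frequencies.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

opp <- count_gene_sites(genes, ref)
sel <- select_recurrent(m, setNames(opp$coding_length, opp$gene_id))
write.table(attr(sel, "details"), file.path(RESULTS, "recurrent_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("recurrently mutated genes (>=4 patients, >10/Mb): %s",
                if (length(sel)) paste(sel, collapse = ", ") else "none"))

# mutual-exclusivity scan over the two most frequently mutated genes
top <- freq$gene_id[order(-freq$n_mutated)][1:2]
me <- mutual_exclusivity(m, top[1], top[2])
rows <- data.frame(comparison = paste(top, collapse = " vs "),
                   a = me$both, b = me$a_only, c = me$b_only, d = me$neither,
                   p_value = me$p_value)

# published immunofluorescence counts: CagA accumulation by LRP1 status
rows <- rbind(rows,
  data.frame(comparison = "CagA accumulation vs LRP1 mutation (all cases)",
             a = 10, b = 4, c = 8, d = 27,
             p_value = fisher_2x2(c(10, 4, 8, 27))),
  data.frame(comparison = "CagA accumulation vs LRP1 mutation (Hp-infected)",
             a = 9, b = 0, c = 6, d = 18,
             p_value = fisher_2x2(c(9, 0, 6, 18))))
write.table(rows, file.path(RESULTS, "association_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("CagA x LRP1: p = %.4g (all cases), p = %.4g (Hp-infected)",
                rows$p_value[2], rows$p_value[3]))
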