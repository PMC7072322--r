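#' Sample-by-gene mutation matrix
#'
#' Counts filtered protein-altering mutations (nonsynonymous SNVs and
#' coding indels) per sample and gene. A variant overlapping several
#' genes is counted in each overlapping gene's column (the `all_genes`
#' annotation), as oncoprint-style matrices conventionally do; burden
#' statistics elsewhere count it once via the primary assignment.
#'
#' @param annotated annotated variant data.frame.
#' @param gene_ids character vector of genes to tabulate (columns).
#' @param sample_ids optional full cohort sample list, so samples with
#'   no passing mutation still appear as zero rows.
#' @return integer matrix, samples x genes.
#' @export
build_matrix <- function(annotated, gene_ids,
                         sample_ids = sort(unique(annotated$sample_id))) {
  pa <- annotated[annotated$effect %in% c("nonsynonymous", "coding_indel"), ,
                  drop = FALSE]
  m <- matrix(0L, nrow = length(sample_ids), ncol = length(gene_ids),
              dimnames = list(sample_ids, gene_ids))
  if (nrow(pa)) {
    gl <- strsplit(pa$all_genes, ",", fixed = TRUE)
    samp <- rep(pa$sample_id, lengths(gl))
    gene <- unlist(gl)
    unknown <- setdiff(gene, gene_ids)
    if (length(unknown)) stop("unknown gene id(s) in cohort: ",
                              paste(unknown, collapse = ", "))
    bad_s <- setdiff(samp, sample_ids)
    if (length(bad_s)) stop("sample(s) not in sample_ids: ",
                            paste(bad_s, collapse = ", "))
    for (k in seq_along(samp)) {
      m[samp[k], gene[k]] <- m[samp[k], gene[k]] + 1L
    }
  }
  m
}

#' Per-gene mutated-sample frequencies
#'
#' Fraction of samples carrying at least one protein-altering mutation,
#' reported in percent with half-up rounding to one decimal
#' (so 14/49 -> 28.6).
#'
#' @param matrix sample-by-gene count matrix from [build_matrix()].
#' @return data.frame: `gene_id`, `n_mutated`, `n_samples`,
#'   `frequency_pct`.
#' @export
gene_frequencies <- function(matrix) {
  if (nrow(matrix) == 0L) stop("mutation matrix has no samples")
  n_mut <- colSums(matrix > 0L)
  data.frame(gene_id = colnames(matrix), n_mutated = as.integer(n_mut),
             n_samples = nrow(matrix),
             frequency_pct = round_half_up(100 * n_mut / nrow(matrix), 1),
             row.names = NULL)
}

#' Select recurrently mutated genes
#'
#' A gene is selected when it is mutated in at least `min_patients`
#' samples (the published rule: more than three patients) and its
#' cohort-aggregate mutation rate exceeds `min_rate_per_mb` mutations
#' per Mb of coding footprint. Both the numerator (total cohort
#' mutations in the gene) and denominator (coding Mb) are reported.
#'
#' @param matrix sample-by-gene count matrix.
#' @param coding_lengths named numeric vector of coding lengths (bp) for
#'   every matrix column.
#' @param min_patients minimum mutated-sample count (inclusive).
#' @param min_rate_per_mb rate threshold (strict).
#' @return character vector of selected gene ids, with the full
#'   per-gene table as attribute `"details"`.
#' @export
select_recurrent <- function(matrix, coding_lengths, min_patients = 4,
                             min_rate_per_mb = 10) {
  genes <- colnames(matrix)
  len <- coding_lengths[genes]
  if (anyNA(len)) stop("coding length missing for gene(s): ",
                       paste(genes[is.na(len)], collapse = ", "))
  if (any(len <= 0)) stop("zero or negative coding length for gene(s): ",
                          paste(genes[len <= 0], collapse = ", "))
  n_patients <- colSums(matrix > 0L)
  n_mutations <- colSums(matrix)
  rate <- n_mutations / (len / 1e6)
  details <- data.frame(gene_id = genes, n_patients = as.integer(n_patients),
                        n_mutations = as.integer(n_mutations),
                        coding_mb = len / 1e6, rate_per_mb = rate,
                        selected = n_patients >= min_patients &
                          rate > min_rate_per_mb,
                        row.names = NULL)
  structure(details$gene_id[details$selected], details = details)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test; the two-sided p-value sums the probabilities
#' of all tables no more probable than the observed one, as is
#' conventional for 2x2 contingency analyses of cohort counts.
#'
#' @param table 2x2 numeric matrix, or `c(a, b, c, d)` filled by row.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (on the
#'   odds ratio of the `[1,1]` cell).
#' @return the p-value.
#' @export
fisher_2x2 <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(table)) {
    if (length(table) != 4L) stop("table must be a 2x2 matrix or length-4 vector")
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("cell counts must be non-negative integers")
  }
  stats::fisher.test(table, alternative = alternative)$p.value
}

#' Mutual exclusivity / co-occurrence of two gene (sets)
#'
#' Cross-tabulates samples by mutation status in `gene_a` versus any
#' gene of `gene_b` and tests the association by Fisher's exact test
#' (two-sided by default; `alternative = "less"` is the exclusivity
#' alternative).
#'
#' @param matrix sample-by-gene count matrix.
#' @param gene_a single gene id.
#' @param gene_b gene id or vector of ids ("any-of" status).
#' @param alternative passed to [fisher_2x2()].
#' @return list with `both`, `a_only`, `b_only`, `neither`, the 2x2
#'   `table` and `p_value`.
#' @export
mutual_exclusivity <- function(matrix, gene_a, gene_b,
                               alternative = "two.sided") {
  miss <- setdiff(c(gene_a, gene_b), colnames(matrix))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  a <- matrix[, gene_a] > 0L
  b <- if (length(gene_b) == 1L) matrix[, gene_b] > 0L else
    rowSums(matrix[, gene_b, drop = FALSE] > 0L) > 0L
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A_mut", "A_wt"), c("B_mut", "B_wt")))
  list(both = tab[1, 1], a_only = tab[1, 2], b_only = tab[2, 1],
       neither = tab[2, 2], table = tab,
       p_value = fisher_2x2(tab, alternative))
}

#' Long-format oncoprint table
#'
#' @param matrix sample-by-gene count matrix.
#' @return data.frame `sample_id`, `gene_id`, `n_mutations` for every
#'   mutated cell.
#' @export
oncoprint_long <- function(matrix) {
  idx <- which(matrix > 0L, arr.ind = TRUE)
  data.frame(sample_id = rownames(matrix)[idx[, 1]],
             gene_id = colnames(matrix)[idx[, 2]],
             n_mutations = matrix[idx], row.names = NULL)
}
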