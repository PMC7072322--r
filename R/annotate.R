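.BASES <- c("A", "C", "G", "T")

# Standard nuclear genetic code; stop ("*") is treated as an amino-acid
# symbol, so stop gain/loss counts as nonsynonymous.
.GENETIC_CODE <- Biostrings::GENETIC_CODE

# .SYN_THIRDS[codon, p]: of the 3 possible substitutions at codon position p,
# how many are synonymous (0..3). Shared by effect classification and
# fractional site counting.
.SYN_THIRDS <- local({
  codons <- names(.GENETIC_CODE)
  m <- matrix(0L, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- .GENETIC_CODE[[cd]]
    for (p in 1:3) {
      for (b in .BASES) {
        if (b == substr(cd, p, p)) next
        alt <- cd
        substr(alt, p, p) <- b
        if (.GENETIC_CODE[[alt]] == aa) m[cd, p] <- m[cd, p] + 1L
      }
    }
  }
  m
})

.SUBCLASS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.subclass6 <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, .complement(ref), ref)
  a <- ifelse(pur, .complement(alt), alt)
  paste0(r, ">", a)
}

#' Annotate filtered variant calls
#'
#' Adds, per record: the assigned gene (`gene_id`, deterministic first
#' overlapping gene in lexicographic order; `all_genes` keeps every
#' overlap for cohort matrices), coding effect (`synonymous`,
#' `nonsynonymous`, `coding_indel` or `noncoding`), CpG status of the
#' site (SNVs only), the pyrimidine-centred trinucleotide class
#' (`context96`, `NA` at sequence edges) and the 6-class substitution
#' label (`subclass6`).
#'
#' @param calls variant call data.frame (see [simulate_cohort()] for the
#'   column contract).
#' @param genes gene model table.
#' @param ref `ReferenceGenome`.
#' @param structures optional precomputed `.gene_structures()` output,
#'   reused across replicate analyses of one reference.
#' @return `calls` with annotation columns appended.
#' @export
annotate_variants <- function(calls, genes, ref, structures = NULL) {
  .assert_columns(calls, c("chrom", "pos", "ref", "alt", "var_class"),
                  "variant calls")
  n <- nrow(calls)
  out <- calls
  out$gene_id <- rep(NA_character_, n)
  out$all_genes <- rep(NA_character_, n)
  out$effect <- rep("noncoding", n)
  out$is_cpg <- rep(NA, n)
  out$context96 <- rep(NA_character_, n)
  out$subclass6 <- rep(NA_character_, n)
  if (n == 0L) return(out)

  anchor <- ref_base(ref, calls$chrom, calls$pos)
  mism <- anchor != substr(calls$ref, 1L, 1L)
  if (any(mism)) {
    i <- which(mism)[1]
    stop(sprintf("reference mismatch at %s:%d (genome %s, record %s)",
                 calls$chrom[i], calls$pos[i], anchor[i], calls$ref[i]))
  }

  is_snv <- calls$var_class == "SNV"
  out$is_cpg[is_snv] <- cpg_status(ref, calls$chrom[is_snv], calls$pos[is_snv])
  out$subclass6[is_snv] <- .subclass6(calls$ref[is_snv], calls$alt[is_snv])
  out$context96[is_snv] <- trinucleotide_context(ref, calls[is_snv, , drop = FALSE])

  if (nrow(genes) == 0L) return(out)
  if (is.null(structures)) structures <- .gene_structures(genes, ref)

  vr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos,
                              end = calls$pos + nchar(calls$ref) - 1L)
  )
  hits <- GenomicRanges::findOverlaps(vr, .genes_granges(genes),
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  hit_genes <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
  for (qi in names(hit_genes)) {
    i <- as.integer(qi)
    gs <- sort(unique(hit_genes[[qi]]))
    out$all_genes[i] <- paste(gs, collapse = ",")
    out$gene_id[i] <- gs[1]
    if (!is_snv[i]) {
      out$effect[i] <- "coding_indel"
      next
    }
    st <- structures[[gs[1]]]
    cidx <- match(calls$pos[i], st$gpos) - 1L  # 0-based coding index
    if (is.na(cidx)) {
      # overlap bookkeeping only (cannot happen for width-1 SNV ranges)
      out$effect[i] <- "noncoding"
      next
    }
    codon_start <- (cidx %/% 3L) * 3L + 1L
    pos_in_codon <- cidx %% 3L + 1L
    codon <- substr(st$spliced, codon_start, codon_start + 2L)
    alt_coding <- if (st$strand == "-") .complement(calls$alt[i]) else calls$alt[i]
    mut <- codon
    substr(mut, pos_in_codon, pos_in_codon) <- alt_coding
    same <- .GENETIC_CODE[[codon]] == .GENETIC_CODE[[mut]]
    out$effect[i] <- if (same) "synonymous" else "nonsynonymous"
  }
  out
}

#' Coding effect of a single variant
#'
#' @param v a one-row variant call data.frame.
#' @inheritParams annotate_variants
#' @return list with elements `effect` and `gene_id` (`NA` if intergenic).
#' @export
classify_coding_effect <- function(v, genes, ref) {
  stopifnot(nrow(v) == 1L)
  a <- annotate_variants(v, genes, ref)
  list(effect = a$effect, gene_id = a$gene_id)
}

#' Pyrimidine-centred trinucleotide context of SNVs
#'
#' Purine-reference substitutions are reverse-complemented so the centre
#' base is C or T; labels follow the `X[R>A]Y` convention. Positions
#' lacking a two-sided context (sequence edges) return `NA`.
#'
#' @inheritParams annotate_variants
#' @return character vector of context labels.
#' @export
trinucleotide_context <- function(ref, calls) {
  if (nrow(calls) == 0L) return(character(0))
  stopifnot(all(calls$var_class == "SNV"))
  tri <- ref_triplet(ref, calls$chrom, calls$pos)
  out <- rep(NA_character_, nrow(calls))
  ok <- !is.na(tri) & !grepl("N", tri)
  pur <- substr(calls$ref, 1, 1) %in% c("A", "G")
  t_ok <- tri[ok]
  r <- calls$ref[ok]; a <- calls$alt[ok]; p <- pur[ok]
  t_ok[p] <- .revcomp(t_ok[p])
  r[p] <- .complement(r[p]); a[p] <- .complement(a[p])
  out[ok] <- sprintf("%s[%s>%s]%s", substr(t_ok, 1, 1), r, a,
                     substr(t_ok, 3, 3))
  out
}

#' Mutation spectrum summary
#'
#' Tabulates SNVs by 6-class substitution and, where context is
#' available, by 96-class trinucleotide context, and reports the modal
#' substitution class.
#'
#' @param variants annotated variant data.frame (see
#'   [annotate_variants()]).
#' @return list with `class6` (named counts over all six classes),
#'   `class96` (named counts), `modal_class` (`NA` when there are no
#'   SNVs) and `modal_count`.
#' @export
spectrum_summary <- function(variants) {
  snv <- variants[variants$var_class == "SNV", , drop = FALSE]
  class6 <- table(factor(snv$subclass6, levels = .SUBCLASS6))
  class6 <- stats::setNames(as.integer(class6), names(class6))
  ctx <- snv$context96[!is.na(snv$context96)]
  class96 <- if (length(ctx)) {
    tab <- table(ctx)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  if (sum(class6) == 0L) {
    modal <- NA_character_; modal_n <- 0L
  } else {
    modal <- names(class6)[which.max(class6)]
    modal_n <- max(class6)
  }
  list(class6 = class6, class96 = class96,
       modal_class = modal, modal_count = modal_n)
}

#' Export the 4-column variant list
#'
#' Writes one row per variant with columns CHROM, POS, REF, ALT
#' (tab-separated, input order preserved).
#'
#' @param variants variant data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_4col <- function(variants, path) {
  out <- data.frame(CHROM = variants$chrom, POS = variants$pos,
                    REF = variants$ref, ALT = variants$alt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
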