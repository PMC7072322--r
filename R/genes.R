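#' Gene (CDS) models
#'
#' A gene model table has one row per CDS interval with columns
#' `gene_id`, `chrom`, `start`, `end`, `strand`. Coordinates are
#' 0-based half-open internally; the GFF3 and TSV readers/writers
#' convert from/to 1-based inclusive. CDS intervals of a gene must be
#' non-overlapping and their total length a multiple of 3.
#'
#' @param genes a gene model data.frame.
#' @param ref optional `ReferenceGenome` to check chromosome bounds against.
#' @return `genes`, invisibly, after validation.
#' @export
validate_genes <- function(genes, ref = NULL) {
  .assert_columns(genes, c("gene_id", "chrom", "start", "end", "strand"),
                  "gene model table")
  if (nrow(genes) == 0L) return(invisible(genes))
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start < 0L) || any(genes$end <= genes$start)) {
    stop("CDS intervals must satisfy 0 <= start < end")
  }
  for (g in split(genes, genes$gene_id)) {
    if (length(unique(g$chrom)) != 1L || length(unique(g$strand)) != 1L) {
      stop("gene on multiple chromosomes/strands: ", g$gene_id[1])
    }
    o <- order(g$start)
    if (any(g$start[o][-1] < g$end[o][-length(o)])) {
      stop("overlapping CDS intervals within gene ", g$gene_id[1])
    }
    len <- sum(g$end - g$start)
    if (len %% 3L != 0L) {
      stop(sprintf("CDS length of gene %s (%d bp) is not a multiple of 3",
                   g$gene_id[1], len))
    }
    if (!is.null(ref)) {
      L <- nchar(.ref_seq(ref, g$chrom[1]))
      if (any(g$end > L)) stop("CDS interval out of chromosome bounds for gene ",
                               g$gene_id[1])
    }
  }
  invisible(genes)
}

# Per-gene coding structure: genomic positions in coding (5'->3' mRNA) order,
# spliced CDS sequence on the coding strand, coding length.
.gene_structures <- function(genes, ref) {
  validate_genes(genes, ref)
  lapply(split(genes, genes$gene_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    s <- .ref_seq(ref, g$chrom[1])
    gpos <- unlist(lapply(seq_len(nrow(g)),
                          function(i) (g$start[i] + 1L):g$end[i]))
    seq_plus <- paste(substring(s, g$start + 1L, g$end), collapse = "")
    if (g$strand[1] == "-") {
      gpos <- rev(gpos)
      spliced <- .revcomp(seq_plus)
    } else {
      spliced <- seq_plus
    }
    list(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
         exons = g, gpos = gpos, spliced = spliced,
         coding_length = nchar(spliced))
  })
}

.genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}

#' Read gene models from GFF3 or TSV
#'
#' GFF3 input must carry CDS features with a `Parent` (or `ID`)
#' attribute naming the gene; the TSV format has columns
#' `gene_id, chrom, start, end, strand` with 1-based inclusive
#' coordinates, one row per CDS interval.
#'
#' @param path input file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"gff3"` or `"tsv"`.
#' @param ref optional `ReferenceGenome` for bounds checking.
#' @return a validated gene model data.frame (0-based half-open).
#' @export
read_genes <- function(path, format = c("auto", "gff3", "tsv"), ref = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    if (length(gr) == 0L) stop("no CDS features in ", path)
    parent <- as.character(gr$Parent %||% gr$ID)
    if (length(parent) == 0L || all(is.na(parent))) {
      stop("CDS features lack Parent/ID attributes in ", path)
    }
    genes <- data.frame(
      gene_id = sub("^gene:", "", parent),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .assert_columns(tab, c("gene_id", "chrom", "start", "end", "strand"),
                    basename(path))
    genes <- data.frame(
      gene_id = as.character(tab$gene_id),
      chrom = as.character(tab$chrom),
      start = as.integer(tab$start) - 1L,
      end = as.integer(tab$end),
      strand = as.character(tab$strand),
      stringsAsFactors = FALSE
    )
  }
  genes <- genes[order(genes$gene_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  validate_genes(genes, ref)
  genes
}

#' Write gene models to GFF3 or TSV
#'
#' @inheritParams read_genes
#' @param genes gene model data.frame (internal 0-based coordinates).
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path)) "gff3" else "tsv"
  }
  validate_genes(genes)
  if (format == "gff3") {
    cds <- .genes_granges(genes)
    cds$type <- "CDS"
    cds$source <- "earlygc"
    cds$Parent <- as.character(cds$gene_id)
    cds$ID <- sprintf("cds:%s:%d", cds$gene_id, seq_along(cds))
    # GFF3 phase: bases to skip to reach the next codon start, in
    # translation order (ascending on +, descending on -)
    phase <- integer(length(cds))
    for (gid in unique(genes$gene_id)) {
      i <- which(genes$gene_id == gid)
      o <- order(genes$start[i], decreasing = genes$strand[i][1] == "-")
      len <- (genes$end - genes$start)[i][o]
      cum <- c(0L, cumsum(len)[-length(len)])
      phase[i][o] <- (3L - cum %% 3L) %% 3L
    }
    cds$phase <- phase
    spans <- unlist(range(GenomicRanges::split(cds, cds$gene_id)))
    spans$type <- "gene"
    spans$source <- "earlygc"
    spans$ID <- names(spans)
    spans$gene_id <- names(spans)
    names(spans) <- NULL
    cds$gene_id <- NULL
    rtracklayer::export(c(spans, cds), path, format = "gff3")
  } else {
    out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                      start = genes$start + 1L, end = genes$end,
                      strand = genes$strand)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
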