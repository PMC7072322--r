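# Shared fixtures and independent oracles.

# Hypergeometric Fisher p by direct enumeration over the support,
# using only lchoose(); independent of stats::fisher.test / dhyper.
oracle_fisher <- function(a, b, c, d,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(lp)
  pobs <- p[a - lo + 1L]
  switch(alternative,
         greater = sum(p[x >= a]),
         less = sum(p[x <= a]),
         two.sided = sum(p[p <= pobs * (1 + 1e-7)]))
}

# Step-up BH computed from the formula directly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# A variant call record sitting exactly on every exome-filter boundary.
make_call <- function(...) {
  rec <- data.frame(
    sample_id = "S01", chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    var_class = "SNV", tumor_depth = 30L, tumor_alt = 3L,
    normal_depth = 30L, normal_alt = 1L, alt_forward = 2L, alt_reverse = 1L,
    variant_score = 0.3, base_quality_min = 30L, call_quality = 100,
    barcode_pairs = 2L, known_variant = FALSE, stringsAsFactors = FALSE
  )
  ov <- list(...)
  for (nm in names(ov)) rec[[nm]] <- ov[[nm]]
  rec
}

# Record passing every targeted-filter boundary.
make_targeted_call <- function(...) {
  ov <- utils::modifyList(list(tumor_depth = 100L, tumor_alt = 10L,
                               alt_forward = 5L, alt_reverse = 5L),
                          list(...))
  do.call(make_call, ov)
}

# A tiny single-gene reference with a hand-written coding sequence.
# CDS (one exon, + strand) spans positions 11..22 (1-based):
# ATG GGG TTC TAA. Flanks are CpG-free.
tiny_gene_fixture <- function() {
  seq <- paste0("ATATATATTA", "ATGGGGTTCTAA", "TTATATATAT")
  ref <- as_reference(c(chr1 = seq))
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 10L, end = 22L,
                      strand = "+", stringsAsFactors = FALSE)
  list(ref = ref, genes = genes)
}

small_sim <- function(seed = 7, n_samples = 6, ...) {
  cfg <- sim_config(seed = seed, n_samples = n_samples, n_chromosomes = 2L,
                    chromosome_length = 1e5, n_genes = 20L,
                    gene_cds_length = 600L, ...)
  gen <- generate_reference(cfg)
  co <- simulate_cohort(gen$reference, gen$genes, cfg)
  c(gen, co, list(config = cfg))
}

call_key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
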