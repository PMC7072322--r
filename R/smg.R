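#' Estimate background mutation rates from non-coding mutations
#'
#' The genome is divided into fixed-size bins (1 Mb by default) and,
#' within each bin, point-mutation rates are estimated separately for
#' CpG and non-CpG sites (CpG sites mutate much faster), together with
#' an indel rate per bp -- always from non-coding mutations only, so the
#' coding signal under test never contaminates its own background. Each
#' rate is mutations / (eligible non-coding sites in bin x n_samples).
#' Bins with fewer than `min_bin_mutations` non-coding mutations are
#' flagged to fall back to the pooled genome-wide rates.
#'
#' @param noncoding annotated variant data.frame restricted to
#'   `effect == "noncoding"` (see [annotate_variants()]).
#' @param ref `ReferenceGenome`.
#' @param genes gene model table (defines the coding mask).
#' @param n_samples number of samples the mutations were pooled over.
#' @param bin_size bin width in bp.
#' @param min_bin_mutations minimum non-coding mutations for a bin to
#'   use its local rates.
#' @param bin_sites optional precomputed [background_bin_sites()] table
#'   (reused across replicate cohorts on one reference).
#' @return a `BackgroundRates` object: `bins` (per-bin counts, rates and
#'   `fallback` flag), `pooled` (genome-wide `rate_cpg`, `rate_noncpg`,
#'   `rate_indel`), plus bookkeeping fields.
#' @export
estimate_background_rates <- function(noncoding, ref, genes, n_samples,
                                      bin_size = 1e6,
                                      min_bin_mutations = 50,
                                      bin_sites = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (nrow(noncoding) > 0) {
    .assert_columns(noncoding, c("chrom", "pos", "var_class", "effect", "is_cpg"),
                    "noncoding variants")
    if (any(noncoding$effect != "noncoding")) {
      stop("estimate_background_rates expects non-coding variants only")
    }
  }
  if (is.null(bin_sites)) bin_sites <- background_bin_sites(ref, genes, bin_size)
  bins <- bin_sites
  bins$mut_cpg <- 0L; bins$mut_noncpg <- 0L; bins$mut_indel <- 0L
  for (ch in unique(bins$chrom)) {
    sel <- bins$chrom == ch
    nb <- sum(sel)
    v <- noncoding[noncoding$chrom == ch, , drop = FALSE]
    vbin <- (v$pos - 1L) %/% as.integer(bin_size) + 1L
    snv <- v$var_class == "SNV"
    bins$mut_cpg[sel] <- tabulate(vbin[snv & v$is_cpg], nbins = nb)
    bins$mut_noncpg[sel] <- tabulate(vbin[snv & !v$is_cpg], nbins = nb)
    bins$mut_indel[sel] <- tabulate(vbin[!snv], nbins = nb)
  }
  safe_rate <- function(m, s, what) {
    r <- ifelse(s > 0, m / (s * n_samples), 0)
    if (any(s == 0 & m > 0)) {
      warning("mutations observed in a category with zero eligible sites (",
              what, "); rate set to 0")
    }
    if (any(s == 0)) r[s == 0] <- 0
    r
  }
  bins$rate_cpg <- safe_rate(bins$mut_cpg, bins$sites_cpg, "CpG")
  bins$rate_noncpg <- safe_rate(bins$mut_noncpg, bins$sites_noncpg, "non-CpG")
  bins$rate_indel <- safe_rate(bins$mut_indel, bins$sites_total, "indel")
  bins$n_mutations <- bins$mut_cpg + bins$mut_noncpg + bins$mut_indel
  bins$fallback <- bins$n_mutations < min_bin_mutations
  pooled <- list(
    rate_cpg = safe_rate(sum(bins$mut_cpg), sum(bins$sites_cpg), "CpG")[1],
    rate_noncpg = safe_rate(sum(bins$mut_noncpg), sum(bins$sites_noncpg),
                            "non-CpG")[1],
    rate_indel = safe_rate(sum(bins$mut_indel), sum(bins$sites_total),
                           "indel")[1]
  )
  structure(list(bins = bins, pooled = pooled, n_samples = n_samples,
                 bin_size = bin_size, min_bin_mutations = min_bin_mutations),
            class = "BackgroundRates")
}

#' Per-bin eligible non-coding site counts
#'
#' Counts, per genomic bin, the non-coding CpG and non-CpG sites that
#' are eligible for background-rate estimation. Depends only on the
#' reference and gene models, so it can be computed once and reused
#' across replicate cohorts.
#'
#' @param ref `ReferenceGenome`.
#' @param genes gene model table (the coding mask).
#' @param bin_size bin width in bp.
#' @return data.frame: `chrom`, `bin`, `bin_start`, `bin_end`,
#'   `sites_cpg`, `sites_noncpg`, `sites_total`.
#' @export
background_bin_sites <- function(ref, genes, bin_size = 1e6) {
  chroms <- names(unclass(ref))
  bin_rows <- lapply(chroms, function(ch) {
    L <- nchar(.ref_seq(ref, ch))
    coding <- logical(L)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g))) coding[(g$start[i] + 1L):g$end[i]] <- TRUE
    is_cpg <- logical(L)
    is_cpg[cpg_site_positions(ref, ch)] <- TRUE
    bin <- (seq_len(L) - 1L) %/% as.integer(bin_size)
    nb <- max(bin) + 1L
    nc <- !coding
    sites_cpg <- tabulate(bin[nc & is_cpg] + 1L, nbins = nb)
    sites_noncpg <- tabulate(bin[nc & !is_cpg] + 1L, nbins = nb)
    data.frame(
      chrom = ch, bin = seq_len(nb) - 1L,
      bin_start = (seq_len(nb) - 1L) * bin_size,
      bin_end = pmin(seq_len(nb) * bin_size, L),
      sites_cpg = sites_cpg, sites_noncpg = sites_noncpg,
      sites_total = sites_cpg + sites_noncpg
    )
  })
  out <- do.call(rbind, bin_rows)
  rownames(out) <- NULL
  out
}

#' @export
print.BackgroundRates <- function(x, ...) {
  cat(sprintf(paste0("BackgroundRates: %d bin(s), %d sample(s); pooled ",
                     "rate_cpg=%.3g rate_noncpg=%.3g rate_indel=%.3g\n"),
              nrow(x$bins), x$n_samples, x$pooled$rate_cpg,
              x$pooled$rate_noncpg, x$pooled$rate_indel))
  invisible(x)
}

#' Resolve background rates for each gene
#'
#' A gene's rates are the footprint-length-weighted average of the
#' rates of the bins its genomic span overlaps; bins flagged as
#' `fallback` contribute the pooled rates instead.
#'
#' @param rates a `BackgroundRates`.
#' @param genes gene model table.
#' @return data.frame: `gene_id`, `rate_cpg`, `rate_noncpg`,
#'   `rate_indel`, `used_fallback`.
#' @export
resolve_gene_rates <- function(rates, genes) {
  spans <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end))
  }))
  out <- lapply(seq_len(nrow(spans)), function(i) {
    sp <- spans[i, ]
    b <- rates$bins[rates$bins$chrom == sp$chrom, , drop = FALSE]
    ov <- pmin(b$bin_end, sp$end) - pmax(b$bin_start, sp$start)
    keep <- ov > 0
    b <- b[keep, , drop = FALSE]; w <- ov[keep]
    if (nrow(b) == 0L) stop("gene outside binned genome: ", sp$gene_id)
    rc <- ifelse(b$fallback, rates$pooled$rate_cpg, b$rate_cpg)
    rn <- ifelse(b$fallback, rates$pooled$rate_noncpg, b$rate_noncpg)
    ri <- ifelse(b$fallback, rates$pooled$rate_indel, b$rate_indel)
    data.frame(gene_id = sp$gene_id,
               rate_cpg = sum(rc * w) / sum(w),
               rate_noncpg = sum(rn * w) / sum(w),
               rate_indel = sum(ri * w) / sum(w),
               used_fallback = any(b$fallback))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count synonymous and nonsynonymous sites per gene
#'
#' Fractional (Nei-Gojobori-style) site counting: each coding position
#' contributes 1/3 site per possible substitution, classified
#' synonymous/nonsynonymous by its codon effect under the standard
#' genetic code (stop counts as an amino acid), and assigned to the
#' position's CpG category in the genome. Integer third-counts are kept
#' alongside so the conservation identity syn + nonsyn == coding length
#' is exact.
#'
#' @param genes gene model table (one or more genes).
#' @param ref `ReferenceGenome`.
#' @param structures optional precomputed `.gene_structures()` output.
#' @return data.frame with one row per gene: fractional
#'   `syn_cpg`, `syn_noncpg`, `nonsyn_cpg`, `nonsyn_noncpg`, the
#'   corresponding `*_thirds` integer counts, and `coding_length`.
#' @export
count_gene_sites <- function(genes, ref, structures = NULL) {
  if (is.null(structures)) structures <- .gene_structures(genes, ref)
  rows <- lapply(structures, function(st) {
    cl <- st$coding_length
    cidx <- seq_len(cl) - 1L
    codon <- substring(st$spliced, (cidx %/% 3L) * 3L + 1L,
                       (cidx %/% 3L) * 3L + 3L)
    picod <- cidx %% 3L + 1L
    syn3 <- .SYN_THIRDS[cbind(match(codon, rownames(.SYN_THIRDS)), picod)]
    iscpg <- cpg_status(ref, st$chrom, st$gpos)
    data.frame(
      gene_id = st$gene_id,
      syn_cpg_thirds = sum(syn3[iscpg]),
      syn_noncpg_thirds = sum(syn3[!iscpg]),
      nonsyn_cpg_thirds = sum(3L - syn3[iscpg]),
      nonsyn_noncpg_thirds = sum(3L - syn3[!iscpg]),
      coding_length = cl
    )
  })
  opp <- do.call(rbind, rows)
  rownames(opp) <- NULL
  opp$syn_cpg <- opp$syn_cpg_thirds / 3
  opp$syn_noncpg <- opp$syn_noncpg_thirds / 3
  opp$nonsyn_cpg <- opp$nonsyn_cpg_thirds / 3
  opp$nonsyn_noncpg <- opp$nonsyn_noncpg_thirds / 3
  opp
}

#' Expected protein-altering mutations per gene
#'
#' E = n_samples x (rate_cpg x nonsynonymous CpG sites + rate_noncpg x
#' nonsynonymous non-CpG sites + rate_indel x coding length).
#'
#' @param opp gene opportunity table from [count_gene_sites()].
#' @param rates per-gene resolved rates ([resolve_gene_rates()] output
#'   aligned to `opp`, or a single list with `rate_cpg`, `rate_noncpg`,
#'   `rate_indel`).
#' @param n_samples cohort size.
#' @return numeric vector of expected counts.
#' @export
expected_mutations <- function(opp, rates, n_samples) {
  n_samples * (rates$rate_cpg * opp$nonsyn_cpg +
                 rates$rate_noncpg * opp$nonsyn_noncpg +
                 rates$rate_indel * opp$coding_length)
}

# Rate-weighted effective trial counts for the exact test: site counts
# scaled by (category rate / non-CpG point rate), times n_samples.
.effective_opportunity <- function(opp, rates, n_samples) {
  if (any(rates$rate_noncpg <= 0)) {
    stop("non-CpG background rate is zero; effective opportunity undefined")
  }
  w_cpg <- rates$rate_cpg / rates$rate_noncpg
  w_ind <- rates$rate_indel / rates$rate_noncpg
  round(n_samples * (opp$nonsyn_noncpg + w_cpg * opp$nonsyn_cpg +
                       w_ind * opp$coding_length))
}

#' One-sided exact enrichment test for a gene
#'
#' Fisher's exact test on the 2x2 table `[[observed_g, opp_g -
#' observed_g], [observed_rest, opp_rest - observed_rest]]`, where the
#' opportunities are rate-weighted effective trial counts; the
#' alternative is enrichment of the gene row.
#'
#' @param observed_g,observed_rest observed protein-altering counts in
#'   the gene and in all other genes.
#' @param opp_g,opp_rest effective opportunities (integer trial counts).
#' @param alternative passed to [stats::fisher.test()].
#' @return the p-value.
#' @export
test_gene <- function(observed_g, opp_g, observed_rest, opp_rest,
                      alternative = "greater") {
  counts <- c(observed_g, opp_g, observed_rest, opp_rest)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts and opportunities must be non-negative integers")
  }
  if (observed_g > opp_g || observed_rest > opp_rest) {
    stop("observed count exceeds effective opportunity (construction bug)")
  }
  tab <- matrix(c(observed_g, opp_g - observed_g,
                  observed_rest, opp_rest - observed_rest),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) m p_(j) / j`, mapped back
#' to input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
adjust_bh <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Significantly-mutated-gene analysis
#'
#' Runs the full procedure on a filtered, annotated cohort: background
#' rates from non-coding mutations (CpG/non-CpG point rates and an
#' indel rate, binned with pooled fallback), fractional
#' synonymous/nonsynonymous site counts per gene, expected
#' protein-altering counts, a per-gene one-sided exact enrichment test
#' (gene vs all other genes on rate-weighted effective opportunities;
#' a Poisson formulation is available via `method = "poisson"`), and
#' Benjamini-Hochberg adjustment.
#'
#' @param annotated annotated variant data.frame ([annotate_variants()]
#'   output of the filter-passing calls).
#' @param ref `ReferenceGenome`.
#' @param genes gene model table.
#' @param n_samples cohort size.
#' @param bin_size,min_bin_mutations see [estimate_background_rates()].
#' @param q_cutoff significance threshold recorded on the result.
#' @param method `"fisher"` (default) or `"poisson"`.
#' @param opportunities,rates,bin_sites optional precomputed
#'   [count_gene_sites()], [estimate_background_rates()] and
#'   [background_bin_sites()] results, reused across replicate runs on
#'   one reference.
#' @return data.frame with one row per gene (`gene_id`, `observed`,
#'   `expected`, `opportunity`, `p_value`, `q_value`, `significant`),
#'   sorted by q then p; the `BackgroundRates` used are attached as
#'   attribute `"rates"`.
#' @export
run_smg <- function(annotated, ref, genes, n_samples, bin_size = 1e6,
                    min_bin_mutations = 50, q_cutoff = 0.05,
                    method = c("fisher", "poisson"),
                    opportunities = NULL, rates = NULL, bin_sites = NULL) {
  method <- match.arg(method)
  .assert_columns(annotated, c("gene_id", "effect", "var_class", "is_cpg"),
                  "annotated cohort")
  if (is.null(rates)) {
    noncoding <- annotated[annotated$effect == "noncoding", , drop = FALSE]
    if (nrow(noncoding) == 0L) {
      stop("no non-coding mutations in the cohort: the background mutation ",
           "rate is unidentifiable and no gene can be tested")
    }
    rates <- estimate_background_rates(noncoding, ref, genes, n_samples,
                                       bin_size, min_bin_mutations, bin_sites)
  }
  if (is.null(opportunities)) opportunities <- count_gene_sites(genes, ref)
  gene_ids <- opportunities$gene_id
  pa <- annotated[annotated$effect %in% c("nonsynonymous", "coding_indel"), ,
                  drop = FALSE]
  observed <- as.integer(table(factor(pa$gene_id, levels = gene_ids)))
  grates <- resolve_gene_rates(rates, genes)
  grates <- grates[match(gene_ids, grates$gene_id), , drop = FALSE]
  expected <- expected_mutations(opportunities, grates, n_samples)
  opp_eff <- .effective_opportunity(opportunities, grates, n_samples)
  tot_obs <- sum(observed)
  tot_opp <- sum(opp_eff)
  p <- vapply(seq_along(gene_ids), function(i) {
    if (method == "poisson") {
      stats::ppois(observed[i] - 1L, expected[i], lower.tail = FALSE)
    } else {
      test_gene(observed[i], opp_eff[i], tot_obs - observed[i],
                tot_opp - opp_eff[i])
    }
  }, numeric(1))
  res <- data.frame(gene_id = gene_ids, observed = observed,
                    expected = expected, opportunity = opp_eff,
                    used_fallback = grates$used_fallback,
                    p_value = p, q_value = adjust_bh(p))
  res$significant <- res$q_value < q_cutoff
  res <- res[order(res$q_value, res$p_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rates") <- rates
  attr(res, "method") <- method
  attr(res, "q_cutoff") <- q_cutoff
  res
}
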