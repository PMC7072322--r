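test_that("fractional site counting matches codon-table enumeration", {
  # single-codon genes with hand-enumerable substitution effects
  r <- as_reference(c(chr1 = "TTGGGTT", chr2 = "TTATGTT"))
  genes <- data.frame(gene_id = c("GLY", "MET"), chrom = c("chr1", "chr2"),
                      start = 2L, end = 5L, strand = "+",
                      stringsAsFactors = FALSE)
  opp <- count_gene_sites(genes, r)
  gly <- opp[opp$gene_id == "GLY", ]
  met <- opp[opp$gene_id == "MET", ]
  expect_equal(gly$syn_cpg + gly$syn_noncpg, 1.0)       # GGG: 3 syn thirds
  expect_equal(gly$nonsyn_cpg + gly$nonsyn_noncpg, 2.0)
  expect_equal(met$syn_cpg + met$syn_noncpg, 0.0)       # ATG: all nonsyn
  expect_equal(met$nonsyn_cpg + met$nonsyn_noncpg, 3.0)
})

test_that("site counts conserve coding length exactly for every gene", {
  cfg <- sim_config(seed = 29, n_chromosomes = 2L, chromosome_length = 1e5,
                    n_genes = 40L, gene_cds_length = 600L)
  gen <- generate_reference(cfg)
  opp <- count_gene_sites(gen$genes, gen$reference)
  thirds <- opp$syn_cpg_thirds + opp$syn_noncpg_thirds +
    opp$nonsyn_cpg_thirds + opp$nonsyn_noncpg_thirds
  expect_identical(thirds, 3L * opp$coding_length)
  expect_error(count_gene_sites(data.frame(gene_id = "B", chrom = "chr1",
                                           start = 0L, end = 4L, strand = "+"),
                                gen$reference), "multiple of 3")
})

test_that("background rates equal mutations over sites x samples", {
  # 100 CG dinucleotides -> 200 CpG sites, 200 non-CpG sites, no genes
  r <- as_reference(c(chr1 = paste(rep("ACGT", 100), collapse = "")))
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  nc <- data.frame(
    chrom = "chr1", pos = c(2L, 6L, 10L, 14L, 1L, 5L, 20L),
    var_class = c(rep("SNV", 6), "deletion"),
    effect = "noncoding",
    is_cpg = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, NA)
  )
  rates <- estimate_background_rates(nc, r, genes, n_samples = 10)
  expect_equal(rates$pooled$rate_cpg, 4 / (200 * 10))
  expect_equal(rates$pooled$rate_noncpg, 2 / (200 * 10))
  expect_equal(rates$pooled$rate_indel, 1 / (400 * 10))
  expect_true(rates$bins$fallback[1])  # 7 < 50 mutations in the bin
  rates2 <- estimate_background_rates(nc, r, genes, 10, min_bin_mutations = 1)
  expect_false(rates2$bins$fallback[1])
  # no mutations at all -> all-zero rates
  r0 <- estimate_background_rates(nc[0, ], r, genes, 10)
  expect_equal(unlist(r0$pooled), c(rate_cpg = 0, rate_noncpg = 0,
                                    rate_indel = 0))
  expect_error(estimate_background_rates(transform(nc, effect = "synonymous"),
                                         r, genes, 10), "non-coding")
})

test_that("expected counts are the linear rate x opportunity combination", {
  opp <- data.frame(nonsyn_cpg = 300, nonsyn_noncpg = 600, coding_length = 1200)
  rates <- list(rate_cpg = 2e-6, rate_noncpg = 1e-6, rate_indel = 0)
  expect_equal(expected_mutations(opp, rates, 20), 0.024)
  rates0 <- list(rate_cpg = 0, rate_noncpg = 0, rate_indel = 0)
  expect_equal(expected_mutations(opp, rates0, 20), 0)
})

test_that("the per-gene exact test matches hypergeometric enumeration", {
  expect_equal(test_gene(0, 1000, 50, 100000), 1)
  p <- test_gene(5, 1000, 100, 1000000)
  expect_equal(p, oracle_fisher(5, 995, 100, 999900, "greater"),
               tolerance = 1e-12)
  expect_error(test_gene(11, 10, 5, 100), "exceeds")
  expect_error(test_gene(-1, 10, 5, 100), "non-negative")
  # enrichment tail is monotone in the observed count at fixed margins
  k <- 105
  ps <- vapply(1:20, function(a) test_gene(a, 1000, k - a, 1000000),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(2:50, 1))
    q <- adjust_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
})

test_that("run_smg refuses cohorts without non-coding mutations", {
  fx <- tiny_gene_fixture()
  ann <- data.frame(sample_id = "S01", chrom = "chr1", pos = 12L,
                    var_class = "SNV", gene_id = "G1", all_genes = "G1",
                    effect = "nonsynonymous", is_cpg = FALSE)
  expect_error(run_smg(ann, fx$ref, fx$genes, n_samples = 5),
               "non-coding mutations")
})

test_that("permuting gene labels permutes but preserves the p-value multiset", {
  # two genes with byte-identical CDS and flanks -> identical opportunities
  cds <- "ATGGGGTTCTAA"
  seq <- paste0(strrep("T", 10), cds, strrep("T", 10), cds, strrep("T", 10))
  r <- as_reference(c(chr1 = seq))
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                      start = c(10L, 32L), end = c(22L, 44L), strand = "+",
                      stringsAsFactors = FALSE)
  base <- data.frame(sample_id = "S01", chrom = "chr1", pos = 2:6,
                     var_class = "SNV", gene_id = NA_character_,
                     all_genes = NA_character_, effect = "noncoding",
                     is_cpg = FALSE)
  coding <- data.frame(sample_id = "S01", chrom = "chr1", pos = c(12L, 13L, 35L),
                       var_class = "SNV",
                       gene_id = c("GA", "GA", "GB"),
                       all_genes = c("GA", "GA", "GB"),
                       effect = "nonsynonymous", is_cpg = FALSE)
  swapped <- transform(coding, gene_id = c("GB", "GB", "GA"),
                       all_genes = c("GB", "GB", "GA"))
  s1 <- run_smg(rbind(base, coding), r, genes, n_samples = 4)
  s2 <- run_smg(rbind(base, swapped), r, genes, n_samples = 4)
  expect_equal(sort(s1$p_value), sort(s2$p_value), tolerance = 1e-12)
  expect_equal(s1$observed[s1$gene_id == "GA"], s2$observed[s2$gene_id == "GB"])
})

test_that("a spiked driver stands out while a neutral gene matches expectation", {
  cfg <- sim_config(seed = 31, n_samples = 20L, n_chromosomes = 2L,
                    chromosome_length = 2e5, n_genes = 50L,
                    gene_cds_length = 600L, driver_genes = c(G001 = 50))
  gen <- generate_reference(cfg)
  co <- simulate_cohort(gen$reference, gen$genes, cfg)
  ann <- annotate_variants(filter_exome(co$calls)$kept, gen$genes,
                           gen$reference)
  res <- run_smg(ann, gen$reference, gen$genes, cfg$n_samples)
  drv <- res[res$gene_id == "G001", ]
  expect_gt(drv$observed, 5 * drv$expected)
  expect_equal(res$gene_id[1], "G001")
  neutral <- res[res$gene_id != "G001", ]
  expect_lte(max(neutral$observed), 3)
})
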