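test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(rate_cpg = -1), "rates")
  expect_error(sim_config(gene_cds_length = 601L), "multiple of 3")
  expect_error(sim_config(driver_genes = c(G001 = 0.5)), "multipliers")
  expect_error(sim_config(artifact_rates = c(bogus = 1)), "artifact")
  expect_error(sim_config(vaf_mean = 0), "vaf_mean")
})

test_that("reference generation is deterministic and honours the gene layout", {
  cfg <- sim_config(seed = 1, n_chromosomes = 2L, chromosome_length = 5e4,
                    n_genes = 10L, gene_cds_length = 300L)
  g1 <- generate_reference(cfg)
  g2 <- generate_reference(cfg)
  expect_identical(unclass(g1$reference), unclass(g2$reference))
  expect_identical(g1$genes, g2$genes)
  expect_true(all(strsplit(unclass(g1$reference)[[1]], "")[[1]] %in%
                    c("A", "C", "G", "T")))
  # non-overlapping CDS within chromosome bounds
  validate_genes(g1$genes, g1$reference)
  for (ch in unique(g1$genes$chrom)) {
    g <- g1$genes[g1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_equal(length(unique(g1$genes$gene_id)), 10L)
})

test_that("degenerate and impossible gene layouts behave as specified", {
  cfg0 <- sim_config(seed = 2, n_genes = 0L, chromosome_length = 1e4)
  gen <- generate_reference(cfg0)
  expect_equal(nrow(gen$genes), 0L)
  cfg_big <- sim_config(seed = 2, n_genes = 500L, gene_cds_length = 900L,
                        chromosome_length = 2e4)
  expect_error(generate_reference(cfg_big), "cannot place")
})

test_that("realized CpG dinucleotide density matches the configured target", {
  cfg <- sim_config(seed = 7, n_chromosomes = 1L, chromosome_length = 1e6,
                    cpg_density = 0.02, n_genes = 0L)
  gen <- generate_reference(cfg)
  s <- unclass(gen$reference)[[1]]
  n_cg <- length(gregexpr("CG", s, fixed = TRUE)[[1]])
  dens <- n_cg / (nchar(s) - 1)
  expect_gte(dens, 0.016)
  expect_lte(dens, 0.024)
})

test_that("cohort simulation is deterministic and zero rates give empty cohorts", {
  sim1 <- small_sim(seed = 3)
  sim2 <- small_sim(seed = 3)
  expect_identical(sim1$calls, sim2$calls)
  expect_identical(sim1$truth, sim2$truth)

  cfg0 <- sim_config(seed = 5, n_samples = 4L, chromosome_length = 5e4,
                     n_genes = 5L, gene_cds_length = 300L,
                     rate_cpg = 0, rate_noncpg = 0, rate_indel = 0,
                     artifact_rates = c(low_depth = 0, normal_support = 0,
                                        strand_bias = 0, known = 0))
  gen <- generate_reference(cfg0)
  co <- simulate_cohort(gen$reference, gen$genes, cfg0)
  expect_equal(nrow(co$calls), 0L)
})

test_that("every emitted record is consistent with the truth table", {
  sim <- small_sim(seed = 11)
  expect_setequal(call_key(sim$calls), call_key(sim$truth))
  art <- sim$truth[sim$truth$class == "artifact", ]
  expect_true(all(art$criterion %in% c("EX1", "EX3", "EX4", "EX5")))
  expect_true(all(is.na(sim$truth$criterion[sim$truth$class == "true"])))
  # read-evidence invariants hold for every record
  expect_true(all(sim$calls$tumor_alt <= sim$calls$tumor_depth))
  expect_true(all(sim$calls$alt_forward + sim$calls$alt_reverse ==
                    sim$calls$tumor_alt))
})

test_that("realized SNV counts match the analytic Poisson mean", {
  cfg <- sim_config(seed = 23, n_samples = 5L, n_chromosomes = 1L,
                    chromosome_length = 2e5, n_genes = 0L,
                    rate_cpg = 1.5e-5, rate_noncpg = 1.5e-6, rate_indel = 0,
                    artifact_rates = c(low_depth = 0, normal_support = 0,
                                       strand_bias = 0, known = 0))
  gen <- generate_reference(cfg)
  cache <- simulation_cache(gen$reference, gen$genes, cfg)
  n_cpg <- length(cache$sites$chr1$cpg)
  n_non <- cache$sites$chr1$L - n_cpg
  lambda <- cfg$n_samples * (n_cpg * cfg$rate_cpg + n_non * cfg$rate_noncpg)
  nrep <- 50
  tot <- vapply(seq_len(nrep), function(i) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    nrow(simulate_cohort(gen$reference, gen$genes, cfg_i, cache)$calls)
  }, numeric(1))
  se <- sqrt(lambda / nrep)
  expect_lt(abs(mean(tot) - lambda), 3 * se)
})

test_that("MSI profile simulation matches its Bernoulli model", {
  p0 <- simulate_msi_profiles(20, rep(0, 5), seed = 1)
  expect_true(all(!as.matrix(p0[, -1])))
  p1 <- simulate_msi_profiles(20, rep(1, 5), seed = 1)
  expect_true(all(as.matrix(p1[, -1])))
  expect_error(simulate_msi_profiles(5, c(0.5, 0.5, 0.5, 0.5, 1.2)), "\\[0, 1\\]")
  ph <- simulate_msi_profiles(1000, rep(0.5, 5), seed = 11)
  frac <- colMeans(as.matrix(ph[, -1]))
  se <- sqrt(0.25 / 1000)
  expect_true(all(abs(frac - 0.5) < 3 * se))
  expect_identical(simulate_msi_profiles(10, 0.3, seed = 2),
                   simulate_msi_profiles(10, 0.3, seed = 2))
})
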