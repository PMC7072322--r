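test_that("the mutation matrix counts protein-altering events per cell", {
  ann <- data.frame(
    sample_id = c("S01", "S01", "S02", "S02", "S03"),
    gene_id = c("LRP1", "LRP1", "TP53", "LRP1", NA),
    all_genes = c("LRP1", "LRP1", "TP53", "LRP1", NA),
    effect = c("nonsynonymous", "coding_indel", "nonsynonymous",
               "synonymous", "noncoding"),
    var_class = c("SNV", "deletion", "SNV", "SNV", "SNV")
  )
  m <- build_matrix(ann, c("TP53", "LRP1"), sample_ids = c("S01", "S02", "S03"))
  expect_equal(m["S01", "LRP1"], 2L)      # two protein-altering hits
  expect_equal(m["S02", "LRP1"], 0L)      # synonymous does not count
  expect_equal(m["S02", "TP53"], 1L)
  expect_equal(sum(m["S03", ]), 0L)       # intergenic-only sample stays zero
  expect_error(build_matrix(transform(ann, all_genes = "NOPE"),
                            c("TP53", "LRP1")), "unknown gene")
  empty <- build_matrix(ann[0, ], c("TP53"), sample_ids = c("S01"))
  expect_true(all(empty == 0L))
})

test_that("a variant spanning two genes is counted in both matrix columns", {
  ann <- data.frame(sample_id = "S01", gene_id = "GA", all_genes = "GA,GB",
                    effect = "nonsynonymous", var_class = "SNV")
  m <- build_matrix(ann, c("GA", "GB"))
  expect_equal(unname(m["S01", ]), c(1L, 1L))
})

test_that("matrix column sums recount the per-gene totals of the variant list", {
  sim <- small_sim(seed = 37, n_samples = 8)
  ann <- annotate_variants(filter_exome(sim$calls)$kept, sim$genes,
                           sim$reference)
  ids <- unique(sim$genes$gene_id)
  m <- build_matrix(ann, ids, sample_ids = sprintf("S%02d", 1:8))
  pa <- ann[ann$effect %in% c("nonsynonymous", "coding_indel"), ]
  for (g in ids) {
    expect_equal(sum(m[, g]), sum(vapply(strsplit(pa$all_genes, ","),
                                         function(x) g %in% x, logical(1))))
  }
})

test_that("gene frequencies reproduce the published percentage convention", {
  m <- matrix(0L, nrow = 49, ncol = 2, dimnames = list(sprintf("S%02d", 1:49),
                                                       c("LRP1", "X")))
  m[1:14, "LRP1"] <- 1L
  fr <- gene_frequencies(m)
  expect_equal(fr$frequency_pct[fr$gene_id == "LRP1"], 28.6)  # 14/49
  expect_equal(fr$frequency_pct[fr$gene_id == "X"], 0)
  m2 <- matrix(0L, nrow = 58, ncol = 1, dimnames = list(NULL, "TP53"))
  m2[1:18, 1] <- 1L
  expect_equal(gene_frequencies(m2)$frequency_pct, 31.0)      # 18/58
  expect_equal(round_half_up(28.571428, 1), 28.6)
  expect_equal(round_half_up(0.25, 1), 0.3)  # half-up, not banker's
})

test_that("recurrence selection applies both the patient and rate thresholds", {
  m <- matrix(0L, nrow = 10, ncol = 3,
              dimnames = list(sprintf("S%02d", 1:10), c("A", "B", "C")))
  m[1:4, "A"] <- 1L; m[1, "A"] <- 2L          # 4 patients, 5 mutations
  m[1:3, "B"] <- 5L                           # 3 patients, high rate
  lens <- c(A = 3000, B = 3000, C = 3000)
  sel <- select_recurrent(m, lens)
  expect_identical(as.character(sel), "A")    # 5 / 0.003 Mb = 1666.7 > 10
  det <- attr(sel, "details")
  expect_equal(det$rate_per_mb[det$gene_id == "A"], 5 / 0.003)
  expect_false(det$selected[det$gene_id == "B"])  # >3 patients required
  expect_false(det$selected[det$gene_id == "C"])  # no mutations
  expect_error(select_recurrent(m, c(A = 3000, B = 0, C = 3000)),
               "zero or negative")
})

test_that("fisher_2x2 reproduces the cohort contingency analyses exactly", {
  p_all <- fisher_2x2(c(10, 4, 8, 27))
  expect_equal(p_all, oracle_fisher(10, 4, 8, 27), tolerance = 1e-9)
  expect_equal(p_all, 0.002656765, tolerance = 1e-6)
  expect_lte(p_all, 0.05)
  p_hp <- fisher_2x2(c(9, 0, 6, 18))
  expect_equal(p_hp, oracle_fisher(9, 0, 6, 18), tolerance = 1e-9)
  expect_lte(p_hp, 0.05)
  expect_equal(fisher_2x2(c(5, 5, 5, 5)), 1)
  expect_error(fisher_2x2(c(1, 2, 3)), "2x2")
  expect_error(fisher_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("fisher_2x2 matches enumeration and its symmetries on random tables", {
  set.seed(99)
  for (i in 1:300) {
    tab <- matrix(rpois(4, sample(c(2, 10, 30), 1)), 2)
    p2 <- fisher_2x2(tab)
    expect_equal(p2, oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
    expect_equal(p2, fisher_2x2(t(tab)), tolerance = 1e-12)
    pg <- fisher_2x2(tab, "greater")
    expect_equal(pg, fisher_2x2(tab[2:1, ], "less"), tolerance = 1e-12)
    expect_equal(pg, oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                                   "greater"), tolerance = 1e-9)
  }
})

test_that("mutual exclusivity reports overlap counts and a consistent p", {
  # 12 A-mutant samples, 10 of which carry no B-set mutation
  m <- matrix(0L, nrow = 30, ncol = 3,
              dimnames = list(sprintf("S%02d", 1:30), c("TP53", "APC", "CTNNB1")))
  m[1:12, "TP53"] <- 1L
  m[11:12, "APC"] <- 1L          # the two co-mutated samples
  m[13:18, "CTNNB1"] <- 1L
  me <- mutual_exclusivity(m, "TP53", c("APC", "CTNNB1"))
  expect_equal(me$both, 2)
  expect_equal(me$a_only, 10)
  expect_equal(me$p_value, fisher_2x2(me$table), tolerance = 1e-12)
  # disjoint sets share no sample
  me2 <- mutual_exclusivity(m, "TP53", "CTNNB1")
  expect_equal(me2$both, 0)
  expect_error(mutual_exclusivity(m, "TP53", "NOPE"), "not in matrix")
})
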