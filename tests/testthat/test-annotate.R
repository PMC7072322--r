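test_that("coding effects follow the standard genetic code", {
  fx <- tiny_gene_fixture()
  # CDS 11..22 is ATG GGG TTC TAA on the + strand
  syn <- make_call(pos = 16L, ref = "G", alt = "A")      # GGG -> GGA (Gly)
  nsy <- make_call(pos = 11L, ref = "A", alt = "G")      # ATG -> GTG (Met->Val)
  stp <- make_call(pos = 20L, ref = "T", alt = "C")      # TAA -> CAA (stop->Gln)
  ncd <- make_call(pos = 2L, ref = "T", alt = "C")       # upstream of the CDS
  ann <- annotate_variants(rbind(syn, nsy, stp, ncd), fx$genes, fx$ref)
  expect_equal(ann$effect, c("synonymous", "nonsynonymous", "nonsynonymous",
                             "noncoding"))
  expect_equal(ann$gene_id, c("G1", "G1", "G1", NA))
  expect_identical(classify_coding_effect(syn, fx$genes, fx$ref)$effect,
                   "synonymous")
})

test_that("indels overlapping a CDS are coding_indel, elsewhere noncoding", {
  fx <- tiny_gene_fixture()
  del_in <- make_call(pos = 14L, ref = "GG", alt = "G", var_class = "deletion")
  ins_out <- make_call(pos = 3L, ref = "A", alt = "ATT",
                       var_class = "insertion")
  ann <- annotate_variants(rbind(del_in, ins_out), fx$genes, fx$ref)
  expect_equal(ann$effect, c("coding_indel", "noncoding"))
})

test_that("effects are strand-consistent under reverse-complement mirroring", {
  fx <- tiny_gene_fixture()
  L <- nchar(unclass(fx$ref)[[1]])
  rc <- as_reference(c(chr1 = paste(rev(strsplit(chartr("ACGT", "TGCA",
    unclass(fx$ref)[[1]]), "")[[1]]), collapse = "")))
  genes_rc <- data.frame(gene_id = "G1", chrom = "chr1",
                         start = L - 22L, end = L - 10L, strand = "-",
                         stringsAsFactors = FALSE)
  cases <- list(c(16L, "G", "A"), c(11L, "A", "G"), c(20L, "T", "C"))
  for (cs in cases) {
    pos <- as.integer(cs[1])
    fwd <- make_call(pos = pos, ref = cs[2], alt = cs[3])
    rev <- make_call(pos = L - pos + 1L, ref = chartr("ACGT", "TGCA", cs[2]),
                     alt = chartr("ACGT", "TGCA", cs[3]))
    e1 <- annotate_variants(fwd, fx$genes, fx$ref)$effect
    e2 <- annotate_variants(rev, genes_rc, rc)$effect
    expect_identical(e1, e2)
  }
})

test_that("a reference mismatch is an error naming the position", {
  fx <- tiny_gene_fixture()
  bad <- make_call(pos = 11L, ref = "C", alt = "G")  # genome has A
  expect_error(annotate_variants(bad, fx$genes, fx$ref),
               "reference mismatch at chr1:11")
})

test_that("CpG status is definitional on both strands", {
  r <- as_reference(c(chr1 = "ACGT", chr2 = "ACAT"))
  expect_true(cpg_status(r, "chr1", 2L))   # the C of CG
  expect_true(cpg_status(r, "chr1", 3L))   # the G of CG
  expect_false(cpg_status(r, "chr1", 1L))  # A never CpG
  expect_false(cpg_status(r, "chr2", 2L))  # C not followed by G
  expect_equal(cpg_site_positions(r, "chr1"), c(2L, 3L))
})

test_that("trinucleotide contexts are pyrimidine-normalised", {
  r <- as_reference(c(chr1 = "TCGA"))
  c_case <- make_call(pos = 2L, ref = "C", alt = "T")   # context TCG
  g_case <- make_call(pos = 3L, ref = "G", alt = "A")   # context CGA -> revcomp
  edge <- make_call(pos = 1L, ref = "T", alt = "A")
  expect_equal(trinucleotide_context(r, rbind(c_case, g_case, edge)),
               c("T[C>T]G", "T[C>T]G", NA))
  r2 <- as_reference(c(chr1 = "ACAT"))
  expect_equal(trinucleotide_context(r2, make_call(pos = 2L, ref = "C",
                                                   alt = "G")), "A[C>G]A")
})

test_that("spectrum summaries count, collapse and report the modal class", {
  fx <- tiny_gene_fixture()
  calls <- rbind(make_call(pos = 16L, ref = "G", alt = "A"),  # G>A == C>T class
                 make_call(pos = 14L, ref = "G", alt = "A"),
                 make_call(pos = 15L, ref = "G", alt = "A"),
                 make_call(pos = 12L, ref = "T", alt = "A"))
  ann <- annotate_variants(calls, fx$genes, fx$ref)
  spec <- spectrum_summary(ann)
  expect_equal(unname(spec$class6["C>T"]), 3L)
  expect_equal(unname(spec$class6["T>A"]), 1L)
  expect_equal(spec$modal_class, "C>T")
  expect_equal(sum(spec$class6), 4L)

  empty <- spectrum_summary(ann[0, , drop = FALSE])
  expect_true(all(empty$class6 == 0L))
  expect_true(is.na(empty$modal_class))
})

test_that("96-class counts collapse to the 6-class table on simulated data", {
  sim <- small_sim(seed = 17)
  ann <- annotate_variants(filter_exome(sim$calls)$kept, sim$genes,
                           sim$reference)
  spec <- spectrum_summary(ann)
  expect_equal(sum(spec$class96),
               sum(!is.na(ann$context96[ann$var_class == "SNV"])))
  collapse <- sub(".*\\[(.*)\\].*", "\\1", names(spec$class96))
  for (cl in unique(collapse)) {
    n_ctx_total <- sum(spec$class96[collapse == cl])
    with_ctx <- !is.na(ann$context96) & ann$subclass6 == cl
    expect_equal(n_ctx_total, sum(with_ctx, na.rm = TRUE))
  }
  # annotation is pure: a shuffled input yields the same per-record results
  idx <- sample.int(nrow(sim$calls))
  ann2 <- annotate_variants(sim$calls[idx, ], sim$genes, sim$reference)
  ann1 <- annotate_variants(sim$calls, sim$genes, sim$reference)
  expect_equal(ann1$effect[idx], ann2$effect)
  expect_equal(ann1$is_cpg[idx], ann2$is_cpg)
  expect_equal(ann1$context96[idx], ann2$context96)
})

test_that("the 4-column export round-trips", {
  sim <- small_sim(seed = 19)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_4col(sim$calls, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(names(back), c("CHROM", "POS", "REF", "ALT"))
  expect_equal(nrow(back), nrow(sim$calls))
  expect_equal(back$POS, sim$calls$pos)
  expect_equal(back$REF, sim$calls$ref)
  export_4col(sim$calls[0, ], path)
  expect_equal(nrow(utils::read.delim(path)), 0L)
})
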