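.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate -> filter (exome ruleset) -> annotate -> significantly
#' mutated genes -> MSI -> cohort statistics, writing every result
#' table plus a JSON run manifest under `outdir`. Outputs are
#' deterministic given `config$seed`; any stage failure aborts with the
#' stage name.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param marker_instability_prob per-marker MSI instability
#'   probabilities for the simulated Bethesda panel.
#' @param min_bin_mutations,q_cutoff SMG-stage parameters (see
#'   [run_smg()]).
#' @return invisibly, a list with the in-memory stage results
#'   (`reference`, `genes`, `cohort`, `report`, `annotated`, `smg`,
#'   `msi`, `matrix`).
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         marker_instability_prob = rep(0.1, 5),
                         min_bin_mutations = 50, q_cutoff = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim <- .stage("simulate", {
    gen <- generate_reference(config)
    cohort <- simulate_cohort(gen$reference, gen$genes, config)
    write_reference(gen$reference, file.path(outdir, "reference.fa"))
    if (nrow(gen$genes)) {
      write_genes(gen$genes, file.path(outdir, "genes.gff3"))
      write_genes(gen$genes, file.path(outdir, "genes.tsv"), format = "tsv")
    }
    write_cohort_vcfs(cohort$calls, file.path(outdir, "vcf"))
    .write_tsv(cohort$truth, file.path(outdir, "truth.tsv"))
    c(gen, cohort)
  })

  report <- .stage("filter", {
    rep <- filter_exome(sim$calls)
    .write_tsv(rep$kept, file.path(outdir, "calls_kept.tsv"))
    write_filter_sidecar(rep, file.path(outdir, "calls_rejected.tsv"))
    rep
  })

  annotated <- .stage("annotate", {
    ann <- annotate_variants(report$kept, sim$genes, sim$reference)
    .write_tsv(ann, file.path(outdir, "annotated.tsv"))
    export_4col(ann, file.path(outdir, "variants_4col.tsv"))
    spec <- spectrum_summary(ann)
    .write_tsv(data.frame(class = names(spec$class6), count = spec$class6),
               file.path(outdir, "spectrum6.tsv"))
    ann
  })

  smg <- .stage("smg", {
    res <- run_smg(annotated, sim$reference, sim$genes, config$n_samples,
                   min_bin_mutations = min_bin_mutations,
                   q_cutoff = q_cutoff)
    .write_tsv(res, file.path(outdir, "smg_results.tsv"))
    .write_tsv(attr(res, "rates")$bins, file.path(outdir, "background_bins.tsv"))
    res
  })

  msi <- .stage("msi", {
    prof <- simulate_msi_profiles(config$n_samples, marker_instability_prob,
                                  seed = config$seed + 77L)
    cls <- classify_msi_panel(prof)
    .write_tsv(cls, file.path(outdir, "msi.tsv"))
    cls
  })

  mat <- .stage("cohort", {
    m <- build_matrix(annotated, sim$genes$gene_id[!duplicated(sim$genes$gene_id)],
                      sample_ids = sprintf("S%02d", seq_len(config$n_samples)))
    .write_tsv(cbind(sample_id = rownames(m), as.data.frame(m)),
               file.path(outdir, "mutation_matrix.tsv"))
    .write_tsv(gene_frequencies(m), file.path(outdir, "gene_frequencies.tsv"))
    .write_tsv(oncoprint_long(m), file.path(outdir, "oncoprint_long.tsv"))
    opp <- count_gene_sites(sim$genes, sim$reference)
    sel <- select_recurrent(m, stats::setNames(opp$coding_length, opp$gene_id))
    .write_tsv(attr(sel, "details"), file.path(outdir, "recurrent_genes.tsv"))
    m
  })

  manifest <- list(
    package = "earlygc",
    version = as.character(utils::packageVersion("earlygc")),
    seed = config$seed,
    config = config[setdiff(names(config), character(0))],
    filter_thresholds = exome_thresholds(),
    smg = list(bin_size = 1e6, min_bin_mutations = min_bin_mutations,
               q_cutoff = q_cutoff),
    non_default_parameters = list()
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(reference = sim$reference, genes = sim$genes,
                 cohort = list(calls = sim$calls, truth = sim$truth),
                 report = report, annotated = annotated, smg = smg,
                 msi = msi, matrix = mat))
}
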