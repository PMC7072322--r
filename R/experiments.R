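#' Filter fidelity on a simulated cohort
#'
#' Simulates one cohort, applies the exome filter, and scores it
#' against the truth table: sensitivity on true somatic events,
#' rejection rate on injected artifacts, and the fraction of artifacts
#' rejected under exactly their labelled criterion.
#'
#' @param config a [sim_config()].
#' @return list with `sensitivity`, `specificity`, `label_exact`
#'   (fractions in `[0, 1]`), and the underlying counts.
#' @export
experiment_filter_fidelity <- function(config = sim_config()) {
  gen <- generate_reference(config)
  co <- simulate_cohort(gen$reference, gen$genes, config)
  rep <- filter_exome(co$calls)
  key <- function(d) paste(d$sample_id, d$chrom, d$pos)
  truth_true <- co$truth[co$truth$class == "true", ]
  truth_art <- co$truth[co$truth$class == "artifact", ]
  kept_keys <- key(rep$kept)
  rej_keys <- key(rep$rejected)
  sens <- mean(key(truth_true) %in% kept_keys)
  spec <- mean(key(truth_art) %in% rej_keys)
  lab <- truth_art$criterion[match(rej_keys, key(truth_art))]
  matched <- !is.na(lab)
  exact <- vapply(which(matched), function(i) {
    identical(rep$rejected$criteria[[i]], lab[i])
  }, logical(1))
  list(sensitivity = sens, specificity = spec,
       label_exact = sum(exact) / nrow(truth_art),
       n_true = nrow(truth_true), n_artifacts = nrow(truth_art))
}

# Shared replicate runner: one reference, many cohorts.
.replicate_smg <- function(config, nrep, fun) {
  gen <- generate_reference(config)
  cache <- simulation_cache(gen$reference, gen$genes, config)
  opp <- count_gene_sites(gen$genes, gen$reference, cache$structures)
  bs <- background_bin_sites(gen$reference, gen$genes)
  lapply(seq_len(nrep), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    co <- simulate_cohort(gen$reference, gen$genes, cfg_i, cache)
    kept <- filter_exome(co$calls)$kept
    ann <- annotate_variants(kept, gen$genes, gen$reference, cache$structures)
    fun(ann, gen, opp, bs)
  })
}

#' Background-rate recovery over replicate cohorts
#'
#' Simulates `nrep` cohorts from one reference, estimates pooled
#' background rates from the non-coding mutations of each, and compares
#' the aggregate estimates with the generator rates under a 3-sigma
#' Poisson envelope (the mutation totals are Poisson, so the standard
#' error of the aggregate rate is sqrt(expected total) / denominator).
#'
#' @param config a [sim_config()].
#' @param nrep number of replicate cohorts.
#' @return data.frame with one row per category (`cpg`, `noncpg`,
#'   `indel`): generator `truth`, aggregate `estimate`, `sigma`, `z`,
#'   and `within_3sigma`.
#' @export
experiment_rate_recovery <- function(config = sim_config(n_samples = 10L),
                                     nrep = 100L) {
  tot <- c(cpg = 0, noncpg = 0, indel = 0)
  sites <- NULL
  res <- .replicate_smg(config, nrep, function(ann, gen, opp, bs) {
    nc <- ann[ann$effect == "noncoding", , drop = FALSE]
    rates <- estimate_background_rates(nc, gen$reference, gen$genes,
                                       config$n_samples, bin_sites = bs)
    list(mut = c(cpg = sum(rates$bins$mut_cpg),
                 noncpg = sum(rates$bins$mut_noncpg),
                 indel = sum(rates$bins$mut_indel)),
         sites = c(cpg = sum(rates$bins$sites_cpg),
                   noncpg = sum(rates$bins$sites_noncpg),
                   indel = sum(rates$bins$sites_total)))
  })
  sites <- res[[1]]$sites
  for (r in res) tot <- tot + r$mut
  truth <- c(cpg = config$rate_cpg, noncpg = config$rate_noncpg,
             indel = config$rate_indel)
  denom <- sites * config$n_samples * nrep
  estimate <- tot / denom
  sigma <- sqrt(truth * denom) / denom
  z <- ifelse(sigma > 0, (estimate - truth) / sigma, 0)
  data.frame(category = names(truth), truth = unname(truth),
             estimate = unname(estimate), sigma = unname(sigma),
             z = unname(z), within_3sigma = abs(unname(z)) <= 3)
}

#' False-discovery control under the null
#'
#' Simulates `nrep` driver-free cohorts and runs the full SMG analysis
#' on each; under a controlled FDR, replicates with any gene at
#' q below `q_cutoff` should be rare.
#'
#' @param config a driver-free [sim_config()].
#' @param nrep replicate count.
#' @param q_cutoff significance threshold.
#' @return list with `n_significant` (per-replicate counts) and
#'   `fraction_zero`.
#' @export
experiment_fdr_null <- function(config = sim_config(n_samples = 20L),
                                nrep = 200L, q_cutoff = 0.05) {
  if (length(config$driver_genes)) stop("null experiment must be driver-free")
  reps <- .replicate_smg(config, nrep, function(ann, gen, opp, bs) {
    res <- run_smg(ann, gen$reference, gen$genes, config$n_samples,
                   q_cutoff = q_cutoff, opportunities = opp, bin_sites = bs)
    sum(res$q_value < q_cutoff)
  })
  n_sig <- vapply(reps, identity, integer(1))
  list(n_significant = n_sig, fraction_zero = mean(n_sig == 0L))
}

#' Driver recovery power
#'
#' Simulates `nrep` cohorts containing one spiked driver gene and
#' scores, per replicate, whether the driver attains the smallest
#' q-value and clears `q_cutoff`.
#'
#' @param config a [sim_config()] with exactly one entry in
#'   `driver_genes`.
#' @param nrep replicate count.
#' @param q_cutoff significance threshold.
#' @return list with `detected` (per-replicate logical) and `power`.
#' @export
experiment_driver_power <- function(config, nrep = 100L, q_cutoff = 0.05) {
  if (length(config$driver_genes) != 1L) {
    stop("power experiment expects exactly one driver gene")
  }
  driver <- names(config$driver_genes)
  reps <- .replicate_smg(config, nrep, function(ann, gen, opp, bs) {
    res <- run_smg(ann, gen$reference, gen$genes, config$n_samples,
                   q_cutoff = q_cutoff, opportunities = opp, bin_sites = bs)
    res$gene_id[1] == driver && res$q_value[1] < q_cutoff
  })
  detected <- vapply(reps, identity, logical(1))
  list(detected = detected, power = mean(detected))
}

#' Modal substitution class across replicate cohorts
#'
#' Simulates one cohort per seed offset and tabulates the 6-class
#' substitution spectrum of the filter-passing SNVs. The headline
#' statistic is the modal class of the spectrum pooled over all
#' replicate cohorts (the claim about real cohorts is a pooled one);
#' per-cohort modes are reported alongside.
#'
#' @param config a [sim_config()].
#' @param n_seeds number of replicate cohorts (seed offsets).
#' @return list with `per_seed` (data.frame: `seed`, `modal_class`,
#'   `ct_fraction`), `pooled_class6` (summed counts), `pooled_modal`
#'   and `pooled_ct_fraction`.
#' @export
experiment_spectrum_modal <- function(config = sim_config(), n_seeds = 3L) {
  gen <- generate_reference(config)
  cache <- simulation_cache(gen$reference, gen$genes, config)
  pooled <- stats::setNames(integer(6), .SUBCLASS6)
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    co <- simulate_cohort(gen$reference, gen$genes, cfg_i, cache)
    kept <- filter_exome(co$calls)$kept
    ann <- annotate_variants(kept, gen$genes, gen$reference, cache$structures)
    spec <- spectrum_summary(ann)
    pooled <<- pooled + spec$class6
    data.frame(seed = cfg_i$seed, modal_class = spec$modal_class,
               ct_fraction = unname(spec$class6["C>T"] / sum(spec$class6)))
  })
  list(per_seed = do.call(rbind, rows), pooled_class6 = pooled,
       pooled_modal = names(pooled)[which.max(pooled)],
       pooled_ct_fraction = unname(pooled["C>T"] / sum(pooled)))
}
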