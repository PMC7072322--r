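.CALL_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "var_class",
                   "tumor_depth", "tumor_alt", "normal_depth", "normal_alt",
                   "alt_forward", "alt_reverse", "variant_score",
                   "base_quality_min", "call_quality", "barcode_pairs",
                   "known_variant")

.ARTIFACT_TYPES <- c(low_depth = "EX1", normal_support = "EX3",
                     strand_bias = "EX4", known = "EX5")

#' Simulation configuration
#'
#' Defines a synthetic tumor/normal cohort: a toy reference with a
#' controlled CpG dinucleotide density, non-overlapping two-exon CDS
#' gene models, per-category somatic mutation rates, optional "driver"
#' genes with an elevated nonsynonymous rate, and rates of injected
#' filter-failing artifact records.
#'
#' Default mutation rates give a total point-mutation burden of about
#' 6.9 per Mb per sample (CpG sites mutate 10x faster than non-CpG
#' sites, the usual deamination excess), within the per-Mb burden range
#' reported for early gastric cancer exomes; see the package vignette
#' for how the defaults were fixed.
#'
#' @param seed integer RNG seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @param n_samples number of tumor/normal pairs.
#' @param n_chromosomes,chromosome_length genome shape (bp).
#' @param cpg_density target fraction of dinucleotide positions that are
#'   CpG.
#' @param n_genes,gene_cds_length gene count and CDS length (bp, must be
#'   a multiple of 3; each gene gets two CDS exons split by a 100 bp
#'   intron, alternating strand).
#' @param rate_cpg,rate_noncpg point mutations per (non-)CpG site per
#'   sample.
#' @param rate_indel indels per bp per sample.
#' @param driver_genes named numeric vector: nonsynonymous rate
#'   multiplier (>= 1) per spiked gene id.
#' @param artifact_rates named numeric vector, expected count per sample
#'   of records violating exactly one exome filter criterion; names must
#'   be among `low_depth` (EX1), `normal_support` (EX3), `strand_bias`
#'   (EX4), `known` (EX5).
#' @param depth_mean mean sequencing depth (reads).
#' @param vaf_mean mean variant allele fraction of true somatic events.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_samples = 19L, n_chromosomes = 2L,
                       chromosome_length = 5e5, cpg_density = 0.02,
                       n_genes = 200L, gene_cds_length = 600L,
                       rate_cpg = 5e-5, rate_noncpg = 5e-6,
                       rate_indel = 5e-7, driver_genes = NULL,
                       artifact_rates = c(low_depth = 2, normal_support = 2,
                                          strand_bias = 2, known = 2),
                       depth_mean = 105, vaf_mean = 0.3) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              cpg_density = cpg_density, n_genes = as.integer(n_genes),
              gene_cds_length = as.integer(gene_cds_length),
              rate_cpg = rate_cpg, rate_noncpg = rate_noncpg,
              rate_indel = rate_indel, driver_genes = driver_genes,
              artifact_rates = artifact_rates, depth_mean = depth_mean,
              vaf_mean = vaf_mean)
  rates <- c(cfg$rate_cpg, cfg$rate_noncpg, cfg$rate_indel, cfg$artifact_rates)
  if (any(!is.finite(rates)) || any(rates < 0)) stop("all rates must be finite and >= 0")
  if (cfg$gene_cds_length %% 3L != 0L) stop("gene_cds_length must be a multiple of 3")
  if (cfg$cpg_density < 0 || cfg$cpg_density > 0.4) stop("cpg_density must be in [0, 0.4]")
  if (length(cfg$driver_genes) && any(cfg$driver_genes < 1)) {
    stop("driver multipliers must be >= 1")
  }
  if (length(cfg$artifact_rates)) {
    bad <- setdiff(names(cfg$artifact_rates), names(.ARTIFACT_TYPES))
    if (length(bad)) stop("unknown artifact type(s): ", paste(bad, collapse = ", "))
  }
  if (cfg$depth_mean < 1) stop("depth_mean must be >= 1")
  if (cfg$vaf_mean <= 0 || cfg$vaf_mean > 1) stop("vaf_mean must be in (0, 1]")
  structure(cfg, class = "sim_config")
}

# CpG-free random sequence, then exact planting of round(d * (L-1)) CG
# dinucleotides at odd positions, so the realized density is controlled.
.sim_chromosome <- function(L, cpg_density) {
  x <- sample(.BASES, L, replace = TRUE)
  repeat {
    i <- which(x[-L] == "C" & x[-1L] == "G")
    if (!length(i)) break
    x[i + 1L] <- sample(c("A", "C", "T"), length(i), replace = TRUE)
  }
  k <- round(cpg_density * (L - 1L))
  if (k > 0L) {
    cand <- seq(1L, L - 1L, by = 2L)
    p <- sample(cand, k)
    x[p] <- "C"
    x[p + 1L] <- "G"
  }
  paste(x, collapse = "")
}

#' Generate a toy reference genome with gene models
#'
#' Chromosomes are uniform-random A/C/G/T with the CpG dinucleotide
#' density forced to `cpg_density` (CpG is otherwise depleted to zero,
#' then planted exactly). Genes are laid out round-robin across
#' chromosomes on an even pitch, each a two-exon CDS of
#' `gene_cds_length` bp with alternating strand; gene ids are
#' `G001, G002, ...` and never overlap.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (a `ReferenceGenome`) and `genes`
#'   (gene model table).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chromosome_length
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  seqs <- vapply(chroms, function(ch) .sim_chromosome(L, config$cpg_density),
                 character(1))
  ref <- as_reference(seqs)

  n_genes <- config$n_genes
  if (n_genes == 0L) {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0))
    return(list(reference = ref, genes = genes))
  }
  intron <- 100L
  footprint <- config$gene_cds_length + intron
  chrom_of <- chroms[(seq_len(n_genes) - 1L) %% length(chroms) + 1L]
  rows <- vector("list", n_genes)
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    m <- length(idx)
    if (m == 0L) next
    pitch <- (L - 200L) %/% m
    if (pitch < footprint + 20L || 100L + (m - 1L) * pitch + footprint > L - 10L) {
      stop(sprintf(paste0("cannot place %d genes of %d bp CDS on a %d bp ",
                          "chromosome: reduce n_genes or gene_cds_length"),
                   m, config$gene_cds_length, L))
    }
    for (j in seq_len(m)) {
      i <- idx[j]
      start0 <- 100L + (j - 1L) * pitch
      e1 <- (config$gene_cds_length %/% 6L) * 3L  # exon split keeps frame tidy
      if (e1 < 3L) e1 <- 3L
      e2 <- config$gene_cds_length - e1
      gid <- sprintf("G%03d", i)
      strand <- if (i %% 2L == 1L) "+" else "-"
      rows[[i]] <- data.frame(
        gene_id = gid, chrom = ch,
        start = c(start0, start0 + e1 + intron),
        end = c(start0 + e1, start0 + e1 + intron + e2),
        strand = strand, stringsAsFactors = FALSE
      )
    }
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  validate_genes(genes, ref)
  if (length(config$driver_genes)) {
    missing_drv <- setdiff(names(config$driver_genes), genes$gene_id)
    if (length(missing_drv)) stop("driver gene id(s) not generated: ",
                                  paste(missing_drv, collapse = ", "))
  }
  list(reference = ref, genes = genes)
}

#' Precompute per-reference simulation tables
#'
#' CpG/non-CpG site partitions per chromosome, gene coding structures
#' and driver-gene nonsynonymous opportunity tables. Reusable across
#' replicate cohorts simulated from the same reference.
#'
#' @param ref `ReferenceGenome`.
#' @param genes gene model table.
#' @param config a [sim_config()].
#' @return an opaque cache list for [simulate_cohort()].
#' @export
simulation_cache <- function(ref, genes, config) {
  chroms <- names(unclass(ref))
  sites <- lapply(chroms, function(ch) {
    L <- nchar(.ref_seq(ref, ch))
    cpg <- cpg_site_positions(ref, ch)
    list(L = L, cpg = cpg,
         noncpg = setdiff(seq_len(L), cpg))
  })
  names(sites) <- chroms
  structures <- if (nrow(genes)) .gene_structures(genes, ref) else list()
  drivers <- list()
  for (g in names(config$driver_genes)) {
    st <- structures[[g]]
    cl <- st$coding_length
    cidx <- seq_len(cl) - 1L
    codon <- substring(st$spliced, (cidx %/% 3L) * 3L + 1L,
                       (cidx %/% 3L) * 3L + 3L)
    picod <- cidx %% 3L + 1L
    ns_thirds <- 3L - .SYN_THIRDS[cbind(match(codon, rownames(.SYN_THIRDS)),
                                        picod)]
    gp <- st$gpos
    iscpg <- cpg_status(ref, st$chrom, gp)
    rate <- ifelse(iscpg, config$rate_cpg, config$rate_noncpg)
    w <- rate * ns_thirds / 3
    drivers[[g]] <- list(st = st, cidx = cidx, codon = codon, picod = picod,
                         gpos = gp, weight = w, lambda1 = sum(w))
  }
  list(sites = sites, structures = structures, drivers = drivers)
}

.true_evidence <- function(n, depth_mean, vaf_mean) {
  td <- pmax(stats::rpois(n, depth_mean), 30L)
  ta <- stats::rbinom(n, td, vaf_mean)
  ta <- pmin(pmax(ta, 3L, ceiling(0.10 * td)), td)
  nd <- pmax(stats::rpois(n, depth_mean), 30L)
  na_ <- pmin(stats::rbinom(n, nd, 0.002), 1L)
  lo <- ceiling(0.2 * ta)
  fwd <- pmin(pmax(stats::rbinom(n, ta, 0.5), lo), ta - lo)
  data.frame(
    tumor_depth = td, tumor_alt = ta, normal_depth = nd, normal_alt = na_,
    alt_forward = as.integer(fwd), alt_reverse = as.integer(ta - fwd),
    variant_score = round(stats::runif(n, 0.3, 1), 4),
    base_quality_min = sample(30:41, n, replace = TRUE),
    call_quality = round(stats::runif(n, 100, 250), 1),
    barcode_pairs = 2L + stats::rpois(n, 2),
    known_variant = rep(FALSE, n)
  )
}

.alt_for_snv <- function(refbase, iscpg) {
  n <- length(refbase)
  alt <- character(n)
  # CpG sites: deamination-biased (C>T / G>A with probability 0.8)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    b <- refbase[i]
    others <- setdiff(.BASES, b)
    if (iscpg[i] && b == "C") {
      alt[i] <- if (u[i] < 0.8) "T" else sample(c("A", "G"), 1L)
    } else if (iscpg[i] && b == "G") {
      alt[i] <- if (u[i] < 0.8) "A" else sample(c("C", "T"), 1L)
    } else {
      alt[i] <- others[1L + floor(u[i] * 3)]
    }
  }
  alt
}

.sample_positions <- function(pool, n) {
  if (n <= 0L || length(pool) == 0L) return(integer(0))
  pool[sample.int(length(pool), min(n, length(pool)))]
}

.driver_nonsyn_alt <- function(drv, j) {
  # j: 1-based index into coding positions; returns genomic ref/alt
  codon <- drv$codon[j]; p <- drv$picod[j]
  aa <- .GENETIC_CODE[[codon]]
  alts <- character(0)
  for (b in setdiff(.BASES, substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- b
    if (.GENETIC_CODE[[mut]] != aa) alts <- c(alts, b)
  }
  a <- if (length(alts) == 1L) alts else sample(alts, 1L)
  st <- drv$st
  refc <- substr(codon, p, p)
  if (st$strand == "-") list(ref = .complement(refc), alt = .complement(a))
  else list(ref = refc, alt = a)
}

#' Simulate a tumor/normal variant-call cohort
#'
#' True somatic SNVs are drawn per site category as Poisson processes
#' (CpG sites at `rate_cpg`, non-CpG at `rate_noncpg`; CpG substitutions
#' are deamination-biased towards C>T); indels are drawn per bp; driver
#' genes receive additional nonsynonymous mutations so their effective
#' nonsynonymous rate is the multiplied background rate. Read evidence
#' of true events is drawn around `depth_mean`/`vaf_mean` and then
#' minimally and deterministically adjusted so every true event passes
#' the exome filter by construction (depth to at least 30, mutant reads
#' to at least max(3, 10% of depth), strand split clamped into the
#' passing band, at most one normal mutant read). Artifact records are
#' injected per `artifact_rates`, each violating exactly one labelled
#' criterion. A truth table accompanies the calls.
#'
#' @param ref,genes output of [generate_reference()].
#' @param config a [sim_config()].
#' @param cache optional [simulation_cache()]; rebuilt if `NULL`.
#' @return list with `calls` (all samples, one row per record) and
#'   `truth` (`class` is `"true"` or `"artifact"`, `criterion` the
#'   violated exome label for artifacts).
#' @export
simulate_cohort <- function(ref, genes, config, cache = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 10007L) %% .Machine$integer.max)
  if (is.null(cache)) cache <- simulation_cache(ref, genes, config)
  chroms <- names(cache$sites)
  out <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- sprintf("S%02d", s)
    recs <- list()
    for (ch in chroms) {
      site <- cache$sites[[ch]]
      seqch <- .ref_seq(ref, ch)
      # CpG and non-CpG point mutations
      for (cat in c("cpg", "noncpg")) {
        pool <- site[[cat]]
        rate <- if (cat == "cpg") config$rate_cpg else config$rate_noncpg
        n <- stats::rpois(1L, length(pool) * rate)
        pos <- .sample_positions(pool, n)
        if (!length(pos)) next
        rb <- substring(seqch, pos, pos)
        alt <- .alt_for_snv(rb, rep(cat == "cpg", length(pos)))
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = ch, pos = pos, ref = rb, alt = alt, var_class = "SNV",
          stringsAsFactors = FALSE)
      }
      # indels
      n_ind <- stats::rpois(1L, site$L * config$rate_indel)
      if (n_ind > 0L) {
        pos <- sample.int(site$L - 5L, n_ind)
        is_del <- stats::runif(n_ind) < 0.5
        len <- sample(1:3, n_ind, replace = TRUE)
        anchor <- substring(seqch, pos, pos)
        refa <- ifelse(is_del, substring(seqch, pos, pos + len), anchor)
        alt <- ifelse(is_del, anchor,
                      paste0(anchor,
                             vapply(len, function(k)
                               paste(sample(.BASES, k, replace = TRUE),
                                     collapse = ""), character(1))))
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = ch, pos = pos, ref = refa, alt = alt,
          var_class = ifelse(is_del, "deletion", "insertion"),
          stringsAsFactors = FALSE)
      }
    }
    # driver spikes: extra nonsynonymous mutations at (multiplier - 1) x base
    for (g in names(cache$drivers)) {
      drv <- cache$drivers[[g]]
      mult <- config$driver_genes[[g]]
      n <- stats::rpois(1L, (mult - 1) * drv$lambda1)
      if (n == 0L) next
      j <- sample.int(length(drv$weight), n, replace = FALSE,
                      prob = drv$weight)
      dd <- lapply(j, function(jj) {
        ra <- .driver_nonsyn_alt(drv, jj)
        data.frame(chrom = drv$st$chrom, pos = drv$gpos[jj], ref = ra$ref,
                   alt = ra$alt, var_class = "SNV", stringsAsFactors = FALSE)
      })
      recs[[length(recs) + 1L]] <- do.call(rbind, dd)
    }
    true_df <- if (length(recs)) do.call(rbind, recs) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), var_class = character(0))
    if (nrow(true_df)) {
      true_df <- true_df[!duplicated(paste(true_df$chrom, true_df$pos)), ,
                         drop = FALSE]
      ev <- .true_evidence(nrow(true_df), config$depth_mean, config$vaf_mean)
      true_df <- cbind(sample_id = sid, true_df, ev)
      true_df$class <- "true"
      true_df$criterion <- NA_character_
    }
    # artifact records, each violating exactly one exome criterion
    arts <- list()
    for (ty in names(config$artifact_rates)) {
      n <- stats::rpois(1L, config$artifact_rates[[ty]])
      if (n == 0L) next
      ch <- sample(chroms, n, replace = TRUE)
      pos <- vapply(ch, function(c2) sample.int(cache$sites[[c2]]$L - 2L, 1L) + 1L,
                    integer(1))
      rb <- ref_base(ref, ch, pos)
      alt <- vapply(rb, function(b) sample(setdiff(.BASES, b), 1L), character(1))
      ev <- .true_evidence(n, config$depth_mean, config$vaf_mean)
      if (ty == "low_depth") {
        ev$tumor_depth <- sample(10:29, n, replace = TRUE)
        ev$tumor_alt <- pmax(3L, ceiling(0.1 * ev$tumor_depth))
      } else if (ty == "normal_support") {
        ev$normal_alt <- sample(2:6, n, replace = TRUE)
      } else if (ty == "strand_bias") {
        ev$tumor_alt <- pmin(pmax(ev$tumor_alt, 10L), ev$tumor_depth)
      } else if (ty == "known") {
        ev$known_variant <- TRUE
      }
      fwd <- if (ty == "strand_bias") {
        pmax(0L, as.integer(ceiling(0.2 * ev$tumor_alt) - 1L))
      } else {
        lo <- ceiling(0.2 * ev$tumor_alt)
        as.integer(pmin(pmax(stats::rbinom(n, ev$tumor_alt, 0.5), lo),
                        ev$tumor_alt - lo))
      }
      ev$alt_forward <- fwd
      ev$alt_reverse <- as.integer(ev$tumor_alt - fwd)
      a <- cbind(sample_id = sid,
                 data.frame(chrom = ch, pos = as.integer(pos), ref = rb,
                            alt = alt, var_class = "SNV",
                            stringsAsFactors = FALSE),
                 ev)
      a$class <- "artifact"
      a$criterion <- .ARTIFACT_TYPES[[ty]]
      arts[[length(arts) + 1L]] <- a
    }
    samp <- rbind(if (nrow(true_df)) true_df, do.call(rbind, arts))
    if (!is.null(samp) && nrow(samp)) {
      samp <- samp[!duplicated(paste(samp$chrom, samp$pos)), , drop = FALSE]
      samp <- samp[order(samp$chrom, samp$pos), , drop = FALSE]
      out[[length(out) + 1L]] <- samp
    }
  }
  all <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(all)) {
    empty <- data.frame(matrix(nrow = 0, ncol = length(.CALL_COLUMNS)))
    names(empty) <- .CALL_COLUMNS
    return(list(calls = empty,
                truth = cbind(empty[0, c("sample_id", "chrom", "pos", "ref",
                                         "alt", "var_class")],
                              data.frame(class = character(0),
                                         criterion = character(0)))))
  }
  rownames(all) <- NULL
  truth <- all[, c("sample_id", "chrom", "pos", "ref", "alt", "var_class",
                   "class", "criterion")]
  calls <- all[, .CALL_COLUMNS]
  list(calls = calls, truth = truth)
}

.BETHESDA_MARKERS <- c("BAT25", "BAT26", "D2S123", "D5S346", "D17S250")

#' Simulate Bethesda-panel instability profiles
#'
#' Each sample receives five independent Bernoulli instability flags,
#' one per Bethesda marker (BAT25, BAT26, D2S123, D5S346, D17S250).
#'
#' @param n_samples number of samples.
#' @param marker_instability_prob per-marker instability probabilities
#'   (length 5, or a scalar recycled).
#' @param seed RNG seed.
#' @return data.frame: `sample_id` plus one logical column per marker.
#' @export
simulate_msi_profiles <- function(n_samples,
                                  marker_instability_prob = rep(0.1, 5),
                                  seed = 1L) {
  p <- rep_len(marker_instability_prob, 5L)
  if (any(p < 0 | p > 1)) stop("marker instability probabilities must be in [0, 1]")
  set.seed(as.integer(seed))
  flags <- vapply(p, function(pp) stats::runif(n_samples) < pp,
                  logical(n_samples))
  flags <- matrix(flags, nrow = n_samples,
                  dimnames = list(NULL, .BETHESDA_MARKERS))
  cbind(data.frame(sample_id = sprintf("S%02d", seq_len(n_samples))),
        as.data.frame(flags))
}
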