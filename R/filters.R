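#' Somatic filter thresholds
#'
#' Default thresholds of the two published filter rulesets. The exome
#' (discovery-stage) ruleset: tumor depth >= 30 with >= 3 mutant reads
#' (EX1), mutant allele fraction >= 10% of all reads (EX2), normal depth
#' >= 30 with <= 1 mutant read (EX3), minimum per-strand fraction of
#' mutant reads >= 0.2 (EX4), and exclusion of known population variants
#' (dbSNP 137 / HapMap / 1000 Genomes membership flag; EX5). The
#' targeted (deep-sequencing) ruleset: variant score >= 0.3 and minimum
#' base quality 30 (TG1), call quality >= 100 (TG2), allele frequency >=
#' 0.1 (TG3), >= 10 mutant reads (TG4), >= 2 read pairs per barcode
#' (TG5), and the known-variant exclusion (TG6). Overriding any default
#' is recorded on the returned [filter_exome()] report.
#'
#' @param ... named threshold overrides.
#' @return named list of thresholds.
#' @export
exome_thresholds <- function(...) {
  .merge_thresholds(list(
    min_tumor_depth = 30, min_tumor_alt = 3, min_vaf = 0.10,
    min_normal_depth = 30, max_normal_alt = 1, min_strand_fraction = 0.2
  ), ...)
}

#' @rdname exome_thresholds
#' @export
targeted_thresholds <- function(...) {
  .merge_thresholds(list(
    min_variant_score = 0.3, min_base_quality = 30, min_call_quality = 100,
    min_vaf = 0.1, min_tumor_alt = 10, min_barcode_pairs = 2
  ), ...)
}

.merge_thresholds <- function(defaults, ...) {
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    defaults[names(ov)] <- ov
    attr(defaults, "non_default") <- names(ov)
  }
  defaults
}

.filter_report <- function(calls, crit, labels, ruleset, thresholds) {
  pass <- rowSums(!crit) == 0L
  viol <- lapply(which(!pass), function(i) labels[!crit[i, ]])
  rejected <- calls[!pass, , drop = FALSE]
  rejected$criteria <- viol
  rownames(rejected) <- NULL
  kept <- calls[pass, , drop = FALSE]
  rownames(kept) <- NULL
  structure(
    list(kept = kept, rejected = rejected, ruleset = ruleset,
         thresholds = thresholds,
         non_default = attr(thresholds, "non_default") %||% character(0)),
    class = "FilterReport"
  )
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport (%s): %d kept, %d rejected\n",
              x$ruleset, nrow(x$kept), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    tab <- sort(table(unlist(x$rejected$criteria)), decreasing = TRUE)
    cat("  violations:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
  }
  if (length(x$non_default)) {
    cat("  NOTE: non-default thresholds in effect:",
        paste(x$non_default, collapse = ", "), "\n")
  }
  invisible(x)
}

.check_call_invariants <- function(calls) {
  .assert_columns(calls, c("sample_id", "chrom", "pos", "ref", "alt",
                           "var_class", "tumor_depth", "tumor_alt",
                           "normal_depth", "normal_alt", "alt_forward",
                           "alt_reverse", "known_variant"), "variant calls")
  with(calls, {
    stopifnot(all(tumor_alt <= tumor_depth), all(normal_alt <= normal_depth),
              all(alt_forward + alt_reverse == tumor_alt), all(pos >= 1))
  })
  invisible(calls)
}

#' Exome-stage somatic filter
#'
#' Applies the five discovery-stage criteria (see [exome_thresholds()]);
#' thresholds are inclusive ("at least"/"at most"), and the strand test
#' excludes records whose minimum per-strand fraction of mutant reads is
#' strictly below 0.2. A record with zero mutant reads is rejected under
#' EX1 without evaluating the undefined strand ratio. Rejected records
#' carry every violated criterion, not just the first.
#'
#' @param calls variant call data.frame.
#' @param thresholds output of [exome_thresholds()].
#' @return a `FilterReport`: list with `kept`, `rejected` (with a
#'   `criteria` list-column of violated labels), `ruleset`, `thresholds`.
#' @export
filter_exome <- function(calls, thresholds = exome_thresholds()) {
  .check_call_invariants(calls)
  if (length(attr(thresholds, "non_default"))) {
    message("filter_exome: non-default thresholds in effect (",
            paste(attr(thresholds, "non_default"), collapse = ", "), ")")
  }
  th <- thresholds
  dp <- calls$tumor_depth; alt <- calls$tumor_alt
  c1 <- dp >= th$min_tumor_depth & alt >= th$min_tumor_alt
  c2 <- ifelse(dp > 0, alt / dp >= th$min_vaf, FALSE)
  c3 <- calls$normal_depth >= th$min_normal_depth &
    calls$normal_alt <= th$max_normal_alt
  c4 <- ifelse(alt > 0,
               pmin(calls$alt_forward, calls$alt_reverse) / pmax(alt, 1) >=
                 th$min_strand_fraction,
               TRUE)  # undefined ratio: record already fails EX1
  c5 <- !calls$known_variant
  crit <- cbind(c1, c2, c3, c4, c5)
  .filter_report(calls, crit, paste0("EX", 1:5), "exome", thresholds)
}

#' Targeted-stage somatic filter
#'
#' Applies the six deep-sequencing criteria (see
#' [targeted_thresholds()]). The score/quality annotations
#' (`variant_score`, `base_quality_min`, `call_quality`,
#' `barcode_pairs`) must be present and non-missing; a missing
#' annotation is an error naming the field, never a silent pass.
#'
#' @param calls variant call data.frame.
#' @param thresholds output of [targeted_thresholds()].
#' @return a `FilterReport` (see [filter_exome()]); labels TG1..TG6.
#' @export
filter_targeted <- function(calls, thresholds = targeted_thresholds()) {
  .check_call_invariants(calls)
  ann <- c("variant_score", "base_quality_min", "call_quality", "barcode_pairs")
  .assert_columns(calls, ann, "variant calls")
  for (f in ann) {
    if (anyNA(calls[[f]])) stop("missing values in required annotation field: ", f)
  }
  if (length(attr(thresholds, "non_default"))) {
    message("filter_targeted: non-default thresholds in effect (",
            paste(attr(thresholds, "non_default"), collapse = ", "), ")")
  }
  th <- thresholds
  c1 <- calls$variant_score >= th$min_variant_score &
    calls$base_quality_min >= th$min_base_quality
  c2 <- calls$call_quality >= th$min_call_quality
  c3 <- ifelse(calls$tumor_depth > 0,
               calls$tumor_alt / calls$tumor_depth >= th$min_vaf, FALSE)
  c4 <- calls$tumor_alt >= th$min_tumor_alt
  c5 <- calls$barcode_pairs >= th$min_barcode_pairs
  c6 <- !calls$known_variant
  crit <- cbind(c1, c2, c3, c4, c5, c6)
  .filter_report(calls, crit, paste0("TG", 1:6), "targeted", thresholds)
}

#' Write rejection reasons to a sidecar TSV
#'
#' @param report a `FilterReport`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_sidecar <- function(report, path) {
  rej <- report$rejected
  out <- data.frame(
    sample_id = rej$sample_id, chrom = rej$chrom, pos = rej$pos,
    ref = rej$ref, alt = rej$alt,
    criteria = vapply(rej$criteria, paste, character(1), collapse = ";")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
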