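.VCF_META <- c(
  "##fileformat=VCFv4.2",
  "##source=earlygc",
  "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Listed in dbSNP 137, HapMap or 1000 Genomes\">",
  "##INFO=<ID=VS,Number=1,Type=Float,Description=\"Variant score\">",
  "##INFO=<ID=CQ,Number=1,Type=Float,Description=\"Variant call quality\">",
  "##INFO=<ID=BC,Number=1,Type=Integer,Description=\"Read pairs per barcode\">",
  "##INFO=<ID=MBQ,Number=1,Type=Integer,Description=\"Minimum base quality over variant-supporting reads\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
  "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Allelic depths, forward strand\">",
  "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Allelic depths, reverse strand\">"
)

#' Write one sample's calls as a tumor/normal VCF
#'
#' Emits VCF v4.2 with TUMOR and NORMAL genotype columns carrying
#' DP/AD/ADF/ADR, and INFO fields VS, CQ, BC, MBQ plus the KNOWN flag.
#' Reference-allele strand depths are not tracked internally and are
#' written as an even split; all contract fields round-trip losslessly.
#' The file is bgzip-compressed (`.vcf.gz`), the form `vcfR` writes.
#'
#' @param calls variant call data.frame for a single sample.
#' @param path output path ending in `.vcf.gz`.
#' @return `path`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_vcf <- function(calls, path) {
  .check_call_invariants(calls)
  if (length(unique(calls$sample_id)) > 1L) {
    stop("write_vcf writes one sample pair per file; split by sample_id")
  }
  if (!grepl("\\.vcf\\.gz$", path)) stop("path must end in .vcf.gz")
  n <- nrow(calls)
  info <- sprintf("VS=%s;CQ=%s;BC=%d;MBQ=%d",
                  format(calls$variant_score, trim = TRUE),
                  format(calls$call_quality, trim = TRUE),
                  calls$barcode_pairs, calls$base_quality_min)
  info <- ifelse(calls$known_variant, paste0(info, ";KNOWN"), info)
  fix <- matrix(NA_character_, nrow = n, ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  fix[, "CHROM"] <- calls$chrom
  fix[, "POS"] <- as.character(calls$pos)
  fix[, "ID"] <- "."
  fix[, "REF"] <- calls$ref
  fix[, "ALT"] <- calls$alt
  fix[, "QUAL"] <- "."
  fix[, "FILTER"] <- "."
  fix[, "INFO"] <- if (n) info else character(0)
  tref <- calls$tumor_depth - calls$tumor_alt
  trf <- ceiling(tref / 2); nref <- calls$normal_depth - calls$normal_alt
  nrf <- ceiling(nref / 2); naf <- ceiling(calls$normal_alt / 2)
  tumor <- sprintf("%d:%d,%d:%d,%d:%d,%d", calls$tumor_depth, tref,
                   calls$tumor_alt, trf, calls$alt_forward, tref - trf,
                   calls$alt_reverse)
  normal <- sprintf("%d:%d,%d:%d,%d:%d,%d", calls$normal_depth, nref,
                    calls$normal_alt, nrf, naf, nref - nrf,
                    calls$normal_alt - naf)
  gt <- cbind(FORMAT = rep("DP:AD:ADF:ADR", n), TUMOR = tumor, NORMAL = normal)
  if (n == 0L) gt <- gt[0, , drop = FALSE]
  obj <- methods::new("vcfR", meta = .VCF_META, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

.split_field <- function(x, idx) {
  as.integer(vapply(strsplit(x, ",", fixed = TRUE), `[`, character(1), idx))
}

#' Read a tumor/normal VCF into variant call records
#'
#' Inverse of [write_vcf()]. Multi-allelic rows are rejected with an
#' instruction to split them; a missing required FORMAT or INFO field is
#' an error naming the field.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param sample_id sample identifier to stamp on the records; defaults
#'   to the file name stem.
#' @return variant call data.frame.
#' @export
read_vcf <- function(path, sample_id = sub("\\.vcf(\\.gz)?$", "",
                                           basename(path))) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    empty <- data.frame(matrix(nrow = 0, ncol = length(.CALL_COLUMNS)))
    names(empty) <- .CALL_COLUMNS
    return(empty)
  }
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multi-allelic record(s) in ", basename(path),
         ": split into biallelic rows before import")
  }
  cols <- colnames(v@gt)
  if (!all(c("TUMOR", "NORMAL") %in% cols)) {
    stop("VCF must carry TUMOR and NORMAL genotype columns")
  }
  fmt <- unique(v@gt[, "FORMAT"])
  for (f in c("DP", "AD", "ADF", "ADR")) {
    if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                    function(x) f %in% x, logical(1)))) {
      stop("required FORMAT field missing from VCF: ", f)
    }
  }
  g <- function(el, col) vcfR::extract.gt(v, element = el)[, col]
  info <- function(f) {
    x <- vcfR::extract.info(v, element = f)
    if (all(is.na(x))) stop("required INFO field missing from VCF: ", f)
    x
  }
  ref <- unname(fix[, "REF"]); alt <- unname(fix[, "ALT"])
  var_class <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                      ifelse(nchar(ref) > nchar(alt), "deletion", "insertion"))
  calls <- data.frame(
    sample_id = sample_id,
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt, var_class = var_class,
    tumor_depth = as.integer(g("DP", "TUMOR")),
    tumor_alt = .split_field(g("AD", "TUMOR"), 2L),
    normal_depth = as.integer(g("DP", "NORMAL")),
    normal_alt = .split_field(g("AD", "NORMAL"), 2L),
    alt_forward = .split_field(g("ADF", "TUMOR"), 2L),
    alt_reverse = .split_field(g("ADR", "TUMOR"), 2L),
    variant_score = as.numeric(info("VS")),
    base_quality_min = as.integer(info("MBQ")),
    call_quality = as.numeric(info("CQ")),
    barcode_pairs = as.integer(info("BC")),
    known_variant = !is.na(vcfR::extract.info(v, element = "KNOWN",
                                              as.numeric = FALSE)),
    stringsAsFactors = FALSE
  )
  # Flag INFO fields come back NA when absent; recompute from raw INFO
  calls$known_variant <- grepl("(^|;)KNOWN(;|$)", fix[, "INFO"])
  .check_call_invariants(calls)
  calls
}

#' Write a cohort as per-sample tumor/normal VCFs
#'
#' @param calls multi-sample variant call data.frame.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_cohort_vcfs <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(calls$sample_id))
  paths <- vapply(ids, function(s) {
    p <- file.path(dir, paste0(s, ".vcf.gz"))
    write_vcf(calls[calls$sample_id == s, , drop = FALSE], p)
    p
  }, character(1))
  paths
}

#' Read a directory of per-sample VCFs
#'
#' @param dir directory of `.vcf`/`.vcf.gz` files.
#' @return combined variant call data.frame.
#' @export
read_cohort_vcfs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.vcf(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no VCF files in ", dir)
  do.call(rbind, lapply(files, read_vcf))
}
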