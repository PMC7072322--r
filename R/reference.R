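#' Reference genome container
#'
#' Internally a reference is a named character vector of uppercase
#' chromosome sequences (alphabet A/C/G/T/N), wrapped in class
#' `"ReferenceGenome"`. Character storage makes single-base and
#' context lookups O(1) via `substr()`.
#'
#' @param x a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return a `ReferenceGenome` object.
#' @export
as_reference <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reference must be a named character vector or DNAStringSet")
  }
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("reference sequences contain non-ACGTN characters: ",
         paste(names(x)[bad], collapse = ", "))
  }
  structure(x, class = "ReferenceGenome")
}

#' Read / write a reference FASTA
#'
#' @param path FASTA file path.
#' @return `read_reference()` returns a [as_reference()] object;
#'   `write_reference()` returns `path` invisibly.
#' @export
read_reference <- function(path) {
  as_reference(Biostrings::readDNAStringSet(path))
}

#' @rdname read_reference
#' @param ref a `ReferenceGenome`.
#' @export
write_reference <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x), "sequence(s),",
      sum(nchar(unclass(x))), "bp total\n")
  invisible(x)
}

.ref_seq <- function(ref, chrom) {
  s <- unclass(ref)[[chrom]]
  if (is.null(s) || is.na(s)) stop("chromosome not in reference: ", chrom)
  s
}

#' Base and trinucleotide context lookup
#'
#' `ref_base()` returns the reference base at 1-based `pos`;
#' `ref_triplet()` returns the pos-1..pos+1 trinucleotide, or `NA` at
#' sequence edges (contexts never wrap).
#'
#' @param ref a `ReferenceGenome`.
#' @param chrom chromosome name (recycled against `pos`).
#' @param pos 1-based positions.
#' @return character vector.
#' @export
ref_base <- function(ref, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  out <- character(n)
  for (ch in unique(chrom)) {
    s <- .ref_seq(ref, ch); i <- which(chrom == ch)
    bad <- pos[i] < 1L | pos[i] > nchar(s)
    if (any(bad)) stop("position out of bounds on ", ch)
    out[i] <- substring(s, pos[i], pos[i])
  }
  out
}

#' @rdname ref_base
#' @export
ref_triplet <- function(ref, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    s <- .ref_seq(ref, ch); i <- which(chrom == ch)
    ok <- pos[i] >= 2L & pos[i] <= nchar(s) - 1L
    out[i[ok]] <- substring(s, pos[i][ok] - 1L, pos[i][ok] + 1L)
  }
  out
}

#' Is a site part of a CpG dinucleotide?
#'
#' A site is a CpG site if it is the C of a CG dinucleotide or the G of
#' a CG dinucleotide (the complementary strand reads CG through the same
#' two bases). A/T/N sites are `FALSE` by definition, as is any site
#' whose relevant neighbour is N or off the sequence end.
#'
#' @inheritParams ref_base
#' @return logical vector.
#' @export
cpg_status <- function(ref, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  out <- logical(n)
  for (ch in unique(chrom)) {
    s <- .ref_seq(ref, ch); L <- nchar(s); i <- which(chrom == ch)
    p <- pos[i]
    b <- substring(s, p, p)
    nxt <- ifelse(p < L, substring(s, p + 1L, p + 1L), "")
    prv <- ifelse(p > 1L, substring(s, p - 1L, p - 1L), "")
    out[i] <- (b == "C" & nxt == "G") | (b == "G" & prv == "C")
  }
  out
}

#' Positions of all CpG sites on one chromosome
#'
#' Returns the sorted 1-based positions of every base belonging to a CG
#' dinucleotide (both the C and the G count as CpG sites).
#'
#' @inheritParams ref_base
#' @return integer vector of positions.
#' @export
cpg_site_positions <- function(ref, chrom) {
  s <- .ref_seq(ref, chrom)
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  sort(unique(c(m, m + 1L)))
}
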