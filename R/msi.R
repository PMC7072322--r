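#' Bethesda microsatellite instability classification
#'
#' Classifies a sample from its per-marker instability flags over the
#' Bethesda panel (BAT25, BAT26, D2S123, D5S346, D17S250): instability
#' in more than 30% of markers is MSI-high (MSI-H), instability in more
#' than none but at most 30% is MSI-low (MSI-L), and no unstable marker
#' is microsatellite-stable (MSS). A hypothetical exact 30% fraction is
#' classed MSI-L (MSI-H requires strictly more than 30%); with the
#' 5-marker panel that boundary is unreachable, but the rule is fixed
#' for generic panel sizes.
#'
#' @param flags logical vector of per-marker instability calls.
#' @param panel_size expected panel size (default the 5-marker Bethesda
#'   panel); a different length is an error.
#' @return `"MSI-H"`, `"MSI-L"` or `"MSS"`.
#' @export
classify_msi <- function(flags, panel_size = 5L) {
  if (anyNA(flags) || !is.logical(flags)) stop("flags must be non-missing logicals")
  if (length(flags) != panel_size) {
    stop(sprintf("expected %d marker flags, got %d", panel_size, length(flags)))
  }
  frac <- mean(flags)
  if (frac > 0.30) "MSI-H" else if (frac > 0) "MSI-L" else "MSS"
}

#' Classify MSI status for a cohort table
#'
#' @param profiles data.frame with `sample_id` and one logical column
#'   per Bethesda marker (see [simulate_msi_profiles()]).
#' @return `profiles` with `unstable_fraction` and `msi_class` appended.
#' @export
classify_msi_panel <- function(profiles) {
  .assert_columns(profiles, c("sample_id", .BETHESDA_MARKERS), "MSI profiles")
  flags <- as.matrix(profiles[, .BETHESDA_MARKERS])
  storage.mode(flags) <- "logical"
  profiles$unstable_fraction <- rowMeans(flags)
  profiles$msi_class <- apply(flags, 1L, classify_msi)
  profiles
}
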