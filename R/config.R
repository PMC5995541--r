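#' Pipeline configuration
#'
#' Bundles every tunable threshold of the client-calling pipeline with the
#' defaults used throughout: a 101-codon sliding window (half-width 50),
#' 25 nt synthetic reads for mappability, a strict 80% unique-mappability
#' requirement, a strict 0.02 reads/codon/million expression cutoff, a strict
#' RPKM(pulldown)/RPKM(input) > 1 localization requirement, the 90th-percentile
#' ("top 10%") client threshold applied in every replicate, 10,000 bootstrap
#' subsets with a 5th-95th percentile band for TMD composition, and an
#' inclusive 0.5 log2 threshold for dual-knockdown proteome calls.
#'
#' @param window_half_width Codons on either side of a position included in
#'   window sums (window size is `2 * window_half_width + 1`).
#' @param read_length_nt Synthetic read length for the mappability filter.
#' @param mappability_threshold Minimum fraction of uniquely mappable
#'   positions; genes must exceed this strictly.
#' @param expression_cutoff Minimum input-side reads per codon per million
#'   mapped reads; strict.
#' @param localization_ratio_min RPKM pulldown/input ratio that must be
#'   exceeded strictly in at least one sample pair.
#' @param client_percentile Percentile of per-replicate maximum
#'   ratio-of-ratios a client must reach in every replicate.
#' @param n_bootstrap Number of random TMD subsets for composition resampling.
#' @param ci_percentiles Length-2 vector of percentile bounds for the
#'   bootstrap band.
#' @param proteome_log2_threshold Absolute log2 ratio at or beyond which a
#'   protein counts as changed in a knockdown (inclusive).
#' @param rng_seed Seed threaded through every stochastic step.
#'
#' @return A list of class `riboprox_config`.
#' @export
pipeline_config <- function(window_half_width = 50L,
                            read_length_nt = 25L,
                            mappability_threshold = 0.80,
                            expression_cutoff = 0.02,
                            localization_ratio_min = 1.0,
                            client_percentile = 90,
                            n_bootstrap = 10000L,
                            ci_percentiles = c(5, 95),
                            proteome_log2_threshold = 0.5,
                            rng_seed = 1L) {
  stopifnot(
    window_half_width >= 0,
    read_length_nt >= 1,
    mappability_threshold > 0, mappability_threshold < 1,
    expression_cutoff > 0,
    localization_ratio_min > 0,
    client_percentile > 0, client_percentile < 100,
    n_bootstrap >= 1,
    length(ci_percentiles) == 2,
    ci_percentiles[1] < ci_percentiles[2],
    all(ci_percentiles > 0), all(ci_percentiles < 100),
    proteome_log2_threshold > 0
  )
  structure(
    list(
      window_half_width = as.integer(window_half_width),
      read_length_nt = as.integer(read_length_nt),
      mappability_threshold = mappability_threshold,
      expression_cutoff = expression_cutoff,
      localization_ratio_min = localization_ratio_min,
      client_percentile = client_percentile,
      n_bootstrap = as.integer(n_bootstrap),
      ci_percentiles = ci_percentiles,
      proteome_log2_threshold = proteome_log2_threshold,
      rng_seed = as.integer(rng_seed)
    ),
    class = "riboprox_config"
  )
}

#' @export
print.riboprox_config <- function(x, ...) {
  cat("riboprox pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# one-line "key=value; ..." rendering used in output file comment headers
config_header <- function(config) {
  vals <- vapply(config, function(v) paste(format(v), collapse = ","), "")
  paste0("# config: ", paste(names(vals), vals, sep = "=", collapse = "; "))
}
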