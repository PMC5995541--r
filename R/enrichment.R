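#' Edge-truncated sliding-window sums
#'
#' Value at codon i is the sum of `counts` over positions
#' `max(1, i - h) .. min(n, i + h)`; windows are truncated at the gene
#' boundaries rather than dropping flanking codons, so the output has the
#' same length as the input.
#'
#' @param counts Numeric vector of per-codon counts.
#' @param half_width Codons on either side of the focal position (h >= 0).
#' @return Numeric vector of windowed sums, same length as `counts`.
#' @export
window_sums <- function(counts, half_width) {
  stopifnot(half_width >= 0)
  n <- length(counts)
  if (n == 0) return(numeric(0))
  h <- as.integer(half_width)
  cs <- c(0, cumsum(as.numeric(counts)))
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  cs[hi + 1L] - cs[lo]
}

#' Windowed pulldown/input enrichment profile for one gene
#'
#' Each sample's window sum is normalized to that sample's total mapped
#' reads, and the profile is the ratio pulldown/input per codon. Positions
#' whose input window sum is zero are undefined (`NA`), never infinite;
#' the reads-per-million constant cancels in the ratio and is omitted.
#'
#' @param pulldown,input Single profile rows (lists with `gene_id`, `counts`,
#'   `sample_total`) for the same gene.
#' @param half_width Window half-width in codons.
#' @return Numeric vector (length `n_codons`) with `NA` where undefined.
#' @export
enrichment_profile <- function(pulldown, input, half_width) {
  if (!identical(pulldown$gene_id, input$gene_id)) {
    stop("pulldown and input profiles are for different genes: ",
         pulldown$gene_id, " vs ", input$gene_id, call. = FALSE)
  }
  pc <- if (is.list(pulldown$counts)) pulldown$counts[[1]] else pulldown$counts
  ic <- if (is.list(input$counts)) input$counts[[1]] else input$counts
  stopifnot(pulldown$sample_total > 0, input$sample_total > 0,
            length(pc) == length(ic))
  wp <- window_sums(pc, half_width) / pulldown$sample_total
  wi <- window_sums(ic, half_width) / input$sample_total
  out <- wp / wi
  out[wi == 0] <- NA_real_
  out
}

#' Positionwise bait/reference ratio of enrichments
#'
#' Divides the test bait's enrichment profile by the reference bait's,
#' codon by codon. A position is defined only where both profiles are
#' defined and the reference is positive; the per-gene statistic is the
#' maximum over defined positions (`NA` if none is defined).
#'
#' @param bait,reference Numeric enrichment vectors of equal length
#'   (as from [enrichment_profile()], same gene and replicate).
#' @return List with `values` (numeric vector, `NA` where undefined) and
#'   `max_value`.
#' @export
ratio_of_ratios <- function(bait, reference) {
  if (length(bait) != length(reference)) {
    stop("profile length mismatch in ratio_of_ratios", call. = FALSE)
  }
  vals <- bait / reference
  vals[is.na(bait) | is.na(reference) | reference <= 0] <- NA_real_
  mx <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  list(values = vals, max_value = mx)
}

#' Enrichment profiles for every (gene, bait, replicate)
#'
#' Applies [enrichment_profile()] across a profile tibble using a pairing
#' table; genes present in both members of a pair are processed.
#'
#' @param profiles Profile tibble (see [read_counts_table()]).
#' @param pairs Pairing tibble (see [read_sample_pairs()]).
#' @param half_width Window half-width in codons.
#' @return Tibble `gene_id`, `bait_id`, `replicate_id`, `values`
#'   (list column).
#' @export
enrichment_profiles <- function(profiles, pairs, half_width) {
  key <- paste(profiles$sample_id, profiles$gene_id, sep = "\r")
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    pd_idx <- which(profiles$sample_id == pairs$pulldown_sample[k])
    in_idx <- which(profiles$sample_id == pairs$input_sample[k])
    common <- intersect(profiles$gene_id[pd_idx], profiles$gene_id[in_idx])
    pd_at <- pd_idx[match(common, profiles$gene_id[pd_idx])]
    in_at <- in_idx[match(common, profiles$gene_id[in_idx])]
    vals <- lapply(seq_along(common), function(j) {
      enrichment_profile(profiles[pd_at[j], ], profiles[in_at[j], ],
                         half_width)
    })
    tibble(gene_id = common, bait_id = pairs$bait_id[k],
           replicate_id = pairs$replicate_id[k], values = vals)
  })
  bind_rows(rows)
}

#' Per-gene maximum bait/reference ratio-of-ratios by replicate
#'
#' Joins the test bait's and the reference bait's enrichment profiles per
#' gene and replicate and records the maximum defined ratio.
#'
#' @param enr Output of [enrichment_profiles()].
#' @param test_bait,reference_bait Bait labels present in `enr`.
#' @return Tibble `gene_id`, `replicate_id`, `values` (list), `max_value`.
#' @export
max_ratio_table <- function(enr, test_bait, reference_bait) {
  b <- enr[enr$bait_id == test_bait, ]
  r <- enr[enr$bait_id == reference_bait, ]
  j <- inner_join(b, r, by = c("gene_id", "replicate_id"),
                  suffix = c("_bait", "_ref"))
  rr <- lapply(seq_len(nrow(j)), function(i) {
    ratio_of_ratios(j$values_bait[[i]], j$values_ref[[i]])
  })
  tibble(gene_id = j$gene_id, replicate_id = j$replicate_id,
         values = lapply(rr, `[[`, "values"),
         max_value = vapply(rr, `[[`, 0, "max_value"))
}
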