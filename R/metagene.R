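#' Align an enrichment profile to the start of the gene's first TMD
#'
#' Offset 0 is the first codon of the first (smallest `start_aa`) annotated
#' TMD; offset d maps to codon `start_aa + d`. Offsets falling outside the
#' gene are absent (`NA`).
#'
#' @param values Numeric enrichment vector for one gene.
#' @param tmds TMD tibble rows for that gene (>= 1 span).
#' @param offsets Integer vector of offsets to extract.
#' @return Numeric vector parallel to `offsets`, `NA` where out of gene.
#' @export
align_to_first_tmd <- function(values, tmds, offsets) {
  if (nrow(tmds) == 0) {
    warning("gene without TMDs skipped in metagene alignment", call. = FALSE)
    return(rep(NA_real_, length(offsets)))
  }
  first <- min(tmds$start_aa)
  pos <- first + offsets
  out <- rep(NA_real_, length(offsets))
  inside <- pos >= 1 & pos <= length(values)
  out[inside] <- values[pos[inside]]
  out
}

#' Metagene curve: mean enrichment around the first TMD over a gene set
#'
#' Genes are averaged unweighted (one vote per aligned profile) at each
#' offset over the profiles that have a defined value there; the number of
#' contributors is recorded per offset. The default offset range spans the
#' targeting ramp (~60 codons downstream of the first TMD) and the later
#' client-specific rise.
#'
#' @param enr Enrichment profile tibble (one bait; see
#'   [enrichment_profiles()]).
#' @param tmds Merged TMD tibble.
#' @param gene_set Character vector of gene ids to average.
#' @param offsets Integer offsets relative to the first TMD start
#'   (default -50..250).
#' @return Tibble `offset`, `mean_enrichment`, `n_genes_contributing`.
#' @export
metagene_curve <- function(enr, tmds, gene_set,
                           offsets = -50:250) {
  rows <- enr[enr$gene_id %in% gene_set, ]
  if (nrow(rows) == 0) stop("empty gene set in metagene_curve", call. = FALSE)
  aligned <- lapply(seq_len(nrow(rows)), function(i) {
    align_to_first_tmd(rows$values[[i]],
                       tmds[tmds$gene_id == rows$gene_id[i], ], offsets)
  })
  mat <- do.call(rbind, aligned)
  tibble(offset = offsets,
         mean_enrichment = colMeans(mat, na.rm = TRUE),
         n_genes_contributing = colSums(!is.na(mat)))
}

#' Half-rise offset of a metagene curve
#'
#' Locates where the curve first reaches halfway between a baseline (mean
#' over `baseline_offsets`) and a plateau (mean over `plateau_offsets`);
#' used to read off the targeting-ramp onset (~60 codons after the first
#' TMD for ER-localized baits).
#'
#' @param curve Output of [metagene_curve()].
#' @param baseline_offsets,plateau_offsets Offset windows defining the two
#'   levels.
#' @return The first offset at which `mean_enrichment` reaches the midpoint
#'   (NA if it never does).
#' @export
rise_midpoint <- function(curve, baseline_offsets = -50:-40,
                          plateau_offsets = 100:120) {
  base <- mean(curve$mean_enrichment[curve$offset %in% baseline_offsets],
               na.rm = TRUE)
  plateau <- mean(curve$mean_enrichment[curve$offset %in% plateau_offsets],
                  na.rm = TRUE)
  half <- (base + plateau) / 2
  after <- curve[curve$offset >= min(baseline_offsets), ]
  hit <- which(after$mean_enrichment >= half)
  if (length(hit) == 0) return(NA_integer_)
  after$offset[hit[1]]
}
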