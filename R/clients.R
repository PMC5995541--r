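#' Expression eligibility filter
#'
#' A gene passes iff (a) in the input (non-pulldown) library of every bait
#' and replicate, its read density strictly exceeds `cutoff` reads per codon
#' per million mapped reads, and (b) in every library (pulldown and input),
#' every edge-truncated window of `2*half_width + 1` codons contains at
#' least one read. Genes missing a profile in any required library fail.
#'
#' @param profiles Profile tibble.
#' @param pairs Pairing tibble; defines which samples are inputs/pulldowns.
#' @param genes Gene table (for codon counts).
#' @param half_width Window half-width in codons (default 50).
#' @param cutoff Reads per codon per million; strict (default 0.02).
#' @return Character vector of passing `gene_id`s.
#' @export
filter_expression <- function(profiles, pairs, genes, half_width = 50L,
                              cutoff = 0.02) {
  input_samples <- unique(pairs$input_sample)
  all_samples <- unique(c(pairs$input_sample, pairs$pulldown_sample))
  n_of <- stats::setNames(genes$n_codons, genes$gene_id)
  candidates <- intersect(unique(profiles$gene_id), genes$gene_id)
  pass <- vapply(candidates, function(g) {
    rows <- which(profiles$gene_id == g)
    have <- profiles$sample_id[rows]
    if (!all(all_samples %in% have)) return(FALSE)
    for (i in rows) {
      s <- profiles$sample_id[i]
      if (!s %in% all_samples) next
      v <- profiles$counts[[i]]
      if (s %in% input_samples) {
        dens <- sum(v) / n_of[[g]] / (profiles$sample_total[i] / 1e6)
        if (!(dens > cutoff)) return(FALSE)
      }
      if (min(window_sums(v, half_width)) <= 0) return(FALSE)
    }
    TRUE
  }, TRUE)
  candidates[pass]
}

#' Localization eligibility filter
#'
#' A gene passes iff RPKM(pulldown)/RPKM(input) strictly exceeds
#' `ratio_min` in at least one sample pair. Gene length cancels in the
#' ratio, which reduces to the depth-normalized read-count ratio.
#'
#' @param profiles Profile tibble.
#' @param pairs Pairing tibble.
#' @param ratio_min Strict lower bound on the RPKM ratio (default 1).
#' @return Character vector of passing `gene_id`s.
#' @export
filter_localization <- function(profiles, pairs, ratio_min = 1.0) {
  passing <- character(0)
  for (k in seq_len(nrow(pairs))) {
    pd <- profiles[profiles$sample_id == pairs$pulldown_sample[k], ]
    ip <- profiles[profiles$sample_id == pairs$input_sample[k], ]
    common <- intersect(pd$gene_id, ip$gene_id)
    if (length(common) == 0) next
    pd <- pd[match(common, pd$gene_id), ]
    ip <- ip[match(common, ip$gene_id), ]
    num <- vapply(pd$counts, sum, 0) / pd$sample_total
    den <- vapply(ip$counts, sum, 0) / ip$sample_total
    ratio <- ifelse(den > 0, num / den, Inf * (num > 0))
    passing <- union(passing, common[!is.na(ratio) & ratio > ratio_min])
  }
  passing
}

#' Call clients from per-replicate maximum ratio-of-ratios
#'
#' Within each replicate the genes supplied (normally the eligible set) are
#' ranked by their maximum positional ratio-of-ratios. The client threshold
#' follows top-decile counting semantics: with `n` genes and percentile `p`,
#' the threshold is the order statistic at rank `floor(n*p/100) + 1`, and
#' every gene whose maximum is at or above it qualifies (ties at the
#' threshold are all included). A gene is a client iff it qualifies in
#' every replicate.
#'
#' @param max_tbl Tibble `gene_id`, `replicate_id`, `max_value` with a
#'   defined maximum for every row; at least two replicates.
#' @param percentile Client percentile in (0,100), default 90.
#' @return Tibble `gene_id`, `replicate_id`, `max_value`, `percentile_rank`,
#'   `top_decile`, `is_client`, with the per-replicate threshold values in
#'   attribute `"thresholds"`.
#' @export
call_clients <- function(max_tbl, percentile = 90) {
  stopifnot(percentile > 0, percentile < 100)
  if (anyNA(max_tbl$max_value)) {
    stop("undefined max_value in call_clients input; drop ineligible genes",
         call. = FALSE)
  }
  reps <- unique(max_tbl$replicate_id)
  if (length(reps) < 2) {
    stop("client calling requires at least 2 replicates", call. = FALSE)
  }
  out <- lapply(reps, function(r) {
    d <- max_tbl[max_tbl$replicate_id == r, ]
    n <- nrow(d)
    rank_at <- min(floor(n * percentile / 100) + 1L, n)
    thr <- sort(d$max_value)[rank_at]
    tibble(gene_id = d$gene_id, replicate_id = r, max_value = d$max_value,
           percentile_rank = 100 *
             vapply(d$max_value, function(v) sum(d$max_value <= v), 0) / n,
           top_decile = d$max_value >= thr, threshold = thr)
  })
  long <- bind_rows(out)
  per_gene <- long %>%
    group_by(.data$gene_id) %>%
    summarise(is_client = all(.data$top_decile) &&
                dplyr::n_distinct(.data$replicate_id) == length(reps),
              .groups = "drop")
  res <- left_join(long, per_gene, by = "gene_id")
  thresholds <- stats::setNames(
    vapply(out, function(d) d$threshold[1], 0),
    vapply(out, function(d) d$replicate_id[1], ""))
  res$threshold <- NULL
  attr(res, "thresholds") <- thresholds
  res
}

#' Full client-call table with eligibility bookkeeping
#'
#' Combines the three eligibility filters (unique mappability, expression,
#' localization) with [call_clients()] ranking on the eligible set, and
#' records which filter(s) each excluded gene failed. Genes whose
#' ratio-of-ratios maximum is undefined everywhere are treated as expression
#' failures (their windows are empty).
#'
#' @param max_tbl Per-gene, per-replicate maxima (may contain `NA`).
#' @param mappable,expressed,localized Character vectors of gene ids passing
#'   each filter.
#' @param percentile Client percentile (default 90).
#' @param rank_among_all If `TRUE`, ranks are computed among all genes with a
#'   defined maximum rather than eligible genes only; clients must still be
#'   eligible. Default `FALSE` (eligible-only ranking).
#' @return Tibble with one row per (gene, replicate) for eligible genes plus
#'   one summary row per ineligible gene (`eligible`, `is_client`,
#'   `filter_failures` columns).
#' @export
client_calls <- function(max_tbl, mappable, expressed, localized,
                         percentile = 90, rank_among_all = FALSE) {
  genes <- unique(max_tbl$gene_id)
  defined <- max_tbl %>%
    group_by(.data$gene_id) %>%
    summarise(ok = !anyNA(.data$max_value), .groups = "drop")
  defined_ids <- defined$gene_id[defined$ok]
  failures <- lapply(genes, function(g) {
    f <- character(0)
    if (!g %in% mappable) f <- c(f, "MAPPABILITY")
    if (!g %in% expressed || !g %in% defined_ids) f <- c(f, "EXPRESSION")
    if (!g %in% localized) f <- c(f, "LOCALIZATION")
    f
  })
  names(failures) <- genes
  eligible_ids <- genes[lengths(failures) == 0]
  rank_ids <- if (rank_among_all) defined_ids else eligible_ids
  ranked <- call_clients(max_tbl[max_tbl$gene_id %in% rank_ids, ],
                         percentile = percentile)
  thresholds <- attr(ranked, "thresholds")
  ranked$eligible <- ranked$gene_id %in% eligible_ids
  ranked$is_client <- ranked$is_client & ranked$eligible
  ranked$filter_failures <- ""
  inel <- setdiff(genes, rank_ids)
  if (length(inel) > 0) {
    extra <- tibble(gene_id = inel, replicate_id = NA_character_,
                    max_value = NA_real_, percentile_rank = NA_real_,
                    top_decile = FALSE, is_client = FALSE, eligible = FALSE,
                    filter_failures = vapply(failures[inel], paste,
                                             "", collapse = ","))
    ranked <- bind_rows(ranked, extra)
  }
  if (rank_among_all) {
    ranked$filter_failures[!ranked$eligible & ranked$filter_failures == ""] <-
      vapply(failures[ranked$gene_id[!ranked$eligible &
                                       ranked$filter_failures == ""]],
             paste, "", collapse = ",")
  }
  attr(ranked, "thresholds") <- thresholds
  ranked
}
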