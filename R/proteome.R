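#' Partition proteins by concordant dual-knockdown abundance change
#'
#' A protein is `down_in_both` when both log2 knockdown/control ratios are
#' at or below `-log2_threshold`, `up_in_both` when both are at or above
#' `+log2_threshold`, and `other` otherwise. The boundary is inclusive.
#' Records whose protein id is listed in `complex_subunits` (the depleted
#' complex's own subunits) are reported separately and excluded from the
#' client partition.
#'
#' @param records Proteome tibble (see [read_proteome_table()]).
#' @param log2_threshold Positive log2 cutoff (default 0.5).
#' @param complex_subunits Ids to set aside (default none).
#' @return The input with an added `class` column
#'   (`down_in_both` / `up_in_both` / `other` / `complex_subunit`).
#' @export
call_regulated <- function(records, log2_threshold = 0.5,
                           complex_subunits = character(0)) {
  stopifnot(log2_threshold > 0)
  a <- records$log2_kd1_vs_control
  b <- records$log2_kd2_vs_control
  class <- ifelse(a <= -log2_threshold & b <= -log2_threshold,
                  "down_in_both",
                  ifelse(a >= log2_threshold & b >= log2_threshold,
                         "up_in_both", "other"))
  class[records$protein_id %in% complex_subunits] <- "complex_subunit"
  mutate(records, class = class)
}

#' Down-regulated proteins whose translation also drops
#'
#' Among `down_in_both` proteins, returns those whose log2 translation
#' change is at or below `-log2_threshold` — abundance decreases
#' explainable by reduced synthesis rather than degradation. Records
#' without a translation measurement are skipped and their number reported.
#'
#' @param records Output of [call_regulated()].
#' @param log2_threshold Positive log2 cutoff (default 0.5).
#' @return Character vector of protein ids, with attribute `"n_skipped"`.
#' @export
flag_translationally_driven <- function(records, log2_threshold = 0.5) {
  down <- records[records$class == "down_in_both", ]
  skipped <- sum(is.na(down$log2_translation_change))
  if (skipped > 0) {
    message(skipped, " down-regulated protein(s) lack a translation value")
  }
  keep <- down[!is.na(down$log2_translation_change) &
                 down$log2_translation_change <= -log2_threshold, ]
  structure(keep$protein_id, n_skipped = skipped)
}

#' TMD content of a down-regulated protein set
#'
#' Counts members with at least one TMD, multipass members (>= 2 TMDs),
#' soluble members (0 TMDs), and the same breakdown restricted to proteins
#' decreased at least 2-fold (|log2| >= 1) in both knockdowns.
#'
#' @param down_set Proteome tibble rows with `n_tmds` present.
#' @return One-row tibble `n`, `n_any_tmd`, `n_multipass`, `n_soluble`,
#'   `n_twofold`, `n_twofold_any_tmd`.
#' @export
tmd_summary <- function(down_set) {
  if (nrow(down_set) > 0 && anyNA(down_set$n_tmds)) {
    stop("n_tmds required for tmd_summary", call. = FALSE)
  }
  twofold <- down_set$log2_kd1_vs_control <= -1 &
    down_set$log2_kd2_vs_control <= -1
  tibble(n = nrow(down_set),
         n_any_tmd = sum(down_set$n_tmds >= 1),
         n_multipass = sum(down_set$n_tmds >= 2),
         n_soluble = sum(down_set$n_tmds == 0),
         n_twofold = sum(twofold),
         n_twofold_any_tmd = sum(twofold & down_set$n_tmds >= 1))
}
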