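#' Read coding sequences into a gene table
#'
#' Each FASTA record becomes one gene with `n_codons = floor(length/3)`
#' (1-based codon coordinates, stop codon not counted). Records whose length
#' is not a multiple of 3 are kept after truncation to the last complete
#' codon, with a warning naming them.
#'
#' @param path FASTA file of in-frame coding sequences.
#' @return A tibble with columns `gene_id`, `n_codons`, `cds_seq`,
#'   `is_secretory`, `excluded`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("CDS FASTA not readable: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate gene_id in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  len <- Biostrings::width(seqs)
  off_frame <- len %% 3L != 0L
  if (any(off_frame)) {
    warning("CDS length not a multiple of 3 (truncated to whole codons): ",
            paste(ids[off_frame], collapse = ", "), call. = FALSE)
  }
  n_codons <- len %/% 3L
  tibble(
    gene_id = ids,
    n_codons = as.integer(n_codons),
    cds_seq = unname(substr(as.character(seqs), 1L, 3L * n_codons)),
    is_secretory = FALSE,
    excluded = FALSE
  )
}

new_gene_table <- function(gene_id, n_codons, cds_seq = NA_character_,
                           is_secretory = FALSE, excluded = FALSE) {
  stopifnot(!anyDuplicated(gene_id), all(n_codons >= 1))
  tbl <- tibble(gene_id = as.character(gene_id),
                n_codons = as.integer(n_codons),
                cds_seq = cds_seq,
                is_secretory = is_secretory,
                excluded = excluded)
  has_seq <- !is.na(tbl$cds_seq)
  if (any(nchar(tbl$cds_seq[has_seq]) != 3L * tbl$n_codons[has_seq])) {
    stop("cds_seq length must equal 3 * n_codons", call. = FALSE)
  }
  tbl
}

#' Assemble dense per-codon footprint profiles from a sparse counts table
#'
#' The counts table is tab-separated with a header and columns `gene_id`,
#' `sample_id`, `codon_position` (1-based) and `count`; positions absent from
#' the table are zero. Sample totals come from a sidecar table
#' (`sample_id`, `total_mapped`) because a counts table may cover only a gene
#' subset while enrichment is normalized to whole-sample depth.
#'
#' @param path Counts table path (or a data frame with the same columns).
#' @param genes Gene table, as from [read_cds_fasta()].
#' @param totals Totals table path or data frame (`sample_id`,
#'   `total_mapped`).
#' @return A profile tibble: `gene_id`, `sample_id`, `counts` (list column of
#'   integer vectors of length `n_codons`), `sample_total`.
#' @export
read_counts_table <- function(path, genes, totals) {
  df <- read_tsv_checked(path, c("gene_id", "sample_id", "codon_position",
                                 "count"))
  tot <- read_tsv_checked(totals, c("sample_id", "total_mapped"))
  if (nrow(df) == 0) {
    return(tibble(gene_id = character(), sample_id = character(),
                  counts = list(), sample_total = integer()))
  }
  unknown <- setdiff(unique(df$gene_id), genes$gene_id)
  if (length(unknown) > 0) {
    stop("counts table contains unknown gene_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(df$count < 0)) stop("negative count in counts table", call. = FALSE)
  n_of <- stats::setNames(genes$n_codons, genes$gene_id)
  bad <- df$codon_position < 1L | df$codon_position > n_of[df$gene_id]
  if (any(bad)) {
    stop("codon_position outside [1, n_codons] for gene ",
         paste(unique(df$gene_id[bad]), collapse = ", "), call. = FALSE)
  }
  dense <- df %>%
    group_by(.data$gene_id, .data$sample_id) %>%
    summarise(counts = {
      v <- integer(n_of[[.data$gene_id[1]]])
      v[.data$codon_position] <- v[.data$codon_position] + .data$count
      list(v)
    }, .groups = "drop")
  out <- left_join(dense, tot, by = "sample_id")
  if (anyNA(out$total_mapped)) {
    stop("sample without a total_mapped entry: ",
         paste(unique(out$sample_id[is.na(out$total_mapped)]),
               collapse = ", "), call. = FALSE)
  }
  validate_profiles(
    tibble(gene_id = out$gene_id, sample_id = out$sample_id,
           counts = out$counts, sample_total = out$total_mapped)
  )
}

validate_profiles <- function(profiles) {
  sums <- vapply(profiles$counts, sum, 0)
  if (any(profiles$sample_total < sums - 1e-9)) {
    stop("sample_total smaller than summed counts", call. = FALSE)
  }
  profiles
}

#' Read a transmembrane-domain table
#'
#' Tab-separated columns `gene_id`, `start_aa`, `end_aa` (1-based inclusive
#' protein coordinates). Duplicate rows are collapsed with a warning; a span
#' with `start_aa > end_aa` is an error.
#'
#' @param path Table path or data frame.
#' @param source `"PREDICTED"` (e.g. TMHMM-style) or `"CURATED"`
#'   (e.g. UniProt-style).
#' @return Tibble `gene_id`, `start_aa`, `end_aa`, `source`.
#' @export
read_tmd_table <- function(path, source = c("PREDICTED", "CURATED")) {
  source <- match.arg(source)
  df <- read_tsv_checked(path, c("gene_id", "start_aa", "end_aa"))
  if (any(df$start_aa < 1)) stop("start_aa must be >= 1", call. = FALSE)
  if (any(df$start_aa > df$end_aa)) {
    stop("TMD span with start_aa > end_aa", call. = FALSE)
  }
  ndup <- nrow(df) - nrow(distinct(df))
  if (ndup > 0) {
    warning(ndup, " duplicate TMD row(s) collapsed", call. = FALSE)
    df <- distinct(df)
  }
  mutate(as_tibble(df),
         start_aa = as.integer(.data$start_aa),
         end_aa = as.integer(.data$end_aa),
         source = source)
}

#' Read a sample-pairing table
#'
#' Columns `bait_id`, `replicate_id`, `pulldown_sample`, `input_sample`; one
#' row per (bait, replicate) pulldown/input library pair.
#'
#' @param path Table path or data frame.
#' @return Validated pairing tibble.
#' @export
read_sample_pairs <- function(path) {
  df <- as_tibble(read_tsv_checked(
    path, c("bait_id", "replicate_id", "pulldown_sample", "input_sample")))
  if (any(df$pulldown_sample == df$input_sample)) {
    stop("pulldown_sample must differ from input_sample", call. = FALSE)
  }
  if (anyDuplicated(df[, c("bait_id", "replicate_id")])) {
    stop("duplicate (bait_id, replicate_id) pair", call. = FALSE)
  }
  df
}

#' Read a SILAC proteome table
#'
#' Columns `protein_id`, `log2_kd1_vs_control`, `log2_kd2_vs_control`, and
#' optionally `log2_translation_change` and `n_tmds`.
#'
#' @param path Table path or data frame.
#' @return Proteome record tibble (missing optional columns filled with NA).
#' @export
read_proteome_table <- function(path) {
  df <- as_tibble(read_tsv_checked(
    path, c("protein_id", "log2_kd1_vs_control", "log2_kd2_vs_control")))
  if (!"log2_translation_change" %in% names(df)) {
    df$log2_translation_change <- NA_real_
  }
  if (!"n_tmds" %in% names(df)) df$n_tmds <- NA_integer_
  if (any(!is.finite(df$log2_kd1_vs_control)) ||
      any(!is.finite(df$log2_kd2_vs_control))) {
    stop("non-finite log2 ratio in proteome table", call. = FALSE)
  }
  df
}

read_tsv_checked <- function(path, required) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_tibble(df)
}

#' Write a result table with a commented configuration header
#'
#' All pipeline outputs are tab-separated UTF-8 with a leading `#` line that
#' echoes the configuration used, so every file records its provenance.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Optional `riboprox_config`; echoed into the header.
#' @export
write_result_table <- function(df, path, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config)) writeLines(config_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a profile tibble to a long counts table (inverse of
#' [read_counts_table()]); zero positions are omitted.
#' @param profiles Profile tibble.
#' @return Long tibble `gene_id`, `sample_id`, `codon_position`, `count`.
#' @export
profiles_to_long <- function(profiles) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    v <- profiles$counts[[i]]
    keep <- which(v != 0)
    tibble(gene_id = profiles$gene_id[i], sample_id = profiles$sample_id[i],
           codon_position = keep, count = v[keep])
  })
  bind_rows(rows)
}

#' Sample totals of a profile tibble as a sidecar table
#' @param profiles Profile tibble.
#' @return Tibble `sample_id`, `total_mapped`.
#' @export
profiles_totals <- function(profiles) {
  distinct(tibble(sample_id = profiles$sample_id,
                  total_mapped = profiles$sample_total))
}
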