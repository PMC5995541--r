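#' Unique-mappability of coding sequences under synthetic fixed-length reads
#'
#' For every nucleotide start position p of every gene such that a full
#' read fits (`p + L - 1 <= length`), the L-mer at p is extracted; a position
#' is uniquely mappable iff its L-mer occurs exactly once among the
#' sense-strand L-mers of the entire collection. The uniqueness universe is
#' the CDS pool itself (reads are aligned to coding sequences, not a genome).
#' Genes shorter than the read length have no testable position and a
#' fraction of 0 by definition.
#'
#' @param genes Gene table with `cds_seq` present for every gene.
#' @param read_length_nt Synthetic read length in nucleotides (default 25).
#' @return Tibble `gene_id`, `n_positions_tested`, `fraction_unique`.
#' @export
compute_mappability <- function(genes, read_length_nt = 25L) {
  stopifnot(read_length_nt >= 1)
  missing_seq <- genes$gene_id[is.na(genes$cds_seq)]
  if (length(missing_seq) > 0) {
    stop("cds_seq missing for gene(s): ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  L <- as.integer(read_length_nt)
  lens <- nchar(genes$cds_seq)
  n_pos <- pmax(lens - L + 1L, 0L)
  # pool all L-mers, then flag the ones seen exactly once via two-sided
  # duplicated() — O(total length), no explicit hash table
  kmers <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (n_pos[i] > 0) {
      starts <- seq_len(n_pos[i])
      kmers[[i]] <- substring(genes$cds_seq[i], starts, starts + L - 1L)
    } else {
      kmers[[i]] <- character(0)
    }
  }
  pool <- unlist(kmers, use.names = FALSE)
  unique_flag <- !(duplicated(pool) | duplicated(pool, fromLast = TRUE))
  idx_end <- cumsum(n_pos)
  idx_start <- idx_end - n_pos + 1L
  frac <- vapply(seq_len(nrow(genes)), function(i) {
    if (n_pos[i] == 0L) return(0)
    sum(unique_flag[idx_start[i]:idx_end[i]]) / n_pos[i]
  }, 0)
  tibble(gene_id = unname(genes$gene_id),
         n_positions_tested = unname(n_pos),
         fraction_unique = unname(frac))
}

#' Genes passing the unique-mappability filter
#'
#' Membership requires `fraction_unique` strictly greater than the threshold
#' (a gene at exactly 80% is excluded).
#'
#' @param results Output of [compute_mappability()].
#' @param threshold Fraction in (0,1); default 0.80.
#' @return Character vector of passing `gene_id`s.
#' @export
filter_mappable <- function(results, threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  results$gene_id[results$fraction_unique > threshold]
}
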