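#' Merge predicted and curated TMD annotations
#'
#' Takes the union of both sources, except that a PREDICTED span sharing at
#' least one residue with a CURATED span of the same gene is dropped in
#' favor of the curated span. Spans on excluded genes (mitochondrially
#' encoded, dubious ORFs, pseudogenes) are removed.
#'
#' @param predicted,curated TMD tibbles (see [read_tmd_table()]).
#' @param excluded_genes Character vector of gene ids to drop entirely.
#' @return Merged TMD tibble.
#' @export
merge_tmd_sources <- function(predicted, curated,
                              excluded_genes = character(0)) {
  predicted <- predicted[!predicted$gene_id %in% excluded_genes, ]
  curated <- curated[!curated$gene_id %in% excluded_genes, ]
  if (nrow(predicted) > 0 && nrow(curated) > 0) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(predicted$start_aa, predicted$end_aa),
      IRanges::IRanges(curated$start_aa, curated$end_aa))
    same_gene <- predicted$gene_id[S4Vectors::queryHits(hits)] ==
      curated$gene_id[S4Vectors::subjectHits(hits)]
    drop <- unique(S4Vectors::queryHits(hits)[same_gene])
    if (length(drop) > 0) predicted <- predicted[-drop, ]
  }
  arrange(bind_rows(predicted, curated), .data$gene_id, .data$start_aa)
}

#' TMD-count distribution over a gene set
#'
#' Counts merged TMDs per gene (genes in the set with no annotated TMD fall
#' in bin 0) and returns the proportion of proteins per count.
#'
#' @param tmds Merged TMD tibble.
#' @param gene_set Nonempty character vector of gene ids.
#' @return Tibble `n_tmds`, `n_proteins`, `proportion` (proportions sum
#'   to 1).
#' @export
tmd_count_histogram <- function(tmds, gene_set) {
  if (length(gene_set) == 0) {
    stop("empty gene set in tmd_count_histogram", call. = FALSE)
  }
  per_gene <- table(factor(tmds$gene_id[tmds$gene_id %in% gene_set],
                           levels = gene_set))
  counts <- table(as.integer(per_gene))
  tibble(n_tmds = as.integer(names(counts)),
         n_proteins = as.integer(counts),
         proportion = as.integer(counts) / length(gene_set))
}

#' Amino-acid property classification table
#'
#' The five (deliberately non-exclusive) property classes used for TMD
#' composition: aliphatic \{A,V,L,I\}, aromatic \{F,W,Y\}, charged
#' \{D,E,K,R\}, hydrophobic \{A,V,L,I,M,F,W,C\}, polar \{S,T,N,Q,Y,H,C\}.
#' A residue may carry several properties (F is aromatic and hydrophobic)
#' or none (G, P). The table ships as an editable two-column file so
#' alternative conventions (e.g. histidine as charged) are a one-line edit.
#'
#' @param path Optional path to an alternative `aa` / `property` table.
#' @return Tibble `aa`, `property`.
#' @export
aa_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "riboprox")
  }
  tbl <- read_tsv_checked(path, c("aa", "property"))
  stopifnot(all(nchar(tbl$aa) == 1))
  tbl
}

aa_standard <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Properties of one amino acid
#'
#' @param aa One-letter code of a standard amino acid.
#' @param table Classification table (default [aa_properties()]).
#' @return Character vector of property labels (possibly empty).
#' @export
classify_residue <- function(aa, table = aa_properties()) {
  if (length(aa) != 1 || !aa %in% aa_standard) {
    stop("nonstandard amino acid code: ", aa, call. = FALSE)
  }
  table$property[table$aa == aa]
}

# per-TMD residue bookkeeping: counts matrix (one column per property) and
# span lengths, pooling residues so long TMDs weigh more
tmd_property_counts <- function(tmds, proteins, table = aa_properties()) {
  props <- sort(unique(table$property))
  residues <- lapply(seq_len(nrow(tmds)), function(i) {
    seq <- proteins[[tmds$gene_id[i]]]
    if (is.null(seq) || is.na(seq)) {
      stop("no protein sequence for gene ", tmds$gene_id[i], call. = FALSE)
    }
    if (tmds$end_aa[i] > nchar(seq)) {
      stop("TMD span beyond protein length for gene ", tmds$gene_id[i],
           call. = FALSE)
    }
    strsplit(substr(seq, tmds$start_aa[i], tmds$end_aa[i]), "")[[1]]
  })
  nonstd <- setdiff(unique(unlist(residues)), aa_standard)
  if (length(nonstd) > 0) {
    stop("nonstandard residue(s) in TMD sequences: ",
         paste(nonstd, collapse = ", "), call. = FALSE)
  }
  counts <- t(vapply(residues, function(r) {
    vapply(props, function(p) sum(r %in% table$aa[table$property == p]), 0)
  }, numeric(length(props))))
  colnames(counts) <- props
  list(counts = counts, lengths = lengths(residues), properties = props)
}

#' Amino-acid property enrichment of client TMDs with bootstrap band
#'
#' Pools all residues of all client TMDs and of all TMDs, computes the
#' fraction belonging to each property class and their ratio
#' (clients / all), then draws `n_bootstrap` random subsets of the same
#' number of TMD spans as the client set, uniformly without replacement
#' from all TMDs, recomputing the ratio each time; the configured
#' percentiles of the resampled ratios give the null band.
#'
#' @param client_tmds,all_tmds TMD tibbles; clients must be a subset of all.
#' @param proteins Named character vector (or list) of protein sequences by
#'   `gene_id`.
#' @param n_bootstrap Number of random subsets (default 10000).
#' @param ci Percentile pair for the band (default `c(5, 95)`).
#' @param seed RNG seed; identical seeds reproduce identical bands.
#' @param table Residue classification table.
#' @return Tibble `property`, `fraction_clients`, `fraction_all`, `ratio`,
#'   `ci_low`, `ci_high`.
#' @export
property_enrichment <- function(client_tmds, all_tmds, proteins,
                                n_bootstrap = 10000L, ci = c(5, 95),
                                seed = 1L, table = aa_properties()) {
  n_all <- nrow(all_tmds)
  k <- nrow(client_tmds)
  if (k > n_all) {
    stop("client TMD set larger than the full TMD set", call. = FALSE)
  }
  stopifnot(n_bootstrap >= 1, k >= 1)
  pc <- tmd_property_counts(all_tmds, proteins, table)
  key_all <- paste(all_tmds$gene_id, all_tmds$start_aa, all_tmds$end_aa)
  key_cli <- paste(client_tmds$gene_id, client_tmds$start_aa,
                   client_tmds$end_aa)
  idx_cli <- match(key_cli, key_all)
  if (anyNA(idx_cli)) {
    stop("client TMDs must be members of the full TMD set", call. = FALSE)
  }
  frac_all <- colSums(pc$counts) / sum(pc$lengths)
  frac_cli <- colSums(pc$counts[idx_cli, , drop = FALSE]) /
    sum(pc$lengths[idx_cli])
  # a property absent from the whole pool has no defined ratio
  ratio <- ifelse(frac_all > 0, frac_cli / frac_all, NA_real_)

  set.seed(seed)
  draws <- replicate(n_bootstrap, sample.int(n_all, k), simplify = FALSE)
  idx <- unlist(draws, use.names = FALSE)
  grp <- rep(seq_len(n_bootstrap), each = k)
  num <- rowsum(pc$counts[idx, , drop = FALSE], grp, reorder = TRUE)
  den <- rowsum(pc$lengths[idx], grp, reorder = TRUE)[, 1]
  boot_ratio <- sweep(num / den, 2, frac_all, "/")
  bands <- vapply(seq_along(frac_all), function(j) {
    if (frac_all[j] > 0) {
      stats::quantile(boot_ratio[, j], probs = ci / 100, names = FALSE)
    } else c(NA_real_, NA_real_)
  }, numeric(2))
  tibble(property = pc$properties,
         fraction_clients = unname(frac_cli),
         fraction_all = unname(frac_all),
         ratio = unname(ratio),
         ci_low = bands[1, ],
         ci_high = bands[2, ])
}

#' Property fractions per position within TMDs
#'
#' For each position measured from the TMD start, the fraction of spans
#' (long enough to reach that position) whose residue there carries each
#' property; a coarse view of how charged/aromatic residues distribute
#' through the membrane span.
#'
#' @inheritParams property_enrichment
#' @param max_position Deepest position from the TMD start to report.
#' @return Tibble `position`, `property`, `fraction`, `n_tmds`.
#' @export
property_by_position <- function(all_tmds, proteins, max_position = 21L,
                                 table = aa_properties()) {
  props <- sort(unique(table$property))
  spans <- lapply(seq_len(nrow(all_tmds)), function(i) {
    seq <- proteins[[all_tmds$gene_id[i]]]
    strsplit(substr(seq, all_tmds$start_aa[i], all_tmds$end_aa[i]), "")[[1]]
  })
  rows <- lapply(seq_len(max_position), function(p) {
    res <- vapply(spans, function(s) if (length(s) >= p) s[p] else NA_character_, "")
    res <- res[!is.na(res)]
    tibble(position = p, property = props,
           fraction = vapply(props, function(pr) {
             mean(res %in% table$aa[table$property == pr])
           }, 0, USE.NAMES = FALSE),
           n_tmds = length(res))
  })
  bind_rows(rows)
}
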