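# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

oracle_window_sums <- function(counts, h) {
  n <- length(counts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    s <- 0
    for (j in lo:hi) s <- s + counts[j]
    out[i] <- s
  }
  out
}

oracle_enrichment <- function(pd_counts, in_counts, pd_total, in_total, h) {
  n <- length(pd_counts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    wp <- oracle_window_sums(pd_counts, h)[i] / pd_total
    wi <- oracle_window_sums(in_counts, h)[i] / in_total
    out[i] <- if (wi == 0) NA_real_ else wp / wi
  }
  out
}

oracle_ratio_of_ratios <- function(bait, ref) {
  n <- length(bait)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(bait[i]) && !is.na(ref[i]) && ref[i] > 0) {
      vals[i] <- bait[i] / ref[i]
    }
  }
  mx <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  list(values = vals, max_value = mx)
}

# occurrence-count mappability: count every L-mer by direct string scans
oracle_mappability <- function(seqs, L) {
  all_kmers <- character(0)
  per_gene <- list()
  for (g in names(seqs)) {
    s <- seqs[[g]]
    n <- nchar(s) - L + 1
    km <- if (n >= 1) {
      vapply(seq_len(n), function(p) substr(s, p, p + L - 1), "")
    } else character(0)
    per_gene[[g]] <- km
    all_kmers <- c(all_kmers, km)
  }
  res <- data.frame(gene_id = names(seqs), n_positions_tested = 0L,
                    fraction_unique = 0)
  for (g in names(seqs)) {
    km <- per_gene[[g]]
    res$n_positions_tested[res$gene_id == g] <- length(km)
    if (length(km) > 0) {
      uniq <- vapply(km, function(k) sum(all_kmers == k) == 1, TRUE)
      res$fraction_unique[res$gene_id == g] <- mean(uniq)
    }
  }
  res
}

oracle_merge_tmds <- function(predicted, curated) {
  keep <- rep(TRUE, nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    for (j in seq_len(nrow(curated))) {
      same <- predicted$gene_id[i] == curated$gene_id[j]
      overlap <- predicted$start_aa[i] <= curated$end_aa[j] &&
        curated$start_aa[j] <= predicted$end_aa[i]
      if (same && overlap) keep[i] <- FALSE
    }
  }
  rbind(predicted[keep, ], curated)
}

# random per-gene profile fixtures
random_profile_row <- function(gene_id, sample_id, n, total = NULL,
                               lambda = 3) {
  cnt <- rpois(n, lambda)
  if (is.null(total)) total <- sum(cnt) + sample(1:100, 1)
  tibble::tibble(gene_id = gene_id, sample_id = sample_id,
                 counts = list(cnt), sample_total = total)
}

random_protein <- function(n, charged_bias = 0) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  w <- rep(1, 20)
  w[aa %in% c("D", "E", "K", "R")] <- 1 + charged_bias
  paste(sample(aa, n, replace = TRUE, prob = w), collapse = "")
}

# a pool of TMD spans on random proteins, for composition tests
make_tmd_pool <- function(n_tmds, tmd_len = 21, charged_bias = 0) {
  ids <- sprintf("p%03d", seq_len(n_tmds))
  proteins <- stats::setNames(
    vapply(ids, function(i) random_protein(60, charged_bias), ""), ids)
  tmds <- tibble::tibble(gene_id = ids, start_aa = 20L,
                         end_aa = 20L + tmd_len - 1L, source = "CURATED")
  list(tmds = tmds, proteins = proteins)
}
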