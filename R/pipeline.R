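#' Run the full client-identification pipeline
#'
#' Orchestrates mappability -> enrichment -> eligibility filters -> client
#' calling -> metagene -> TMD composition -> proteome calling, on either a
#' simulated dataset (the default when `data` is `NULL`) or a dataset
#' assembled from the reader functions. Progress and per-filter gene counts
#' go to `message()`; with `out_dir` set, every result table is written
#' tab-separated with a commented configuration header and listed in the
#' returned manifest.
#'
#' @param config A [pipeline_config()].
#' @param data Optional list with elements `transcriptome`
#'   (`genes`, `proteins`, `tmds`, `truth` optional), `ribo` (`profiles`,
#'   `pairs`, `test_bait`, `reference_bait`) and optionally `proteome`;
#'   the layout produced by [simulate_dataset()].
#' @param sim_spec [simulation_spec()] used when `data` is `NULL`
#'   (its `rng_seed` is forced to `config$rng_seed`).
#' @param out_dir Optional output directory (created if needed).
#' @param rank_among_all Rank clients among all genes with a defined
#'   statistic instead of eligible genes only (see [client_calls()]).
#' @return List with `mappability`, `eligible`, `max_ratios`, `calls`,
#'   `clients`, `metagene`, `tmd_histogram`, `property_enrichment`
#'   (`NULL` without protein sequences or clients), `proteome`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         sim_spec = NULL, out_dir = NULL,
                         rank_among_all = FALSE) {
  if (is.null(data)) {
    if (is.null(sim_spec)) sim_spec <- simulation_spec()
    sim_spec$rng_seed <- config$rng_seed
    message("simulating dataset (seed ", sim_spec$rng_seed, ")")
    data <- simulate_dataset(sim_spec)
  }
  tx <- data$transcriptome
  ribo <- data$ribo
  genes <- tx$genes

  mapp <- compute_mappability(genes, config$read_length_nt)
  mappable <- filter_mappable(mapp, config$mappability_threshold)
  message("mappability filter: ", length(mappable), "/", nrow(genes),
          " genes pass")

  enr <- enrichment_profiles(ribo$profiles, ribo$pairs,
                             config$window_half_width)
  expressed <- filter_expression(ribo$profiles, ribo$pairs, genes,
                                 config$window_half_width,
                                 config$expression_cutoff)
  message("expression filter: ", length(expressed), " genes pass")
  localized <- filter_localization(ribo$profiles, ribo$pairs,
                                   config$localization_ratio_min)
  message("localization filter: ", length(localized), " genes pass")

  max_tbl <- max_ratio_table(enr, ribo$test_bait, ribo$reference_bait)
  calls <- client_calls(max_tbl, mappable, expressed, localized,
                        percentile = config$client_percentile,
                        rank_among_all = rank_among_all)
  clients <- unique(calls$gene_id[calls$is_client])
  eligible <- unique(calls$gene_id[calls$eligible])
  message(length(eligible), " eligible genes; ", length(clients),
          " clients called")

  tmd_genes <- unique(tx$tmds$gene_id)
  metagene <- NULL
  if (length(tmd_genes) > 0) {
    curves <- list()
    for (bait in unique(ribo$pairs$bait_id)) {
      sub <- enr[enr$bait_id == bait, ]
      curves[[paste(bait, "tmd_genes")]] <-
        mutate(metagene_curve(sub, tx$tmds, tmd_genes),
               bait_id = bait, gene_set = "tmd_genes")
      cl_tmd <- intersect(clients, tmd_genes)
      if (length(cl_tmd) > 0) {
        curves[[paste(bait, "clients")]] <-
          mutate(metagene_curve(sub, tx$tmds, cl_tmd),
                 bait_id = bait, gene_set = "clients")
      }
    }
    metagene <- bind_rows(curves)
  }

  tmd_hist <- if (length(tmd_genes) > 0) {
    tmd_count_histogram(tx$tmds, tmd_genes)
  } else NULL

  prop_enr <- NULL
  client_tmds <- tx$tmds[tx$tmds$gene_id %in% clients, ]
  if (!is.null(tx$proteins) && nrow(client_tmds) > 0) {
    prop_enr <- property_enrichment(client_tmds, tx$tmds, tx$proteins,
                                    n_bootstrap = config$n_bootstrap,
                                    ci = config$ci_percentiles,
                                    seed = config$rng_seed)
  }

  proteome_res <- NULL
  if (!is.null(data$proteome)) {
    reg <- call_regulated(data$proteome, config$proteome_log2_threshold)
    down <- reg[reg$class == "down_in_both", ]
    proteome_res <- list(
      records = reg,
      translationally_driven = flag_translationally_driven(
        reg, config$proteome_log2_threshold),
      tmd_summary = if (!anyNA(down$n_tmds)) tmd_summary(down) else NULL)
    message(nrow(down), " proteins down in both knockdowns")
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- list(
      mappability = mapp,
      max_ratios = max_tbl[, c("gene_id", "replicate_id", "max_value")],
      client_calls = calls[, setdiff(names(calls), "values")],
      metagene = metagene,
      tmd_histogram = tmd_hist,
      property_enrichment = prop_enr,
      proteome_calls = if (!is.null(proteome_res)) proteome_res$records
                       else NULL
    )
    written <- Filter(Negate(is.null), written)
    manifest <- bind_rows(lapply(names(written), function(nm) {
      path <- file.path(out_dir, paste0(nm, ".tsv"))
      write_result_table(written[[nm]], path, config)
      tibble(file = basename(path), n_rows = nrow(written[[nm]]))
    }))
    write_result_table(manifest, file.path(out_dir, "manifest.tsv"), config)
  }

  list(mappability = mapp, eligible = eligible, max_ratios = max_tbl,
       calls = calls, clients = clients, metagene = metagene,
       tmd_histogram = tmd_hist, property_enrichment = prop_enr,
       proteome = proteome_res, manifest = manifest, config = config,
       data = data)
}
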