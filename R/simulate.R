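#' Simulation settings
#'
#' Parameters of the synthetic study: a transcriptome in which a fraction of
#' genes carry TMDs (single spans or multipass clusters), a subset of
#' multipass genes are planted clients, every ER-localized bait's pulldown
#' shows a logistic targeting ramp beginning ~60 codons after the first TMD,
#' and client genes additionally gain a `client_peak_gain`-fold enrichment
#' step shortly after their TMD cluster under the test bait only. Expression
#' factors are log-normal across genes, with a small silent subpopulation of
#' non-TMD genes so the expression and zero-window filters have real work.
#' Proteome effects mirror the dual-knockdown design: clients shift by
#' `proteome_effect_log2` in both knockdowns.
#'
#' @param n_genes Number of genes.
#' @param fraction_tmd_genes Fraction of genes with TMD annotations.
#' @param fraction_clients Expected client fraction among TMD genes
#'   (clients are drawn from multipass genes only; must not exceed
#'   `multipass_prob`).
#' @param gene_length_range Codon-length interval genes are drawn from.
#' @param tmd_length TMD length in codons (default 21).
#' @param multipass_prob Probability a TMD gene carries a cluster of >= 2
#'   TMDs rather than a single span.
#' @param cluster_size_range TMDs per multipass cluster.
#' @param loop_length_range Codons between consecutive cluster TMDs.
#' @param first_tmd_start_range Codon interval for the first TMD start.
#' @param targeting_ramp_start Codons after the first TMD at which the
#'   targeting ramp is centered (default 60).
#' @param ramp_width Codons over which the logistic ramp rises (default 20).
#' @param ramp_gain Pulldown enrichment plateau of the targeting ramp.
#' @param client_peak_gain Extra multiplicative enrichment of client genes
#'   downstream of the TMD cluster (default 4).
#' @param client_peak_offset Codons after the cluster end at which the
#'   client peak starts (default 20).
#' @param input_depth Mean input reads per codon at expression factor 1.
#' @param expression_sdlog sdlog of the log-normal expression factors.
#' @param silent_fraction Fraction of non-TMD genes that are essentially
#'   untranslated.
#' @param silent_factor Expression multiplier for silent genes.
#' @param n_replicates Biological replicates per bait (default 2).
#' @param noise_model `"poisson"` or `"nbinom"` count noise.
#' @param nb_dispersion Size parameter when `noise_model = "nbinom"`.
#' @param proteome_effect_log2 Planted client log2 shift in both knockdowns.
#' @param proteome_noise_sd SD of the proteome log2 ratios.
#' @param translation_driven_fraction Fraction of clients whose decrease is
#'   translational rather than degradative.
#' @param client_tmd_charge_boost Probability that a client-TMD residue is
#'   resampled from the charged + aromatic alphabet, planting the
#'   destabilizing-residue signal in client TMD composition.
#' @param rng_seed Base seed for all generator draws.
#' @return A list of class `riboprox_simspec`.
#' @export
simulation_spec <- function(n_genes = 500L,
                            fraction_tmd_genes = 0.4,
                            fraction_clients = 0.2,
                            gene_length_range = c(200L, 600L),
                            tmd_length = 21L,
                            multipass_prob = 0.6,
                            cluster_size_range = c(2L, 5L),
                            loop_length_range = c(3L, 12L),
                            first_tmd_start_range = c(30L, 80L),
                            targeting_ramp_start = 60L,
                            ramp_width = 20L,
                            ramp_gain = 3,
                            client_peak_gain = 4,
                            client_peak_offset = 20L,
                            input_depth = 20,
                            expression_sdlog = 0.75,
                            silent_fraction = 0.05,
                            silent_factor = 1e-3,
                            n_replicates = 2L,
                            noise_model = c("poisson", "nbinom"),
                            nb_dispersion = 10,
                            proteome_effect_log2 = -1.0,
                            proteome_noise_sd = 0.2,
                            translation_driven_fraction = 0.1,
                            client_tmd_charge_boost = 0.08,
                            rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    n_genes >= 1,
    fraction_tmd_genes >= 0, fraction_tmd_genes <= 1,
    fraction_clients >= 0, fraction_clients <= multipass_prob,
    gene_length_range[1] >= 1, diff(gene_length_range) >= 0,
    tmd_length >= 1, targeting_ramp_start >= 0, client_peak_offset >= 0,
    client_peak_gain > 0, ramp_gain >= 1, input_depth > 0,
    n_replicates >= 1
  )
  structure(as.list(environment()), class = "riboprox_simspec")
}

#' Simulate a transcriptome with planted TMD architecture
#'
#' Draws gene lengths, uniform-nucleotide coding sequences, TMD placements
#' (single spans or multipass clusters), expression factors, and the truth
#' labels used to score recovery. Geometry is resampled (fresh length and
#' cluster) when a cluster plus the client peak would not leave room for a
#' full enrichment window before the stop codon; after 200 failed retries
#' for one gene the generator aborts.
#'
#' @param spec A [simulation_spec()].
#' @param seed RNG seed (default `spec$rng_seed`).
#' @return List with `genes` (gene table), `proteins` (named character
#'   vector of protein sequences), `tmds` (TMD tibble, CURATED), and
#'   `truth` (`gene_id`, `is_tmd`, `is_multipass`, `is_client`,
#'   `first_tmd_start`, `cluster_end`, `expr_factor`, `is_silent`).
#' @export
simulate_transcriptome <- function(spec, seed = spec$rng_seed) {
  set.seed(seed)
  n <- spec$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  is_tmd <- stats::rbinom(n, 1, spec$fraction_tmd_genes) == 1
  is_multi <- is_tmd & stats::rbinom(n, 1, spec$multipass_prob) == 1
  p_client <- if (spec$multipass_prob > 0) {
    spec$fraction_clients / spec$multipass_prob
  } else 0
  is_client <- is_multi & stats::rbinom(n, 1, p_client) == 1

  n_codons <- integer(n)
  first_start <- rep(NA_integer_, n)
  cluster_end <- rep(NA_integer_, n)
  tmd_rows <- vector("list", n)
  margin <- spec$client_peak_offset + 80L  # room for a fully-post-peak window
  for (i in seq_len(n)) {
    for (try in seq_len(200L)) {
      len <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], 1)
      if (!is_tmd[i]) break
      s <- sample(spec$first_tmd_start_range[1]:spec$first_tmd_start_range[2],
                  1)
      k <- if (is_multi[i]) {
        sample(spec$cluster_size_range[1]:spec$cluster_size_range[2], 1)
      } else 1L
      loops <- if (k > 1) {
        sample(spec$loop_length_range[1]:spec$loop_length_range[2], k - 1,
               replace = TRUE)
      } else integer(0)
      starts <- s + cumsum(c(0L, loops + spec$tmd_length))
      ends <- starts + spec$tmd_length - 1L
      if (max(ends) + margin <= len) {
        first_start[i] <- s
        cluster_end[i] <- max(ends)
        tmd_rows[[i]] <- tibble(gene_id = ids[i], start_aa = starts,
                                end_aa = ends, source = "CURATED")
        break
      }
      if (try == 200L) {
        stop("could not place TMD cluster for gene ", ids[i], call. = FALSE)
      }
    }
    n_codons[i] <- len
  }

  expr <- stats::rlnorm(n, meanlog = 0, sdlog = spec$expression_sdlog)
  silent <- !is_tmd & stats::rbinom(n, 1, spec$silent_fraction) == 1
  expr[silent] <- expr[silent] * spec$silent_factor

  cds <- vapply(n_codons, function(m) {
    paste(sample(c("A", "C", "G", "T"), 3L * m, replace = TRUE),
          collapse = "")
  }, "")

  # protein sequences for TMD composition analyses: globular-like background,
  # hydrophobic-rich TMD spans, client TMDs salted with charged/aromatic
  # residues (kept independent of the uniform-nucleotide CDS used for
  # mappability)
  proteins <- character(n)
  for (i in seq_len(n)) {
    aa <- sample(names(aa_freq_background), n_codons[i], replace = TRUE,
                 prob = aa_freq_background)
    if (is_tmd[i]) {
      for (j in seq_len(nrow(tmd_rows[[i]]))) {
        span <- tmd_rows[[i]]$start_aa[j]:tmd_rows[[i]]$end_aa[j]
        aa[span] <- sample(names(aa_freq_tmd), length(span), replace = TRUE,
                           prob = aa_freq_tmd)
        if (is_client[i] && spec$client_tmd_charge_boost > 0) {
          hit <- stats::rbinom(length(span), 1,
                               spec$client_tmd_charge_boost) == 1
          aa[span][hit] <- sample(c("D", "E", "K", "R", "F", "W", "Y"),
                                  sum(hit), replace = TRUE)
        }
      }
    }
    proteins[i] <- paste(aa, collapse = "")
  }
  names(proteins) <- ids

  list(
    genes = new_gene_table(ids, n_codons, cds, is_secretory = is_tmd),
    proteins = proteins,
    tmds = bind_rows(tmd_rows),
    truth = tibble(gene_id = ids, is_tmd = is_tmd, is_multipass = is_multi,
                   is_client = is_client, first_tmd_start = first_start,
                   cluster_end = cluster_end, expr_factor = expr,
                   is_silent = silent)
  )
}

# amino-acid alphabets for simulated proteins: rough globular-protein
# frequencies and a hydrophobic TMD alphabet
aa_freq_background <- c(A = 0.08, R = 0.05, N = 0.04, D = 0.055, C = 0.015,
                        Q = 0.04, E = 0.065, G = 0.07, H = 0.02, I = 0.06,
                        L = 0.095, K = 0.06, M = 0.02, F = 0.04, P = 0.045,
                        S = 0.07, T = 0.055, W = 0.01, Y = 0.03, V = 0.07)
aa_freq_tmd <- c(L = 0.24, I = 0.12, V = 0.12, A = 0.11, F = 0.09,
                 M = 0.04, G = 0.06, S = 0.05, T = 0.05, W = 0.02,
                 Y = 0.03, C = 0.02, P = 0.02, N = 0.01, Q = 0.01,
                 H = 0.01, K = 0.01, R = 0.01, D = 0.005, E = 0.005)

# expected pulldown/input enrichment along one gene for one bait
positional_enrichment <- function(spec, n_codons, first_start, cluster_end,
                                  is_client, is_test_bait) {
  f <- rep(1, n_codons)
  if (is.na(first_start)) return(f)
  pos <- seq_len(n_codons)
  center <- first_start + spec$targeting_ramp_start
  f <- 1 + (spec$ramp_gain - 1) *
    stats::plogis((pos - center) / (spec$ramp_width / 4))
  if (isTRUE(is_client) && is_test_bait) {
    peak_start <- cluster_end + spec$client_peak_offset
    f[pos >= peak_start] <- f[pos >= peak_start] * spec$client_peak_gain
  }
  f
}

#' Simulate footprint profiles for a test and a reference ER bait
#'
#' Input libraries have flat per-codon means `input_depth * expr_factor`;
#' pulldown means are the input means times the positional enrichment
#' (targeting ramp for every TMD gene under every ER bait, client peak under
#' the test bait only). Counts are independent Poisson (or negative
#' binomial) draws per codon, per sample, per replicate. All libraries
#' report a common sequencing depth as `sample_total` (depth-matched
#' libraries); in `analytic` mode the expected means are emitted instead of
#' draws, so downstream statistics equal their infinite-depth values.
#'
#' @param spec A [simulation_spec()].
#' @param transcriptome Output of [simulate_transcriptome()].
#' @param test_bait,reference_bait Bait labels (reference emulates a
#'   general-ER tail-anchor fusion: ramp, never the client peak).
#' @param analytic Emit expected means instead of stochastic counts.
#' @param seed RNG seed (default `spec$rng_seed + 1`).
#' @return List with `profiles` (profile tibble) and `pairs` (pairing
#'   tibble).
#' @export
simulate_profiles <- function(spec, transcriptome,
                              test_bait = "Emc5BirA",
                              reference_bait = "UbcTA",
                              analytic = FALSE,
                              seed = spec$rng_seed + 1L) {
  set.seed(seed)
  tr <- transcriptome$truth
  genes <- transcriptome$genes
  baits <- c(test_bait, reference_bait)
  rows <- list()
  sums <- c()
  for (bait in baits) {
    for (rep_i in seq_len(spec$n_replicates)) {
      for (fraction in c("pulldown", "input")) {
        sid <- paste(bait, paste0("rep", rep_i), fraction, sep = "_")
        counts <- vector("list", nrow(genes))
        for (g in seq_len(nrow(genes))) {
          mu <- spec$input_depth * tr$expr_factor[g]
          mean_vec <- rep(mu, genes$n_codons[g])
          if (fraction == "pulldown") {
            mean_vec <- mean_vec * positional_enrichment(
              spec, genes$n_codons[g], tr$first_tmd_start[g],
              tr$cluster_end[g], tr$is_client[g], bait == test_bait)
          }
          counts[[g]] <- if (analytic) {
            mean_vec
          } else if (spec$noise_model == "poisson") {
            stats::rpois(length(mean_vec), mean_vec)
          } else {
            stats::rnbinom(length(mean_vec), mu = mean_vec,
                           size = spec$nb_dispersion)
          }
        }
        rows[[sid]] <- tibble(gene_id = genes$gene_id, sample_id = sid,
                              counts = counts)
        sums[sid] <- sum(vapply(counts, sum, 0))
      }
    }
  }
  total <- if (analytic) 1.05 * max(sums) else ceiling(1.05 * max(sums))
  profiles <- bind_rows(rows)
  profiles$sample_total <- total
  pairs <- bind_rows(lapply(baits, function(bait) {
    tibble(bait_id = bait,
           replicate_id = paste0("rep", seq_len(spec$n_replicates)),
           pulldown_sample = paste(bait,
                                   paste0("rep", seq_len(spec$n_replicates)),
                                   "pulldown", sep = "_"),
           input_sample = paste(bait,
                                paste0("rep", seq_len(spec$n_replicates)),
                                "input", sep = "_"))
  }))
  list(profiles = profiles, pairs = pairs,
       test_bait = test_bait, reference_bait = reference_bait)
}

#' Simulate a dual-knockdown SILAC proteome table
#'
#' Planted clients shift by `proteome_effect_log2` in both knockdowns;
#' everything else is centered at zero. A configurable fraction of clients
#' is translationally driven (their translation change shifts too);
#' remaining translation changes are null. TMD counts are taken from the
#' transcriptome's annotations.
#'
#' @param spec A [simulation_spec()].
#' @param transcriptome Output of [simulate_transcriptome()].
#' @param seed RNG seed (default `spec$rng_seed + 2`).
#' @return Proteome tibble (see [read_proteome_table()]) plus an
#'   `is_client` truth column.
#' @export
simulate_proteome <- function(spec, transcriptome,
                              seed = spec$rng_seed + 2L) {
  set.seed(seed)
  tr <- transcriptome$truth
  n <- nrow(tr)
  mu <- ifelse(tr$is_client, spec$proteome_effect_log2, 0)
  kd1 <- stats::rnorm(n, mu, spec$proteome_noise_sd)
  kd2 <- stats::rnorm(n, mu, spec$proteome_noise_sd)
  driven <- tr$is_client &
    stats::rbinom(n, 1, spec$translation_driven_fraction) == 1
  tl <- stats::rnorm(n, ifelse(driven, spec$proteome_effect_log2, 0),
                     spec$proteome_noise_sd)
  n_tmds <- as.integer(table(factor(transcriptome$tmds$gene_id,
                                    levels = tr$gene_id)))
  tibble(protein_id = tr$gene_id,
         log2_kd1_vs_control = kd1,
         log2_kd2_vs_control = kd2,
         log2_translation_change = tl,
         n_tmds = n_tmds,
         is_client = tr$is_client,
         is_translation_driven = driven)
}

#' Simulate a complete study (transcriptome, profiles, proteome)
#'
#' Stage seeds are derived from `spec$rng_seed` so one integer reproduces
#' the whole dataset.
#'
#' @param spec A [simulation_spec()].
#' @param analytic Passed to [simulate_profiles()].
#' @return List `transcriptome`, `ribo` (profiles + pairs), `proteome`.
#' @export
simulate_dataset <- function(spec, analytic = FALSE) {
  transcriptome <- simulate_transcriptome(spec, seed = spec$rng_seed)
  ribo <- simulate_profiles(spec, transcriptome, analytic = analytic,
                            seed = spec$rng_seed + 1L)
  proteome <- simulate_proteome(spec, transcriptome,
                                seed = spec$rng_seed + 2L)
  list(transcriptome = transcriptome, ribo = ribo, proteome = proteome)
}
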