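test_that("curated spans displace overlapping predictions", {
  pred <- tibble::tibble(gene_id = "g1", start_aa = 10L, end_aa = 30L,
                         source = "PREDICTED")
  cur <- tibble::tibble(gene_id = "g1", start_aa = 12L, end_aa = 32L,
                        source = "CURATED")
  merged <- merge_tmd_sources(pred, cur)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$source, "CURATED")
  expect_equal(merged$start_aa, 12L)

  disjoint <- merge_tmd_sources(
    pred, tibble::tibble(gene_id = "g1", start_aa = 50L, end_aa = 70L,
                         source = "CURATED"))
  expect_equal(nrow(disjoint), 2L)
  # same span on a different gene does not displace
  other <- merge_tmd_sources(
    pred, dplyr::mutate(cur, gene_id = "g2"))
  expect_equal(nrow(other), 2L)
  # excluded genes are removed from both sources
  excl <- merge_tmd_sources(pred, cur, excluded_genes = "g1")
  expect_equal(nrow(excl), 0L)
})

test_that("merging matches a pairwise interval oracle on random spans", {
  set.seed(41)
  for (case in 1:40) {
    genes <- sprintf("g%d", 1:4)
    mk <- function(src, n) {
      s <- sample(1:80, n, replace = TRUE)
      tibble::tibble(gene_id = sample(genes, n, replace = TRUE),
                     start_aa = as.integer(s),
                     end_aa = as.integer(s + sample(5:25, n, replace = TRUE)),
                     source = src)
    }
    pred <- mk("PREDICTED", sample(1:6, 1))
    cur <- mk("CURATED", sample(1:6, 1))
    got <- merge_tmd_sources(pred, cur)
    want <- oracle_merge_tmds(pred, cur)
    key <- function(d) sort(paste(d$gene_id, d$start_aa, d$end_aa, d$source))
    expect_equal(key(got), key(want))
    # invariant: no surviving prediction overlaps a curated span in-gene
    surv <- got[got$source == "PREDICTED", ]
    for (i in seq_len(nrow(surv))) {
      cg <- cur[cur$gene_id == surv$gene_id[i], ]
      expect_false(any(surv$start_aa[i] <= cg$end_aa &
                         cg$start_aa <= surv$end_aa[i]))
    }
  }
})

test_that("TMD count histogram covers zero bins and sums to one", {
  tmds <- tibble::tibble(gene_id = c("a", "b", rep("c", 7)),
                         start_aa = 1L, end_aa = 10L, source = "CURATED")
  hist <- tmd_count_histogram(tmds, c("a", "b", "c"))
  expect_equal(hist$proportion[hist$n_tmds == 1], 2 / 3)
  expect_equal(hist$proportion[hist$n_tmds == 7], 1 / 3)
  with_zero <- tmd_count_histogram(tmds, c("a", "b", "c", "naked"))
  expect_equal(with_zero$proportion[with_zero$n_tmds == 0], 1 / 4)
  expect_equal(sum(with_zero$proportion), 1, tolerance = 1e-9)
  expect_error(tmd_count_histogram(tmds, character(0)), "empty gene set")
})

test_that("residue classification follows the shipped table", {
  expect_equal(classify_residue("K"), "CHARGED")
  expect_setequal(classify_residue("F"), c("AROMATIC", "HYDROPHOBIC"))
  expect_setequal(classify_residue("Y"), c("AROMATIC", "POLAR"))
  expect_equal(classify_residue("G"), character(0))
  expect_error(classify_residue("B"), "B")
})

test_that("client set equal to all TMDs gives unit ratios and a unit band", {
  set.seed(42)
  pool <- make_tmd_pool(12)
  pe <- property_enrichment(pool$tmds, pool$tmds, pool$proteins,
                            n_bootstrap = 50, seed = 1)
  expect_equal(pe$ratio, rep(1, 5))
  expect_equal(pe$ci_low, rep(1, 5))
  expect_equal(pe$ci_high, rep(1, 5))
  expect_error(property_enrichment(pool$tmds, pool$tmds[1:3, ],
                                   pool$proteins, 10, seed = 1),
               "larger")
})

test_that("pooled fractions weight long TMDs by their residue count", {
  proteins <- c(g1 = "KKKKKKKKKK", g2 = "LLLL")
  tmds <- tibble::tibble(gene_id = c("g1", "g2"),
                         start_aa = c(1L, 1L), end_aa = c(10L, 4L),
                         source = "CURATED")
  pe <- property_enrichment(tmds, tmds, proteins, n_bootstrap = 5, seed = 1)
  expect_equal(pe$fraction_all[pe$property == "CHARGED"], 10 / 14)
  expect_equal(pe$fraction_all[pe$property == "ALIPHATIC"], 4 / 14)
})

test_that("identical seeds reproduce identical bootstrap bands", {
  set.seed(43)
  pool <- make_tmd_pool(30)
  cli <- pool$tmds[sample(30, 8), ]
  a <- property_enrichment(cli, pool$tmds, pool$proteins,
                           n_bootstrap = 200, seed = 99)
  b <- property_enrichment(cli, pool$tmds, pool$proteins,
                           n_bootstrap = 200, seed = 99)
  expect_identical(a, b)
  c <- property_enrichment(cli, pool$tmds, pool$proteins,
                           n_bootstrap = 200, seed = 100)
  expect_false(identical(a$ci_low, c$ci_low))
})

test_that("charge-biased client TMDs show an elevated charged ratio", {
  set.seed(44)
  base <- make_tmd_pool(60)
  biased <- make_tmd_pool(15, charged_bias = 4)
  biased$tmds$gene_id <- sprintf("q%03d", 1:15)
  names(biased$proteins) <- biased$tmds$gene_id
  all_tmds <- dplyr::bind_rows(base$tmds, biased$tmds)
  proteins <- c(base$proteins, biased$proteins)
  pe <- property_enrichment(biased$tmds, all_tmds, proteins,
                            n_bootstrap = 500, seed = 7)
  charged <- pe[pe$property == "CHARGED", ]
  expect_gt(charged$ratio, 1)
  expect_gt(charged$ratio, charged$ci_high)  # outside the null band
})

test_that("per-position fractions average the right residues", {
  proteins <- c(g1 = "KLAV", g2 = "KV")
  tmds <- tibble::tibble(gene_id = c("g1", "g2"), start_aa = 1L,
                         end_aa = c(4L, 2L), source = "CURATED")
  pp <- property_by_position(tmds, proteins, max_position = 3)
  p1 <- pp[pp$position == 1 & pp$property == "CHARGED", ]
  expect_equal(p1$fraction, 1)          # K in both spans
  expect_equal(p1$n_tmds, 2L)
  p3 <- pp[pp$position == 3, ]
  expect_equal(unique(p3$n_tmds), 1L)   # only g1 reaches position 3
})
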