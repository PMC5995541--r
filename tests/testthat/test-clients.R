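make_pairs <- function(baits = "b1", reps = "r1") {
  dplyr::bind_rows(lapply(baits, function(b) {
    tibble::tibble(bait_id = b, replicate_id = reps,
                   pulldown_sample = paste(b, reps, "pd", sep = "_"),
                   input_sample = paste(b, reps, "in", sep = "_"))
  }))
}

spread_counts <- function(n, positions, value = 1L) {
  v <- integer(n)
  v[positions] <- value
  v
}

test_that("expression filter uses a strict reads/codon/million cutoff", {
  pairs <- make_pairs()
  genes <- tibble::tibble(gene_id = c("gpass", "gedge"), n_codons = 100L,
                          cds_seq = NA_character_)
  profiles <- tibble::tibble(
    gene_id = rep(c("gpass", "gedge"), each = 2),
    sample_id = rep(c("b1_r1_in", "b1_r1_pd"), 2),
    counts = list(spread_counts(100, seq(10, 100, 10)),   # 10 reads
                  spread_counts(100, seq(10, 100, 10)),
                  spread_counts(100, c(30, 70)),          # exactly 0.02
                  spread_counts(100, c(30, 70))),
    sample_total = 1e6)
  keep <- filter_expression(profiles, pairs, genes, half_width = 50,
                            cutoff = 0.02)
  expect_true("gpass" %in% keep)   # 0.1 > 0.02
  expect_false("gedge" %in% keep)  # 0.02 is not > 0.02
})

test_that("a zero 101-codon window in any sample fails the filter", {
  pairs <- make_pairs()
  genes <- tibble::tibble(gene_id = "g", n_codons = 300L,
                          cds_seq = NA_character_)
  dense <- spread_counts(300, seq(1, 300, 5), 2L)
  gap <- dense
  gap[80:200] <- 0L  # >101 consecutive zeros in the pulldown only
  profiles <- tibble::tibble(
    gene_id = "g", sample_id = c("b1_r1_in", "b1_r1_pd"),
    counts = list(dense, gap), sample_total = 1e6)
  expect_equal(filter_expression(profiles, pairs, genes, 50, 0.02),
               character(0))
  ok <- profiles
  ok$counts <- list(dense, dense)
  expect_equal(filter_expression(ok, pairs, genes, 50, 0.02), "g")
})

test_that("localization requires a strict RPKM ratio > 1 in some pair", {
  pairs <- make_pairs(baits = c("b1", "b2"))
  counts10 <- spread_counts(50, 1:10)
  counts20 <- spread_counts(50, 1:20)
  profiles <- tibble::tibble(
    gene_id = "g",
    sample_id = c("b1_r1_pd", "b1_r1_in", "b2_r1_pd", "b2_r1_in"),
    counts = list(counts10, counts10, counts20, counts10),
    sample_total = c(1e5, 1e5, 1e5, 1e5))
  # pair b1: equal shares, ratio exactly 1 -> not sufficient
  expect_equal(filter_localization(profiles[1:2, ], pairs[1, ]), character(0))
  # pair b2 doubles the pulldown share -> passes
  expect_equal(filter_localization(profiles, pairs), "g")
})

test_that("localization membership matches a per-pair oracle", {
  set.seed(21)
  pairs <- make_pairs(baits = c("b1", "b2"))
  for (case in 1:20) {
    ids <- sprintf("g%d", 1:8)
    profiles <- dplyr::bind_rows(lapply(ids, function(g) {
      dplyr::bind_rows(lapply(pairs$bait_id, function(b) {
        tibble::tibble(
          gene_id = g,
          sample_id = paste(b, "r1", c("pd", "in"), sep = "_"),
          counts = list(rpois(20, 3), rpois(20, 3)),
          sample_total = sample(5000:6000, 2))
      }))
    }))
    got <- sort(filter_localization(profiles, pairs))
    want <- Filter(function(g) {
      any(vapply(seq_len(nrow(pairs)), function(k) {
        pd <- profiles[profiles$gene_id == g &
                         profiles$sample_id == pairs$pulldown_sample[k], ]
        ip <- profiles[profiles$gene_id == g &
                         profiles$sample_id == pairs$input_sample[k], ]
        rpkm <- function(row) {
          (sum(row$counts[[1]]) / (20 * 3 / 1000)) /
            (row$sample_total / 1e6)
        }
        rpkm(pd) / rpkm(ip) > 1
      }, TRUE))
    }, ids)
    expect_equal(got, sort(want))
  }
})

test_that("top decile of 10 genes is exactly the top gene per replicate", {
  max_tbl <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:10), 2),
    replicate_id = rep(c("r1", "r2"), each = 10),
    max_value = c(1:10, c(2:10, 1) + 0.5))  # g10 top in r1, g09 top in r2
  calls <- call_clients(max_tbl, percentile = 90)
  expect_equal(sum(calls$top_decile[calls$replicate_id == "r1"]), 1L)
  expect_equal(unique(calls$gene_id[calls$is_client]), character(0))

  # make the same gene top in both replicates
  max_tbl$max_value[20] <- 99
  calls <- call_clients(max_tbl, percentile = 90)
  expect_equal(unique(calls$gene_id[calls$is_client]), "g10")
})

test_that("a gene must reach the decile in every replicate", {
  max_tbl <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:10), 2),
    replicate_id = rep(c("r1", "r2"), each = 10),
    max_value = c(c(1:9, 100), c(5, 1:4, 6:9, 4.5)))  # g10 median in r2
  calls <- call_clients(max_tbl)
  expect_false(any(calls$is_client))
})

test_that("ties at one value make every gene a client", {
  max_tbl <- tibble::tibble(gene_id = rep(sprintf("g%d", 1:6), 2),
                            replicate_id = rep(c("r1", "r2"), each = 6),
                            max_value = 3.3)
  calls <- call_clients(max_tbl)
  expect_true(all(calls$is_client))
  expect_error(call_clients(max_tbl[max_tbl$replicate_id == "r1", ]),
               "2 replicates")
})

test_that("client sets match a nearest-rank oracle on random maxima", {
  set.seed(22)
  for (case in 1:30) {
    n <- sample(5:40, 1)
    p <- sample(c(50, 75, 90), 1)
    ids <- sprintf("g%02d", seq_len(n))
    max_tbl <- tibble::tibble(
      gene_id = rep(ids, 2),
      replicate_id = rep(c("r1", "r2"), each = n),
      max_value = round(runif(2 * n, 0, 4), 1))  # rounding makes ties
    calls <- call_clients(max_tbl, percentile = p)
    got <- sort(unique(calls$gene_id[calls$is_client]))
    want <- Reduce(intersect, lapply(c("r1", "r2"), function(r) {
      d <- max_tbl[max_tbl$replicate_id == r, ]
      thr <- sort(d$max_value)[min(floor(n * p / 100) + 1, n)]
      d$gene_id[d$max_value >= thr]
    }))
    expect_equal(got, sort(want))
    # no-ties case never exceeds the decile count per replicate
    for (r in c("r1", "r2")) {
      d <- max_tbl[max_tbl$replicate_id == r, ]
      if (!anyDuplicated(d$max_value)) {
        expect_lte(sum(calls$top_decile[calls$replicate_id == r]),
                   ceiling(n * (100 - p) / 100))
      }
    }
  }
})

test_that("ineligible genes are recorded with their failed filters", {
  max_tbl <- tibble::tibble(
    gene_id = rep(c("a", "b", "c", "d"), 2),
    replicate_id = rep(c("r1", "r2"), each = 4),
    max_value = c(4, 1, 1, NA, 4, 1, 1, NA))
  calls <- client_calls(max_tbl, mappable = c("a", "b", "d"),
                        expressed = c("a", "b", "c", "d"),
                        localized = c("a", "b", "d"),
                        percentile = 60)
  expect_true(all(calls$eligible[calls$gene_id %in% c("a", "b")]))
  cfail <- calls$filter_failures[calls$gene_id == "c"][1]
  expect_match(cfail, "MAPPABILITY")
  expect_match(cfail, "LOCALIZATION")
  dfail <- calls$filter_failures[calls$gene_id == "d"][1]
  expect_match(dfail, "EXPRESSION")  # undefined statistic
  expect_true(any(calls$is_client[calls$gene_id == "a"]))
})
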