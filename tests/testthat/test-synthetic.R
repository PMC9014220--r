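test_that("generation is deterministic: same seed, byte-identical output", {
  g1 <- generate_sequences(n_circ = 12, n_mir = 8, n_mrna = 15,
                           n_planted = 2, rng_seed = 99)
  g2 <- generate_sequences(n_circ = 12, n_mir = 8, n_mrna = 15,
                           n_planted = 2, rng_seed = 99)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$truth$triplets, g2$truth$triplets)

  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$sequences$circ, f1, circular = TRUE)
  write_fasta(g2$sequences$circ, f2, circular = TRUE)
  expect_identical(readLines(f1), readLines(f2))

  design <- study_design()
  c1 <- simulate_counts(design, g1$truth, rng_seed = 5)
  c2 <- simulate_counts(design, g2$truth, rng_seed = 5)
  expect_identical(c1$circ$counts, c2$circ$counts)
  expect_identical(c1$mir$counts, c2$mir$counts)
})

test_that("with no planted triplets no sequence contains any seed site", {
  g <- generate_sequences(n_circ = 10, n_mir = 6, n_mrna = 12,
                          n_planted = 0, rng_seed = 7)
  expect_equal(nrow(g$truth$triplets), 0L)
  expect_equal(nrow(find_sites(g$sequences$circ, g$sequences$mir,
                               circular = TRUE)), 0L)
  expect_equal(nrow(find_sites(g$sequences$mrna, g$sequences$mir,
                               circular = FALSE)), 0L)
})

test_that("planted sites are discoverable with the promised counts and
           junction-spanning placement", {
  g <- generate_sequences(n_circ = 10, n_mir = 6, n_mrna = 12,
                          n_planted = 3, rng_seed = 21)
  tr <- g$truth$triplets
  for (k in seq_len(nrow(tr))) {
    circ_sites <- find_sites_circular(g$sequences$circ[[tr$circ_id[k]]],
                                      g$sequences$mir[[tr$mir_id[k]]])
    expect_equal(length(unique(circ_sites$start)), tr$site_count_circ[k])
    expect_true(any(circ_sites$spans_junction))
    # the junction-spanning site is invisible to a linear scan
    lin <- find_sites_linear(g$sequences$circ[[tr$circ_id[k]]],
                             g$sequences$mir[[tr$mir_id[k]]])
    expect_lt(length(unique(lin$start)), length(unique(circ_sites$start)) + 1)
    expect_lt(nrow(lin), nrow(circ_sites))

    utr_sites <- find_sites_linear(g$sequences$mrna[[tr$mrna_id[k]]],
                                   g$sequences$mir[[tr$mir_id[k]]])
    expect_equal(length(unique(utr_sites$start)), tr$site_count_mrna[k])
  }
  # cross-talk: non-partner sequences carry no sites for the planted miRNAs
  other_circ <- setdiff(names(g$sequences$circ), tr$circ_id)
  expect_equal(nrow(find_sites(g$sequences$circ[other_circ],
                               g$sequences$mir[tr$mir_id],
                               circular = TRUE)), 0L)
})

test_that("impossible embeddings fail with an explicit message", {
  sc <- planted_scenario(1, site_count_circ = 2)
  expect_error(
    generate_sequences(n_circ = 3, n_mir = 3, n_mrna = 3, n_planted = sc,
                       rng_seed = 1, circ_len = 18, utr_len = 100),
    "too short")
})

test_that("null counts with zero dispersion sit at the baseline", {
  ids <- sprintf("f%02d", 1:20)
  truth <- make_truth(ids, "m1", "g1")
  design <- study_design(replicates_per_group = 13)  # 52 samples
  counts <- simulate_counts(design, truth, baseline_mean = 1000,
                            dispersion = 0, rng_seed = 31)
  m <- rowMeans(counts$circ$counts)
  se <- sqrt(1000 / ncol(counts$circ$counts))
  expect_true(all(abs(m - 1000) < 5 * se))
})

test_that("a planted 2-log2FC feature is recovered by the DE pipeline with
           high power", {
  ids <- sprintf("c%03d", 1:100)
  truth <- make_truth(ids, c("m1", "m2"), c("g1", "g2"),
                      de_circ = data.frame(feature_id = "c001", log2fc = 2))
  design <- study_design()
  cmp <- comparison_samples(design, "control")
  hits <- vapply(1:100, function(s) {
    counts <- simulate_counts(design, truth, baseline_mean = 500,
                              dispersion = 0.1, rng_seed = s)
    cc <- counts$circ
    expr <- srpbm(cc)
    de <- call_de(ceRNAnet:::subset_expression(expr, cmp$a),
                  ceRNAnet:::subset_expression(expr, cmp$b),
                  ceRNAnet:::subset_counts(cc, cmp$a),
                  ceRNAnet:::subset_counts(cc, cmp$b))
    de$passes_filter[de$feature_id == "c001"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("sponge coupling induces the expected correlations and preserves
           the planted effect size", {
  sc <- planted_scenario(1)
  sc$circ_id <- "c001"; sc$mir_id <- "m001"; sc$mrna_id <- "g001"
  truth <- make_truth(sprintf("c%03d", 1:10), sprintf("m%03d", 1:8),
                      sprintf("g%03d", 1:12),
                      de_circ = data.frame(feature_id = "c001", log2fc = 2),
                      de_mir = data.frame(feature_id = "m001", log2fc = -2),
                      de_mrna = data.frame(feature_id = "g001", log2fc = 2),
                      triplets = sc)
  design <- study_design()
  cmp <- comparison_samples(design, "control")
  res <- vapply(1:100, function(s) {
    counts <- simulate_counts(design, truth, rng_seed = 1000 + s)
    x <- counts$circ$counts["c001", c(cmp$a, cmp$b)]
    y <- counts$mrna$counts["g001", c(cmp$a, cmp$b)]
    m <- counts$mir$counts["m001", c(cmp$a, cmp$b)]
    c(cor_xy = cor(x, y), cor_xm = cor(x, m),
      l2fc = log2fc(mean(counts$circ$counts["c001", cmp$a]),
                    mean(counts$circ$counts["c001", cmp$b])))
  }, numeric(3))
  expect_gte(mean(res["cor_xy", ] > 0), 0.95)
  expect_gt(mean(res["cor_xm", ] < 0), 0.8)  # negative miR-target coupling
  expect_lt(abs(median(res["l2fc", ]) - 2), 0.3)
})

test_that("the truth ledger survives a JSON round trip", {
  g <- generate_sequences(n_circ = 8, n_mir = 6, n_mrna = 8, n_planted = 2,
                          rng_seed = 3)
  p <- tempfile(fileext = ".json")
  write_truth(g$truth, p)
  back <- read_truth(p)
  expect_equal(back$triplets, g$truth$triplets)
  expect_equal(back$de_features$mir, g$truth$de_features$mir)
  expect_equal(back$feature_ids$circ, g$truth$feature_ids$circ)
  expect_equal(back$rng_seed, g$truth$rng_seed)
})
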