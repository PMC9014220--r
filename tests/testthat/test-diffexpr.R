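test_that("pooled Fisher P matches exhaustive hypergeometric enumeration", {
  # identical margins give P = 1
  expect_equal(fisher_feature_test(0, 0, 10, 10), 1)
  # hand-picked and random small tables vs the enumeration oracle
  tabs <- rbind(c(1, 10, 11, 14),
                c(3, 20, 9, 25),
                c(0, 12, 7, 30),
                c(5, 9, 2, 18))
  for (i in seq_len(nrow(tabs))) {
    a <- tabs[i, 1]; la <- tabs[i, 2]; b <- tabs[i, 3]; lb <- tabs[i, 4]
    expect_equal(fisher_feature_test(a, b, la, lb),
                 oracle_fisher(a, la - a, b, lb - b), tolerance = 1e-12)
  }
  # row swap leaves P unchanged
  expect_equal(fisher_feature_test(3, 9, 20, 25),
               fisher_feature_test(9, 3, 25, 20), tolerance = 1e-14)
  expect_error(fisher_feature_test(11, 2, 10, 10), "exceeds")
})

test_that("log2 fold change handles zeros via the pseudocount", {
  expect_equal(log2fc(5, 5), 0)
  expect_equal(log2fc(1, 4, pseudocount = 1e-9), 2, tolerance = 1e-6)
  expect_equal(log2fc(0, 10, pseudocount = 0.1), log2(10.1 / 0.1))
  expect_equal(log2fc(0, 10, pseudocount = 0.1), 6.658, tolerance = 1e-3)
  expect_error(log2fc(-1, 2), "negative")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
})

make_de_inputs <- function(counts_a, counts_b, lib_a = NULL, lib_b = NULL) {
  ids <- sprintf("f%03d", seq_len(nrow(counts_a)))
  dimnames(counts_a) <- list(ids, sprintf("a%d", seq_len(ncol(counts_a))))
  dimnames(counts_b) <- list(ids, sprintf("b%d", seq_len(ncol(counts_b))))
  ca <- count_matrix(counts_a, library_size = lib_a)
  cb <- count_matrix(counts_b, library_size = lib_b)
  list(ea = srpbm(ca), eb = srpbm(cb), ca = ca, cb = cb)
}

test_that("identical groups yield no DE calls and threshold edges hold", {
  set.seed(5)
  m <- matrix(rpois(60, 200), 20, 3)
  x <- make_de_inputs(m, m)
  de <- call_de(x$ea, x$eb, x$ca, x$cb)
  expect_false(any(de$passes_filter))
  expect_true(all(de$p_adjusted >= de$p_value))
  expect_true(all((de$log2_fold_change > 0) == (de$direction == "up")))

  # |log2FC| just under 1 fails no matter how small P is
  rec <- de[1, ]
  rec$log2_fold_change <- 0.99
  rec$p_value <- 1e-9
  pass <- abs(rec$log2_fold_change) >= 1 & rec$p_value <= 0.05
  expect_false(pass)
})

test_that("swapping group labels negates fold changes and keeps P", {
  set.seed(23)
  a <- matrix(rpois(90, 150), 30, 3)
  b <- matrix(rpois(90, 250), 30, 3)
  x <- make_de_inputs(a, b)
  de_ab <- call_de(x$ea, x$eb, x$ca, x$cb)
  de_ba <- call_de(x$eb, x$ea, x$cb, x$ca)
  o <- match(de_ab$feature_id, de_ba$feature_id)
  expect_equal(de_ab$log2_fold_change, -de_ba$log2_fold_change[o],
               tolerance = 1e-12)
  expect_equal(de_ab$p_value, de_ba$p_value[o], tolerance = 1e-12)
})

test_that("the Fisher test keeps its nominal level under its own sampling
           model (Poisson counting noise, no biological dispersion)", {
  ids <- sprintf("f%04d", 1:2500)
  truth <- make_truth(ids, "m1", "g1")
  design <- study_design()
  cmp <- comparison_samples(design, "control")
  counts <- simulate_counts(design, truth, baseline_mean = 200,
                            dispersion = 0, rng_seed = 77)
  cc <- counts$circ
  ca <- rowSums(cc$counts[, cmp$a])
  cb <- rowSums(cc$counts[, cmp$b])
  p <- fisher_feature_test(ca, cb, sum(cc$library_size[cmp$a]),
                           sum(cc$library_size[cmp$b]))
  rate <- mean(p <= 0.05)
  mcse <- sqrt(0.05 * 0.95 / length(p))
  expect_lte(rate, 0.05 + 2 * mcse)
})

test_that("DE records are sorted by P with feature-id tiebreak", {
  set.seed(9)
  a <- matrix(rpois(30, 100), 10, 3)
  x <- make_de_inputs(a, a)
  de <- call_de(x$ea, x$eb, x$ca, x$cb)
  expect_false(is.unsorted(de$p_value))
  ties <- split(de$feature_id, de$p_value)
  expect_true(all(vapply(ties, function(v) !is.unsorted(v), logical(1))))
})
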