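test_that("hypergeometric P matches point-mass summation and its limits", {
  expect_equal(hypergeom_p(0, 10, 20, 100), 1)
  expect_equal(hypergeom_p(10, 10, 10, 10), 1)
  expect_equal(hypergeom_p(4, 10, 20, 100),
               oracle_hypergeom(4, 10, 20, 100), tolerance = 1e-12)
  set.seed(61)
  for (i in 1:50) {
    N <- sample(50:400, 1)
    K <- sample(5:40, 1)
    n <- sample(5:40, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_p(k, n, K, N), oracle_hypergeom(k, n, K, N),
                 tolerance = 1e-12)
  }
  # more hits can only be more surprising
  ps <- vapply(0:10, hypergeom_p, numeric(1), list_size = 10,
               term_size = 20, background_size = 100)
  expect_false(is.unsorted(rev(ps)))
  expect_error(hypergeom_p(11, 10, 20, 100), "inconsistent")
})

test_that("the enrichment factor is observed over expected", {
  expect_equal(enrichment_factor(5, 10, 50, 1000), 10)
  # hits at exactly the background rate give EF 1
  expect_equal(enrichment_factor(2, 10, 20, 100), 1)
  set.seed(67)
  for (i in 1:100) {
    N <- sample(100:1000, 1); K <- sample(1:80, 1)
    n <- sample(1:80, 1); k <- sample(0:min(n, K), 1)
    expect_equal(enrichment_factor(k, n, K, N), (k / n) / (K / N))
  }
  expect_error(enrichment_factor(1, 0, 5, 10), "denominator")
})

test_that("enrich ranks a perfectly matching rare term first and enforces
           the minimum count", {
  background <- sprintf("gene%03d", 1:200)
  coll <- list(hit_term = background[1:10],
               big_term = background[1:150],
               other = background[51:70])
  res <- enrich(background[1:10], coll, background)
  expect_identical(res$term_id[1], "hit_term")
  expect_true(res$passes[res$term_id == "hit_term"])
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # a count of 2 never passes, whatever its P
  res2 <- enrich(background[1:2], list(tiny = background[1:2]), background)
  expect_equal(res2$count, 2L)
  expect_false(res2$passes)

  expect_message(enrich(c("gene001", "not_in_bg"), coll, background),
                 "absent")
})

test_that("random gene lists under a null collection stay near the nominal
           rejection rate", {
  set.seed(71)
  background <- sprintf("g%04d", 1:500)
  coll <- lapply(1:20, function(i) sample(background, 25))
  names(coll) <- sprintf("term%02d", 1:20)
  hits <- 0L; total <- 0L
  for (d in 1:500) {
    gl <- sample(background, 30)
    res <- enrich(gl, coll, background)
    hits <- hits + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  mcse <- sqrt(0.05 * 0.95 / total)
  expect_lte(hits / total, 0.05 + 2 * mcse)
})

test_that("tightening any enrichment threshold never adds passing terms", {
  set.seed(73)
  background <- sprintf("g%04d", 1:300)
  coll <- lapply(1:15, function(i) sample(background, sample(10:60, 1)))
  names(coll) <- sprintf("t%02d", 1:15)
  gl <- unique(c(coll[[1]][1:8], sample(background, 25)))
  base <- enrich(gl, coll, background,
                 enrichment_thresholds(p = 0.2, min_count = 1, min_ef = 0.5))
  for (th in list(enrichment_thresholds(p = 0.05, min_count = 1,
                                        min_ef = 0.5),
                  enrichment_thresholds(p = 0.2, min_count = 3,
                                        min_ef = 0.5),
                  enrichment_thresholds(p = 0.2, min_count = 1,
                                        min_ef = 1.5))) {
    tight <- enrich(gl, coll, background, th)
    expect_true(all(tight$term_id[tight$passes] %in%
                      base$term_id[base$passes]))
  }
})

test_that("kappa similarity matches the closed form and drives term edges", {
  bg <- sprintf("g%03d", 1:100)
  expect_lte(kappa_similarity(bg[1:20], bg[21:40], bg), 0)
  expect_equal(kappa_similarity(bg[1:20], bg[1:20], bg), 1)

  # hand-worked 2x2: |A|=30, |B|=40, overlap 25
  a <- bg[1:30]; b <- bg[6:45]
  po <- (25 + 55) / 100
  pe <- 0.3 * 0.4 + 0.7 * 0.6
  expect_equal(kappa_similarity(a, b, bg), (po - pe) / (1 - pe))

  enr <- data.frame(term_id = c("A", "B", "C"), count = 5L, list_size = 10L,
                    term_size = 20L, background_size = 100L,
                    enrichment_factor = 3, p_value = 1e-4,
                    p_adjusted = 1e-3, passes = TRUE,
                    stringsAsFactors = FALSE)
  coll <- list(A = a, B = b, C = bg[61:80])
  g <- term_similarity_network(enr, coll, bg, kappa_threshold = 0.3)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)   # only A-B are similar enough
  ep <- igraph::ends(g, igraph::E(g))
  expect_setequal(as.vector(ep), c("A", "B"))
})

test_that("multi-list enrichment produces one table per list and a -log10 P
           heatmap over union passing terms", {
  set.seed(79)
  background <- sprintf("g%04d", 1:200)
  coll <- list(T1 = background[1:12], T2 = background[100:140])
  lists <- list(ctrl = background[1:10], surg = background[100:130])
  out <- enrich_lists(lists, coll, background)
  expect_named(out$results, c("ctrl", "surg"))
  expect_true(all(rownames(out$heatmap) %in% names(coll)))
  expect_equal(colnames(out$heatmap), c("ctrl", "surg"))
  r <- out$results$ctrl
  expect_equal(unname(out$heatmap["T1", "ctrl"]),
               -log10(r$p_value[r$term_id == "T1"]))
})

test_that("GMT files parse into named member sets", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst term\tg1\tg2\tg3",
               "T2\tsecond term\tg2\tg4"), p)
  sets <- read_gmt(p)
  expect_named(sets, c("T1", "T2"))
  expect_setequal(sets$T1, c("g1", "g2", "g3"))
  expect_setequal(sets$T2, c("g2", "g4"))
})
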