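# minimal DE table in the shape call_de() produces
fake_de <- function(ids, l2fc, p = 1e-4, pass = TRUE) {
  data.frame(feature_id = ids, mean_expr_a = 1, mean_expr_b = 2,
             log2_fold_change = l2fc, p_value = p, p_adjusted = p,
             direction = ifelse(l2fc > 0, "up", "down"),
             passes_filter = pass, stringsAsFactors = FALSE)
}

fake_sites <- function(target_ids, mir_ids, starts = 0L) {
  n <- length(target_ids)
  starts <- rep_len(starts, n)
  data.frame(mir_id = mir_ids, target_id = target_ids, start = starts,
             end = starts + 7L, site_type = rep("7mer-m8", n),
             spans_junction = rep(FALSE, n), stringsAsFactors = FALSE)
}

test_that("candidate pairs require DE membership plus site evidence", {
  de_c <- fake_de(c("c1", "c2"), c(2, -1.5))
  de_m <- fake_de(c("m1", "m2"), c(-2, 1.2))
  de_g <- fake_de("g1", 1.8)
  sites_c <- rbind(fake_sites("c1", "m1", 0L), fake_sites("c1", "m1", 30L),
                   fake_sites("c3", "m1", 5L))   # c3 is not DE
  sites_g <- fake_sites("g1", "m1", 12L)
  pairs <- candidate_pairs(de_c, de_m, de_g, sites_c, sites_g)
  expect_equal(pairs$circ_mir$circ_id, "c1")
  expect_equal(pairs$circ_mir$n_sites, 2L)  # distinct starts
  expect_equal(pairs$mir_mrna$mrna_id, "g1")

  # no sites anywhere -> both lists empty
  none <- candidate_pairs(de_c, de_m, de_g, fake_sites(character(0),
                          character(0), integer(0)),
                          fake_sites(character(0), character(0), integer(0)))
  expect_equal(nrow(none$circ_mir), 0L)
  expect_equal(nrow(none$mir_mrna), 0L)
})

test_that("the direction constraint drops same-direction pairs only when
           enabled", {
  de_c <- fake_de("c1", -2)          # down
  de_m <- fake_de("m1", -1.5)        # down too
  de_g <- fake_de("g1", 1.8)
  sites_c <- fake_sites("c1", "m1")
  sites_g <- fake_sites("g1", "m1")
  off <- candidate_pairs(de_c, de_m, de_g, sites_c, sites_g,
                         direction_constraint = FALSE)
  on <- candidate_pairs(de_c, de_m, de_g, sites_c, sites_g,
                        direction_constraint = TRUE)
  expect_equal(nrow(off$circ_mir), 1L)   # default keeps the pair
  expect_equal(nrow(on$circ_mir), 0L)    # constraint removes it
  expect_equal(nrow(on$mir_mrna), 1L)    # opposite directions survive
})

test_that("shared miRNAs equal the brute-force set intersection", {
  set.seed(19)
  for (i in 1:50) {
    cm <- data.frame(circ_id = "c", mir_id = sample(letters[1:8], 5, TRUE),
                     n_sites = 1L)
    gm <- data.frame(mir_id = sample(letters[1:8], 5, TRUE), mrna_id = "g",
                     n_sites = 1L)
    expect_equal(shared_mirnas(list(circ_mir = cm, mir_mrna = gm)),
                 sort(intersect(unique(cm$mir_id), unique(gm$mir_id))))
  }
  empty <- list(circ_mir = data.frame(circ_id = "c", mir_id = "a",
                                      n_sites = 1L),
                mir_mrna = data.frame(mir_id = "b", mrna_id = "g",
                                      n_sites = 1L))
  expect_length(shared_mirnas(empty), 0)
})

test_that("the sensitivity correlation obeys its closed form and limits", {
  # no miRNA involvement -> no sensitivity
  for (cxy in c(-0.5, 0, 0.4, 0.9))
    expect_equal(relationship_S(cxy, 0, 0), 0)
  # worked example
  expect_equal(relationship_S(0.9, -0.8, -0.8), 0.9 - (0.9 - 0.64) / 0.36)
  expect_equal(relationship_S(0.9, -0.8, -0.8), 0.1778, tolerance = 1e-3)
  expect_error(relationship_S(0.5, 1, 0.2), "undefined")
  # Pearson sanity on a hand-computable vector pair
  expect_equal(cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
})

test_that("S equals the regression-residual oracle on random triplets", {
  set.seed(29)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    m <- rnorm(n)
    x <- -0.7 * m + rnorm(n)
    y <- -0.7 * m + rnorm(n)
    S <- relationship_S(cor(x, y), cor(x, m), cor(y, m))
    expect_equal(S, oracle_S_residual(x, y, m), tolerance = 1e-10)
  }
})

test_that("triplet scoring flags validity and assembly keeps only valid
           triplets", {
  set.seed(41)
  samples <- sprintf("s%d", 1:6)
  mk_expr <- function(ids, vals) {
    m <- matrix(vals, length(ids), 6, byrow = TRUE,
                dimnames = list(ids, samples))
    expression_matrix(m, unit = "SRPBM")
  }
  shared <- c(1, 3, 9, 27, 81, 243)  # strong common signal
  expr <- list(circ = mk_expr("c1", shared * 2),
               mir = mk_expr("m1", rev(shared)),
               mrna = mk_expr("g1", shared * 5))
  pairs <- list(circ_mir = data.frame(circ_id = "c1", mir_id = "m1",
                                      n_sites = 2L),
                mir_mrna = data.frame(mir_id = "m1", mrna_id = "g1",
                                      n_sites = 1L))
  tr <- score_triplets(pairs, expr, samples)
  expect_equal(nrow(tr), 1L)
  expect_gt(tr$cor_xy, 0.99)

  tr$valid <- TRUE
  net <- assemble_network(tr)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$edge_type, c("circRNA-miRNA", "miRNA-mRNA"))

  tr$valid <- FALSE
  empty <- assemble_network(tr)
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("raising triplet thresholds never adds triplets and the network's
           miRNA set matches the valid shared set", {
  set.seed(53)
  samples <- sprintf("s%d", 1:6)
  ids_c <- sprintf("c%d", 1:4); ids_m <- sprintf("m%d", 1:3)
  ids_g <- sprintf("g%d", 1:5)
  expr <- list(
    circ = expression_matrix(matrix(rlnorm(24, 3), 4, 6,
             dimnames = list(ids_c, samples)), unit = "SRPBM"),
    mir = expression_matrix(matrix(rlnorm(18, 3), 3, 6,
             dimnames = list(ids_m, samples)), unit = "TPM"),
    mrna = expression_matrix(matrix(rlnorm(30, 3), 5, 6,
             dimnames = list(ids_g, samples)), unit = "FPKM"))
  pairs <- list(
    circ_mir = data.frame(circ_id = rep(ids_c, each = 3),
                          mir_id = rep(ids_m, 4), n_sites = 1L),
    mir_mrna = data.frame(mir_id = rep(ids_m, each = 5),
                          mrna_id = rep(ids_g, 3), n_sites = 1L))
  loose <- score_triplets(pairs, expr, samples,
                          triplet_thresholds(cor = -1, s = -2))
  for (ct in c(-0.5, 0, 0.5)) {
    for (st in c(-1, 0, 0.2)) {
      tight <- score_triplets(pairs, expr, samples,
                              triplet_thresholds(cor = ct, s = st))
      expect_lte(sum(tight$valid), sum(loose$valid))
      expect_true(all(tight$cor_xy[tight$valid] >= ct))
      expect_true(all(tight$S[tight$valid] >= st))
      net <- assemble_network(tight)
      expect_setequal(net$nodes$id[net$nodes$class == "miRNA"],
                      unique(tight$mir_id[tight$valid]))
    }
  }
})

test_that("GraphML export round-trips node classes and edge attributes", {
  tr <- data.frame(circ_id = "c1", mir_id = "m1", mrna_id = "g1",
                   cor_xy = 0.9, cor_cm = -0.8, cor_tm = -0.8, S = 0.4,
                   n_sites_circ = 2L, n_sites_mrna = 1L, valid = TRUE,
                   stringsAsFactors = FALSE)
  de <- list(circ = fake_de("c1", 2), mir = fake_de("m1", -2),
             mrna = fake_de("g1", 1.5))
  net <- assemble_network(tr, de = de)
  expect_equal(net$nodes$direction[net$nodes$id == "m1"], "down")
  p <- tempfile(fileext = ".graphml")
  write_network_graphml(net, p)
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$class, c("circRNA", "miRNA", "mRNA"))
})
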