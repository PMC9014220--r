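#' One seeded end-to-end inference on synthetic data
#'
#' Generates sequences and counts, runs DE per class for one comparison,
#' scans seed sites restricted to the DE sets, scores triplets and
#' assembles the network. The workhorse behind the recovery and null
#' experiments.
#'
#' @param rng_seed integer seed (sequences use it; counts use `seed + 1e6`).
#' @param condition which comparison to run (default `"control"`).
#' @param n_circ,n_mir,n_mrna,n_planted universe sizes
#'   ([generate_sequences()] defaults).
#' @param baseline_mean,dispersion,latent_sigma noise parameters
#'   ([simulate_counts()] defaults).
#' @param de,triplet threshold lists.
#' @param rules seed-matching rules.
#' @return list with `network`, `truth`, `de`, `triplets`.
#' @export
infer_synthetic_network <- function(rng_seed,
                                    condition = "control",
                                    n_circ = 100L, n_mir = 50L,
                                    n_mrna = 200L, n_planted = 5L,
                                    baseline_mean = 500, dispersion = 0.1,
                                    latent_sigma = 0.5,
                                    de = de_thresholds(),
                                    triplet = triplet_thresholds(),
                                    rules = site_rules()) {
  gs <- generate_sequences(n_circ, n_mir, n_mrna, n_planted,
                           rng_seed = rng_seed)
  design <- study_design()
  counts <- simulate_counts(design, gs$truth, baseline_mean = baseline_mean,
                            dispersion = dispersion,
                            rng_seed = rng_seed + 1000000L,
                            latent_sigma = latent_sigma)
  expr <- lapply(stats::setNames(nm = c("circ", "mir", "mrna")),
                 function(cls) normalize_class(counts[[cls]], cls))
  cmp <- comparison_samples(design, condition)
  de_tabs <- lapply(stats::setNames(nm = c("circ", "mir", "mrna")),
                    function(cls)
    call_de(subset_expression(expr[[cls]], cmp$a),
            subset_expression(expr[[cls]], cmp$b),
            subset_counts(counts[[cls]], cmp$a),
            subset_counts(counts[[cls]], cmp$b), thresholds = de))
  ids <- function(d) d$feature_id[d$passes_filter]
  sites_circ <- find_sites(gs$sequences$circ[ids(de_tabs$circ)],
                           gs$sequences$mir[ids(de_tabs$mir)],
                           circular = TRUE, rules = rules)
  sites_mrna <- find_sites(gs$sequences$mrna[ids(de_tabs$mrna)],
                           gs$sequences$mir[ids(de_tabs$mir)],
                           circular = FALSE, rules = rules)
  pairs <- candidate_pairs(de_tabs$circ, de_tabs$mir, de_tabs$mrna,
                           sites_circ, sites_mrna)
  triplets <- score_triplets(pairs, expr, c(cmp$a, cmp$b),
                             thresholds = triplet)
  list(network = assemble_network(triplets, de = de_tabs),
       truth = gs$truth, de = de_tabs, triplets = triplets)
}

#' Planted-edge recovery across seeds
#'
#' Runs [infer_synthetic_network()] for each seed and scores the assembled
#' network's edge set against the planted triplets.
#'
#' @param seeds integer vector of seeds.
#' @param ... passed to [infer_synthetic_network()].
#' @return data.frame with one row per seed: precision, recall, f1 and the
#'   edge counts.
#' @export
recovery_experiment <- function(seeds, ...) {
  rows <- lapply(seeds, function(s) {
    res <- suppressMessages(infer_synthetic_network(rng_seed = s, ...))
    sc <- edge_recovery(res$network, res$truth)
    data.frame(seed = s, tp = sc$tp, n_found = sc$n_found,
               n_truth = sc$n_truth, precision = sc$precision,
               recall = sc$recall, f1 = sc$f1)
  })
  do.call(rbind, rows)
}

#' Empty-network rate with nothing planted
#'
#' With no planted triplets the generator guarantees a site-free universe,
#' so any non-empty network is downstream leakage (spurious DE features can
#' never be linked without sites). Returns the fraction of seeds yielding an
#' empty network.
#'
#' @param seeds integer vector of seeds.
#' @param n_circ,n_mir,n_mrna universe sizes (smaller than the recovery
#'   default: the property is threshold leakage, not composition).
#' @param ... passed to [infer_synthetic_network()].
#' @export
null_leakage_experiment <- function(seeds, n_circ = 30L, n_mir = 20L,
                                    n_mrna = 60L, ...) {
  empty <- vapply(seeds, function(s) {
    res <- suppressMessages(suppressWarnings(
      infer_synthetic_network(rng_seed = s, n_planted = 0L,
                              n_circ = n_circ, n_mir = n_mir,
                              n_mrna = n_mrna, ...)))
    nrow(res$network$nodes) == 0L
  }, logical(1))
  data.frame(seed = seeds, empty = empty)
}

#' Null rejection rate of the pooled-count Fisher test
#'
#' Simulates features with identical NB distributions in both groups (no
#' planted effects), pools the replicates per group and applies
#' [fisher_feature_test()] per feature against the class library sizes.
#' Returns, per seed, the fraction of features with raw `P <= p_cut` and
#' the fraction passing the full DE filter (`|log2FC| >= 1` as well).
#' Because pooling models counting noise only, biological overdispersion
#' (`dispersion > 0`) inflates the raw-P rejection rate far above the
#' nominal level; the fold-change filter absorbs most of it.
#'
#' @param seeds integer vector of seeds.
#' @param n_features features per seed (default 2000).
#' @param baseline_mean,dispersion NB parameters (defaults 500, 0.1).
#' @param p_cut nominal criterion (default 0.05).
#' @export
fisher_null_experiment <- function(seeds, n_features = 2000L,
                                   baseline_mean = 500, dispersion = 0.1,
                                   p_cut = 0.05) {
  ids <- sprintf("f%05d", seq_len(n_features))
  design <- study_design()
  cmp <- comparison_samples(design, "control")
  rows <- lapply(seeds, function(s) {
    truth <- structure(list(
      triplets = planted_scenario(0),
      de_features = list(circ = data.frame(feature_id = character(0),
                                           log2fc = numeric(0)),
                         mir = data.frame(feature_id = character(0),
                                          log2fc = numeric(0)),
                         mrna = data.frame(feature_id = character(0),
                                           log2fc = numeric(0))),
      feature_ids = list(circ = ids, mir = "m1", mrna = "g1"),
      rng_seed = s), class = "SyntheticTruth")
    counts <- simulate_counts(design, truth, baseline_mean = baseline_mean,
                              dispersion = dispersion, rng_seed = s)
    cc <- counts$circ
    ca <- rowSums(cc$counts[, cmp$a, drop = FALSE])
    cb <- rowSums(cc$counts[, cmp$b, drop = FALSE])
    p <- fisher_feature_test(ca, cb, sum(cc$library_size[cmp$a]),
                             sum(cc$library_size[cmp$b]))
    l2fc <- log2fc(rowMeans(cc$counts[, cmp$a, drop = FALSE]),
                   rowMeans(cc$counts[, cmp$b, drop = FALSE]))
    data.frame(seed = s, n = n_features,
               rate_raw_p = mean(p <= p_cut),
               rate_filtered = mean(p <= p_cut & abs(l2fc) >= 1))
  })
  do.call(rbind, rows)
}
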