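# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# two-sided Fisher P by exhaustive enumeration over all tables with the
# observed margins (point-probability summation)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  supp <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(supp, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by hand: sort, running minimum of p * m / rank from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj_sorted)[order(o)]
}

# all 0-based starts of an exact substring, by direct comparison
oracle_substring_starts <- function(target, core) {
  L <- nchar(target)
  k <- nchar(core)
  if (L < k) return(integer(0))
  starts <- 0:(L - k)
  starts[vapply(starts, function(s)
    substr(target, s + 1, s + k) == core, logical(1))]
}

# circular matching by enumerating every rotation and mapping hits back to
# canonical coordinates, deduplicated modulo the circle length
oracle_rotation_starts <- function(circ, core) {
  L <- nchar(circ)
  hits <- integer(0)
  for (r in 0:(L - 1)) {
    rot <- paste0(substr(circ, r + 1, L), substr(circ, 1, r))
    hits <- c(hits, (oracle_substring_starts(rot, core) + r) %% L)
  }
  sort(unique(hits))
}

# sensitivity correlation via regression residuals: raw correlation minus
# the correlation of the residuals of x ~ m and y ~ m
oracle_S_residual <- function(x, y, m) {
  rx <- stats::resid(stats::lm(x ~ m))
  ry <- stats::resid(stats::lm(y ~ m))
  stats::cor(x, y) - stats::cor(rx, ry)
}

# upper-tail hypergeometric by summing point masses
oracle_hypergeom <- function(count, list_size, term_size, background_size) {
  supp <- count:min(list_size, term_size)
  sum(stats::dhyper(supp, term_size, background_size - term_size, list_size))
}

# random RNA string
rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# a hand-built SyntheticTruth with arbitrary DE features and no planted
# triplets (for count-simulation tests that do not need sequences)
make_truth <- function(circ_ids, mir_ids, mrna_ids,
                       de_circ = NULL, de_mir = NULL, de_mrna = NULL,
                       triplets = planted_scenario(0), rng_seed = 1L) {
  de0 <- data.frame(feature_id = character(0), log2fc = numeric(0),
                    stringsAsFactors = FALSE)
  structure(list(
    triplets = triplets,
    de_features = list(circ = if (is.null(de_circ)) de0 else de_circ,
                       mir = if (is.null(de_mir)) de0 else de_mir,
                       mrna = if (is.null(de_mrna)) de0 else de_mrna),
    feature_ids = list(circ = circ_ids, mir = mir_ids, mrna = mrna_ids),
    rng_seed = rng_seed), class = "SyntheticTruth")
}
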