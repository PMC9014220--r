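#' The 2x2 study design
#'
#' Two ages (young, aging) crossed with two conditions (control, surgery),
#' with a fixed number of replicates per cell. Sample ids follow
#' `<age>_<condition>_<rep>`. Each differential-expression comparison slices
#' out the two age groups within one condition, giving `2 * replicates`
#' samples per comparison (6 under the default of 3 replicates, the minimum
#' at which sample correlations start to be meaningful).
#'
#' @param replicates_per_group replicates per design cell (default 3,
#'   minimum 2).
#' @return a `StudyDesign` data.frame with columns `sample_id`, `age`,
#'   `condition`, `rep`.
#' @export
study_design <- function(replicates_per_group = 3L) {
  replicates_per_group <- as.integer(replicates_per_group)
  if (is.na(replicates_per_group) || replicates_per_group < 2L)
    stop("replicates_per_group must be an integer >= 2")
  grid <- expand.grid(rep = seq_len(replicates_per_group),
                      condition = c("control", "surgery"),
                      age = c("young", "aging"),
                      stringsAsFactors = FALSE)
  out <- data.frame(
    sample_id = sprintf("%s_%s_%d", grid$age, grid$condition, grid$rep),
    age = grid$age, condition = grid$condition, rep = grid$rep,
    stringsAsFactors = FALSE)
  class(out) <- c("StudyDesign", "data.frame")
  out
}

#' Default planted sponge-triplet scenario
#'
#' Each planted triplet couples one circRNA, one miRNA and one mRNA: the
#' circRNA and mRNA are up-regulated in aging samples while the shared miRNA
#' is down-regulated (sponge derepression), and the circRNA carries two seed
#' sites for the miRNA (one spanning the back-splice junction) while the
#' mRNA 3'UTR carries one.
#'
#' @param n_planted number of triplets.
#' @param effect_log2fc absolute log2 fold change of the planted age effect
#'   (applied +/+ to circRNA/mRNA and - to the miRNA).
#' @param site_count_circ,site_count_mrna seed sites embedded per target.
#' @param junction_spanning embed one circRNA site across the back-splice
#'   junction?
#' @return data.frame with one row per triplet (ids filled in by
#'   [generate_sequences()]).
#' @export
planted_scenario <- function(n_planted, effect_log2fc = 2,
                             site_count_circ = 2L, site_count_mrna = 1L,
                             junction_spanning = TRUE) {
  if (n_planted == 0L) {
    return(data.frame(circ_id = character(0), mir_id = character(0),
                      mrna_id = character(0), effect_log2fc_circ = numeric(0),
                      effect_log2fc_mir = numeric(0),
                      effect_log2fc_mrna = numeric(0),
                      site_count_circ = integer(0),
                      site_count_mrna = integer(0),
                      junction_spanning = logical(0)))
  }
  data.frame(circ_id = NA_character_, mir_id = NA_character_,
             mrna_id = NA_character_,
             effect_log2fc_circ = rep(abs(effect_log2fc), n_planted),
             effect_log2fc_mir = rep(-abs(effect_log2fc), n_planted),
             effect_log2fc_mrna = rep(abs(effect_log2fc), n_planted),
             site_count_circ = rep(as.integer(site_count_circ), n_planted),
             site_count_mrna = rep(as.integer(site_count_mrna), n_planted),
             junction_spanning = rep(isTRUE(junction_spanning), n_planted),
             stringsAsFactors = FALSE)
}

.rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# does `seq` contain a core match for any seed in `cores`?
# (presence only, so a plain fixed-string scan is enough)
.has_any_site <- function(seq, cores, circular) {
  subject <- if (circular) paste0(seq, seq) else seq
  any(vapply(cores, grepl, logical(1), x = subject, fixed = TRUE))
}

# sample a sequence free of all seed cores, bounded attempts
.clean_sequence <- function(len, cores, circular, max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    s <- .rand_rna(len)
    if (!.has_any_site(s, cores, circular)) return(s)
  }
  stop(sprintf(
    "could not sample a seed-free sequence of length %d in %d attempts",
    len, max_attempts))
}

# overwrite `core` into `seq` at 0-based start, wrapping modulo length
.embed_at <- function(seq, core, start0) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  cc <- strsplit(core, "")[[1]]
  idx <- ((start0 + seq_along(cc) - 1L) %% L) + 1L
  chars[idx] <- cc
  paste(chars, collapse = "")
}

# embed `n` non-overlapping copies of core into a clean sequence; one copy
# wraps the junction when `junction` is TRUE. Verifies that afterwards the
# target carries sites for exactly the intended miRNA, at exactly `n`
# distinct starts; resamples otherwise.
.planted_target <- function(len, core, n, junction, all_cores, circular,
                            max_attempts = 1000L) {
  k <- nchar(core)
  if (junction && !circular) stop("junction-spanning sites need a circle")
  if (len < (n + 1L) * k)
    stop(sprintf("sequence of length %d too short for %d seed sites", len, n))
  for (attempt in seq_len(max_attempts)) {
    s <- .clean_sequence(len, all_cores, circular, max_attempts)
    starts <- integer(0)
    if (junction) starts <- len - sample.int(k - 1L, 1L)  # wraps the joint
    # non-wrapping slots, kept clear of each other and of the wrapped copy
    need <- n - length(starts)
    if (need > 0) {
      avail <- 0:(len - k)
      if (length(starts)) {
        wrap_end <- starts[1] + k - len  # first position past the wrapped tail
        avail <- avail[avail >= wrap_end & avail + k <= starts[1]]
      }
      if (length(avail) < need)
        stop(sprintf("sequence of length %d too short for %d seed sites",
                     len, n))
      repeat {
        cand <- sort(avail[sample.int(length(avail), need)])
        if (need == 1 || all(diff(cand) >= k)) break
      }
      starts <- c(starts, cand)
    }
    for (st in starts) s <- .embed_at(s, core, st)
    # verify: intended core found at exactly n distinct starts, no other core
    subject <- if (circular) paste0(s, s) else s
    hits <- .match_starts(core, subject)
    if (circular) hits <- unique((hits - 1L) %% len)
    n_found <- length(unique(hits))
    others <- setdiff(all_cores, core)
    if (n_found == n && !.has_any_site(s, others, circular)) return(s)
  }
  stop("could not embed the requested seed sites cleanly")
}

#' Generate synthetic sequence sets with planted sponge triplets
#'
#' Produces mature miRNA sequences, circRNA back-splice-joined sequences and
#' mRNA 3'UTRs such that (i) every planted triplet's circRNA and mRNA carry
#' the requested number of seed-match sites (reverse complement of miRNA
#' positions 2-8) for the triplet's miRNA — with one circRNA site spanning
#' the back-splice junction when requested — and (ii) every non-planted
#' sequence carries no seed site for any generated miRNA (rejection-sampled,
#' bounded attempts). All miRNA seeds are pairwise distinct.
#'
#' @param n_circ,n_mir,n_mrna features per class.
#' @param n_planted number of planted triplets (uses [planted_scenario()]
#'   defaults), or a scenario data.frame.
#' @param rng_seed integer seed; identical seeds give identical output.
#' @param circ_len,utr_len,mir_len_range sequence lengths (nt).
#' @return list with `sequences` (named character vectors `circ`, `mir`,
#'   `mrna`) and `truth`, a `SyntheticTruth` list holding the planted
#'   triplet table, per-class truly-DE feature tables and the seed.
#' @export
generate_sequences <- function(n_circ = 100L, n_mir = 50L, n_mrna = 200L,
                               n_planted = 5L, rng_seed = 1L,
                               circ_len = 400L, utr_len = 800L,
                               mir_len_range = c(20L, 24L)) {
  scenario <- if (is.data.frame(n_planted)) n_planted
              else planted_scenario(n_planted)
  np <- nrow(scenario)
  if (np > min(n_circ, n_mir, n_mrna))
    stop("n_planted exceeds the smallest class size")
  stopifnot(all(scenario$site_count_circ >= 1L),
            all(scenario$site_count_mrna >= 1L))
  set.seed(rng_seed)

  circ_ids <- sprintf("circ_%04d", seq_len(n_circ))
  mir_ids <- sprintf("mir_%04d", seq_len(n_mir))
  mrna_ids <- sprintf("mrna_%04d", seq_len(n_mrna))

  # miRNAs first, with pairwise-distinct 7mer seeds
  mirs <- character(n_mir)
  seeds <- character(0)
  for (i in seq_len(n_mir)) {
    repeat {
      m <- .rand_rna(sample(seq(mir_len_range[1], mir_len_range[2]), 1L))
      sd7 <- seed_of(m)
      if (!sd7 %in% seeds) break
    }
    mirs[i] <- m
    seeds <- c(seeds, seed_of(m))
  }
  names(mirs) <- mir_ids
  cores <- vapply(mirs, function(m) .rna_rc(seed_of(m)), character(1))

  scenario$circ_id <- circ_ids[seq_len(np)]
  scenario$mir_id <- mir_ids[seq_len(np)]
  scenario$mrna_id <- mrna_ids[seq_len(np)]

  circs <- stats::setNames(character(n_circ), circ_ids)
  mrnas <- stats::setNames(character(n_mrna), mrna_ids)
  for (i in seq_len(n_circ)) {
    j <- match(circ_ids[i], scenario$circ_id)
    circs[i] <- if (!is.na(j)) {
      .planted_target(circ_len, cores[[scenario$mir_id[j]]],
                      scenario$site_count_circ[j],
                      scenario$junction_spanning[j], cores, circular = TRUE)
    } else .clean_sequence(circ_len, cores, circular = TRUE)
  }
  for (i in seq_len(n_mrna)) {
    j <- match(mrna_ids[i], scenario$mrna_id)
    mrnas[i] <- if (!is.na(j)) {
      .planted_target(utr_len, cores[[scenario$mir_id[j]]],
                      scenario$site_count_mrna[j], junction = FALSE,
                      cores, circular = FALSE)
    } else .clean_sequence(utr_len, cores, circular = FALSE)
  }

  de <- function(ids, l2fc) data.frame(feature_id = ids, log2fc = l2fc,
                                       stringsAsFactors = FALSE)
  truth <- list(
    triplets = scenario,
    de_features = list(circ = de(scenario$circ_id, scenario$effect_log2fc_circ),
                       mir = de(scenario$mir_id, scenario$effect_log2fc_mir),
                       mrna = de(scenario$mrna_id, scenario$effect_log2fc_mrna)),
    feature_ids = list(circ = circ_ids, mir = mir_ids, mrna = mrna_ids),
    rng_seed = rng_seed)
  class(truth) <- "SyntheticTruth"
  list(sequences = list(circ = circs, mir = mirs, mrna = mrnas),
       truth = truth)
}

#' Simulate NB count matrices for the 2x2 design
#'
#' Counts are negative binomial with `variance = mean + dispersion * mean^2`
#' (`dispersion = 0` degenerates to Poisson). Every feature shares
#' `baseline_mean`; truly-DE features (the planted triplets plus any extra
#' DE features in the truth ledger) have their mean multiplied by
#' `2^log2fc` in aging samples, under both conditions. For each planted
#' triplet a per-sample latent miRNA-activity factor
#' `a ~ LogNormal(0, latent_sigma)` multiplies the circRNA and mRNA means
#' and divides the miRNA mean, inducing the positive circ-mRNA and negative
#' miR-target correlations that the ceRNA inference step looks for.
#' Library sizes are the per-class column sums.
#'
#' @param design a [study_design()].
#' @param truth `SyntheticTruth` from [generate_sequences()].
#' @param baseline_mean expected count of a non-DE feature (default 500).
#' @param dispersion NB dispersion (default 0.1, a typical bulk RNA-seq
#'   biological coefficient of variation of ~0.32).
#' @param rng_seed integer seed.
#' @param latent_sigma log-scale SD of the shared miRNA-activity factor
#'   (default 0.5, the strong-coupling scenario: population circRNA-mRNA
#'   correlation ~0.87 while observed fold changes stay near the planted
#'   effect).
#' @param mrna_length_bp exon-model length attached to every synthetic mRNA
#'   so FPKM is defined (a constant: synthetic UTRs carry no isoform
#'   structure).
#' @return named list of [count_matrix()] objects (`circ`, `mir`, `mrna`).
#' @export
simulate_counts <- function(design, truth, baseline_mean = 500,
                            dispersion = 0.1, rng_seed = 1L,
                            latent_sigma = 0.5, mrna_length_bp = 2000L) {
  stopifnot(inherits(design, "StudyDesign"), inherits(truth, "SyntheticTruth"))
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  set.seed(rng_seed)
  ns <- nrow(design)
  aging <- design$age == "aging"

  rnb <- function(mu) {
    if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }

  # per-feature x sample mean matrices
  mean_mat <- function(ids, de_tab) {
    mu <- matrix(baseline_mean, length(ids), ns,
                 dimnames = list(ids, design$sample_id))
    hit <- match(de_tab$feature_id, ids)
    for (k in seq_along(hit)) {
      mu[hit[k], aging] <- mu[hit[k], aging] * 2^de_tab$log2fc[k]
    }
    mu
  }
  mus <- list(circ = mean_mat(truth$feature_ids$circ, truth$de_features$circ),
              mir = mean_mat(truth$feature_ids$mir, truth$de_features$mir),
              mrna = mean_mat(truth$feature_ids$mrna, truth$de_features$mrna))

  # latent sponge coupling, one factor per (triplet, sample)
  tr <- truth$triplets
  for (k in seq_len(nrow(tr))) {
    a <- stats::rlnorm(ns, meanlog = 0, sdlog = latent_sigma)
    mus$circ[tr$circ_id[k], ] <- mus$circ[tr$circ_id[k], ] * a
    mus$mrna[tr$mrna_id[k], ] <- mus$mrna[tr$mrna_id[k], ] * a
    mus$mir[tr$mir_id[k], ] <- mus$mir[tr$mir_id[k], ] / a
  }

  out <- lapply(mus, function(mu) {
    cnt <- matrix(rnb(mu), nrow(mu), ncol(mu), dimnames = dimnames(mu))
    count_matrix(cnt)
  })
  # a flat exon-model length for synthetic mRNAs keeps FPKM well-defined
  out$mrna$feature_length <- stats::setNames(
    rep(as.numeric(mrna_length_bp), nrow(out$mrna$counts)),
    rownames(out$mrna$counts))
  out
}

#' Serialise / reload the synthetic ground truth
#'
#' The truth ledger (planted triplets, per-class DE features, feature ids,
#' seed) round-trips through JSON without loss so recovery experiments can
#' reload it.
#'
#' @param truth a `SyntheticTruth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$triplets <- as.data.frame(x$triplets, stringsAsFactors = FALSE)
  x$de_features <- lapply(x$de_features, function(d)
    as.data.frame(d, stringsAsFactors = FALSE))
  class(x) <- "SyntheticTruth"
  x
}

#' Write sequence sets as FASTA
#'
#' One file per RNA class; circRNA records carry `circular=true` in the
#' description so that downstream scanning picks the circular matcher.
#'
#' @param sequences named character vector of RNA sequences.
#' @param path output FASTA.
#' @param circular mark records as circular?
#' @export
write_fasta <- function(sequences, path, circular = FALSE) {
  x <- Biostrings::RNAStringSet(sequences)
  if (circular) names(x) <- paste(names(sequences), "circular=true")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @return `read_fasta`: named character vector; the `circular` attribute
#'   records whether records were flagged circular.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  circ <- grepl("circular=true", names(x))
  names(x) <- sub("\\s.*$", "", names(x))
  out <- stats::setNames(as.character(x), names(x))
  attr(out, "circular") <- any(circ)
  out
}
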