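#' Configuration for an end-to-end run
#'
#' Collects every tunable of the pipeline: the synthetic scenario (feature
#' counts, planted triplets, NB noise, coupling strength), the DE / triplet /
#' enrichment thresholds, the seed-matching rule, the comparisons to run and
#' the RNG seed. A config round-trips through YAML unchanged, so the
#' manifest plus the config reproduce a run bit for bit.
#'
#' @param outdir run directory (created by [run_all()]).
#' @param rng_seed integer master seed.
#' @param n_circ,n_mir,n_mrna,n_planted synthetic universe sizes.
#' @param baseline_mean,dispersion,latent_sigma NB noise and sponge-coupling
#'   parameters (see [simulate_counts()]).
#' @param replicates_per_group design replicates (default 3).
#' @param de,triplet,enrich threshold lists ([de_thresholds()],
#'   [triplet_thresholds()], [enrichment_thresholds()]).
#' @param rules seed-matching rules ([site_rules()]).
#' @param direction_constraint require opposite DE directions within pairs?
#' @param comparisons conditions to compare aging vs young within.
#' @param gmt optional path to a GMT collection; enrichment runs only when
#'   given.
#' @export
run_config <- function(outdir,
                       rng_seed = 1L,
                       n_circ = 100L, n_mir = 50L, n_mrna = 200L,
                       n_planted = 5L,
                       baseline_mean = 500, dispersion = 0.1,
                       latent_sigma = 0.5,
                       replicates_per_group = 3L,
                       de = de_thresholds(),
                       triplet = triplet_thresholds(),
                       enrich = enrichment_thresholds(),
                       rules = site_rules(),
                       direction_constraint = FALSE,
                       comparisons = c("control", "surgery"),
                       gmt = NULL) {
  cfg <- list(outdir = outdir, rng_seed = as.integer(rng_seed),
              n_circ = as.integer(n_circ), n_mir = as.integer(n_mir),
              n_mrna = as.integer(n_mrna), n_planted = as.integer(n_planted),
              baseline_mean = baseline_mean, dispersion = dispersion,
              latent_sigma = latent_sigma,
              replicates_per_group = as.integer(replicates_per_group),
              de = de, triplet = triplet, enrich = enrich, rules = rules,
              direction_constraint = isTRUE(direction_constraint),
              comparisons = comparisons, gmt = gmt)
  validate_config(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname run_config
#' @param cfg a config list.
#' @export
validate_config <- function(cfg) {
  stopifnot(cfg$n_planted <= min(cfg$n_circ, cfg$n_mir, cfg$n_mrna),
            cfg$baseline_mean > 0, cfg$dispersion >= 0,
            cfg$replicates_per_group >= 2,
            all(cfg$comparisons %in% c("control", "surgery")),
            cfg$de$p >= 0, cfg$de$p <= 1, cfg$de$fold_change >= 1,
            cfg$triplet$cor >= -1, cfg$triplet$cor <= 1)
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
    stop("config error: GMT file not found: ", cfg$gmt)
  invisible(TRUE)
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis
#'
#' simulate -> quantify -> (per comparison) DE -> seed sites -> candidate
#' pairs -> triplet scoring -> network assembly -> optional enrichment.
#' Each stage writes its tables under the run directory (one flat
#' sub-directory per comparison for easy diffing between conditions), a
#' structured log line records every stage's input/output sizes, and a
#' `manifest.json` captures versions, thresholds, seed, stage counts and
#' input checksums. A stage failure aborts with a stage-named error;
#' earlier outputs are retained.
#'
#' @param config a [run_config()].
#' @return the run directory, invisibly; its `manifest.json` holds the
#'   per-stage counts.
#' @export
run_all <- function(config) {
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ceRNAnet")),
    r_version = R.version.string,
    rng_seed = config$rng_seed,
    thresholds = list(de = config$de, triplet = config$triplet,
                      enrich = config$enrich),
    stages = list())
  log_stage <- function(name, ...) {
    rec <- list(...)
    manifest$stages[[name]] <<- rec
    message(sprintf("[%s] %s", name,
                    paste(names(rec), unlist(rec), sep = "=",
                          collapse = " ")))
  }

  design <- study_design(config$replicates_per_group)

  sim <- .stage("simulate", {
    gs <- generate_sequences(config$n_circ, config$n_mir, config$n_mrna,
                             config$n_planted, rng_seed = config$rng_seed)
    counts <- simulate_counts(design, gs$truth,
                              baseline_mean = config$baseline_mean,
                              dispersion = config$dispersion,
                              rng_seed = config$rng_seed + 1L,
                              latent_sigma = config$latent_sigma)
    write_fasta(gs$sequences$circ, file.path(config$outdir, "circ.fa"),
                circular = TRUE)
    write_fasta(gs$sequences$mir, file.path(config$outdir, "mir.fa"))
    write_fasta(gs$sequences$mrna, file.path(config$outdir, "mrna_utr.fa"))
    write_truth(gs$truth, file.path(config$outdir, "truth.json"))
    for (cls in names(counts))
      write_counts(counts[[cls]],
                   file.path(config$outdir, paste0("counts_", cls, ".tsv")))
    list(seqs = gs$sequences, truth = gs$truth, counts = counts)
  })
  log_stage("simulate", n_circ = config$n_circ, n_mir = config$n_mir,
            n_mrna = config$n_mrna, n_planted = config$n_planted)

  expr <- .stage("quantify", {
    lapply(stats::setNames(nm = c("circ", "mir", "mrna")), function(cls)
      normalize_class(sim$counts[[cls]], cls))
  })
  log_stage("quantify", units = paste(vapply(expr, `[[`, "", "unit"),
                                      collapse = ","))

  for (cond in config$comparisons) {
    cdir <- file.path(config$outdir, cond)
    dir.create(cdir, showWarnings = FALSE)
    cmp <- comparison_samples(design, cond)

    de <- .stage(paste0("de/", cond), {
      out <- lapply(stats::setNames(nm = c("circ", "mir", "mrna")),
                    function(cls) {
        d <- call_de(subset_expression(expr[[cls]], cmp$a),
                     subset_expression(expr[[cls]], cmp$b),
                     subset_counts(sim$counts[[cls]], cmp$a),
                     subset_counts(sim$counts[[cls]], cmp$b),
                     thresholds = config$de)
        write_de(d, file.path(cdir, paste0("de_", cls, ".tsv")))
        d
      })
      out
    })
    log_stage(paste0("de/", cond),
              de_circ = sum(de$circ$passes_filter),
              de_mir = sum(de$mir$passes_filter),
              de_mrna = sum(de$mrna$passes_filter))

    net <- .stage(paste0("network/", cond), {
      de_mir_ids <- de$mir$feature_id[de$mir$passes_filter]
      de_circ_ids <- de$circ$feature_id[de$circ$passes_filter]
      de_mrna_ids <- de$mrna$feature_id[de$mrna$passes_filter]
      sites_circ <- find_sites(sim$seqs$circ[de_circ_ids],
                               sim$seqs$mir[de_mir_ids],
                               circular = TRUE, rules = config$rules)
      sites_mrna <- find_sites(sim$seqs$mrna[de_mrna_ids],
                               sim$seqs$mir[de_mir_ids],
                               circular = FALSE, rules = config$rules)
      write_sites(rbind(sites_circ, sites_mrna),
                  file.path(cdir, "sites.tsv"))
      pairs <- candidate_pairs(de$circ, de$mir, de$mrna,
                               sites_circ, sites_mrna,
                               config$direction_constraint)
      triplets <- score_triplets(pairs, expr, c(cmp$a, cmp$b),
                                 thresholds = config$triplet)
      network <- assemble_network(triplets, de = de)
      write_network_tables(network,
                           edge_path = file.path(cdir, "edges.tsv"),
                           triplet_path = file.path(cdir, "triplets.tsv"))
      write_network_graphml(network, file.path(cdir, "network.graphml"))
      network
    })
    log_stage(paste0("network/", cond),
              nodes = nrow(net$nodes), edges = nrow(net$edges),
              triplets = nrow(net$triplets))

    if (!is.null(config$gmt)) {
      .stage(paste0("enrich/", cond), {
        terms <- read_gmt(config$gmt)
        genes <- net$nodes$id[net$nodes$class == "mRNA"]
        background <- rownames(sim$counts$mrna$counts)
        res <- enrich(genes, terms, background, thresholds = config$enrich)
        utils::write.table(res, file.path(cdir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage(paste0("enrich/", cond), terms = nrow(res),
                  passing = sum(res$passes))
        res
      })
    }
  }

  manifest$inputs <- as.list(tools::md5sum(
    list.files(config$outdir, pattern = "\\.(fa|tsv|json)$",
               full.names = TRUE)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$outdir)
}

#' Edge-recovery scores against a truth ledger
#'
#' Compares an assembled network's edge set with the edges implied by the
#' planted triplets (each triplet contributes one circRNA-miRNA and one
#' miRNA-mRNA edge) and returns precision, recall and F1.
#'
#' @param net a `CeRNANetwork`.
#' @param truth a `SyntheticTruth`.
#' @export
edge_recovery <- function(net, truth) {
  tr <- truth$triplets
  truth_edges <- unique(c(paste(tr$circ_id, tr$mir_id, sep = "~"),
                          paste(tr$mir_id, tr$mrna_id, sep = "~")))
  found_edges <- unique(paste(net$edges$source, net$edges$target,
                              sep = "~"))
  tp <- length(intersect(found_edges, truth_edges))
  precision <- if (length(found_edges)) tp / length(found_edges) else
    (if (length(truth_edges)) 0 else 1)
  recall <- if (length(truth_edges)) tp / length(truth_edges) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(tp = tp, n_found = length(found_edges),
       n_truth = length(truth_edges),
       precision = precision, recall = recall, f1 = f1)
}
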