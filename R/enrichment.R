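#' Thresholds for term enrichment
#'
#' A term is significant when raw hypergeometric `P < p`, the hit count
#' reaches `min_count` and the enrichment factor exceeds `min_ef`.
#'
#' @param p raw P cut-off (default 0.05, strict inequality).
#' @param min_count minimum genes from the list in the term (default 3).
#' @param min_ef minimum enrichment factor (default 1.5, strict inequality).
#' @export
enrichment_thresholds <- function(p = 0.05, min_count = 3L, min_ef = 1.5) {
  list(p = p, min_count = as.integer(min_count), min_ef = min_ef)
}

#' Upper-tail hypergeometric P
#'
#' `P(X >= count)` for `X ~ Hypergeom(term_size, background_size - term_size,
#' list_size)`: the chance of drawing at least `count` term members in a
#' random gene list of the same size.
#'
#' @param count observed hits (list and term overlap).
#' @param list_size genes in the query list.
#' @param term_size genes in the term.
#' @param background_size genes in the universe.
#' @export
hypergeom_p <- function(count, list_size, term_size, background_size) {
  if (any(count > list_size) || any(list_size > background_size) ||
      any(term_size > background_size) || any(count > term_size))
    stop("inconsistent sizes for the hypergeometric test")
  stats::phyper(count - 1, term_size, background_size - term_size,
                list_size, lower.tail = FALSE)
}

#' Enrichment factor
#'
#' Observed over expected hit rate:
#' `(count / list_size) / (term_size / background_size)`.
#'
#' @inheritParams hypergeom_p
#' @export
enrichment_factor <- function(count, list_size, term_size, background_size) {
  if (any(list_size == 0) || any(term_size == 0) || any(background_size == 0))
    stop("zero denominator in enrichment factor")
  (count / list_size) / (term_size / background_size)
}

#' Read a GMT term collection
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors of member genes; names are term
#'   ids, with descriptions in the `description` attribute.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
    desc <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- lapply(lines, function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(lines, `[`, character(1), 1L)
    desc <- stats::setNames(vapply(lines, `[`, character(1), 2L),
                            names(sets))
  }
  attr(sets, "description") <- desc
  sets
}

#' Hypergeometric term enrichment with the standard filters
#'
#' Every term in the collection is scored against the gene list over the
#' background universe; P values are BH-adjusted across the collection and
#' the pass flag applies the [enrichment_thresholds()]. Query genes absent
#' from the background are dropped (with a message); term membership is
#' intersected with the background.
#'
#' @param gene_list character vector of query genes.
#' @param term_collection named list of member-gene vectors (see
#'   [read_gmt()]).
#' @param background character vector: the gene universe (defaults in the
#'   pipeline to all quantified mRNAs).
#' @param thresholds an [enrichment_thresholds()] list.
#' @return data.frame sorted by (p_value, term_id): `term_id`, `count`,
#'   `list_size`, `term_size`, `background_size`, `enrichment_factor`,
#'   `p_value`, `p_adjusted`, `passes`.
#' @export
enrich <- function(gene_list, term_collection, background,
                   thresholds = enrichment_thresholds()) {
  background <- unique(background)
  gene_list <- unique(gene_list)
  absent <- setdiff(gene_list, background)
  if (length(absent)) {
    message(length(absent), " query gene(s) absent from the background, dropped")
    gene_list <- intersect(gene_list, background)
  }
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(term_collection), function(tid) {
    members <- intersect(term_collection[[tid]], background)
    K <- length(members)
    k <- length(intersect(gene_list, members))
    data.frame(term_id = tid, count = k, list_size = n, term_size = K,
               background_size = N,
               enrichment_factor = if (K > 0 && n > 0)
                 enrichment_factor(k, n, K, N) else NA_real_,
               p_value = if (K > 0 && n > 0) hypergeom_p(k, n, K, N) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$passes <- out$p_value < thresholds$p &
    out$count >= thresholds$min_count &
    !is.na(out$enrichment_factor) &
    out$enrichment_factor > thresholds$min_ef
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Cohen's kappa between two gene sets over a background
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` of the two
#' membership indicator vectors over the universe; the similarity used to
#' draw edges between enriched terms.
#'
#' @param set_a,set_b character vectors of member genes.
#' @param background the gene universe.
#' @export
kappa_similarity <- function(set_a, set_b, background) {
  background <- unique(background)
  a <- background %in% set_a
  b <- background %in% set_b
  n <- length(background)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(1)  # identical constant vectors
  (po - pe) / (1 - pe)
}

#' Term-similarity network over passing terms
#'
#' Nodes are the terms that pass the enrichment filters; an edge joins two
#' terms when the kappa similarity of their memberships (over the
#' background) exceeds the threshold.
#'
#' @param enriched result of [enrich()].
#' @param term_collection the collection the terms came from.
#' @param background the gene universe used for enrichment.
#' @param kappa_threshold edge threshold (default 0.3, strict inequality).
#' @return igraph graph with node attributes `p_value`, `count`,
#'   `enrichment_factor` and edge attribute `kappa`.
#' @export
term_similarity_network <- function(enriched, term_collection, background,
                                    kappa_threshold = 0.3) {
  keep <- enriched[enriched$passes, , drop = FALSE]
  ids <- keep$term_id
  edges <- data.frame(from = character(0), to = character(0),
                      kappa = numeric(0), stringsAsFactors = FALSE)
  if (length(ids) >= 2) {
    cmb <- utils::combn(ids, 2)
    kap <- apply(cmb, 2, function(p)
      kappa_similarity(term_collection[[p[1]]], term_collection[[p[2]]],
                       background))
    sel <- kap > kappa_threshold
    edges <- data.frame(from = cmb[1, sel], to = cmb[2, sel],
                        kappa = kap[sel], stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, p_value = keep$p_value,
                          count = keep$count,
                          enrichment_factor = keep$enrichment_factor,
                          stringsAsFactors = FALSE))
}

#' Enrichment over several gene lists plus a heatmap matrix
#'
#' Runs [enrich()] per list (e.g. the control-network and surgery-network
#' mRNAs) and builds a terms x lists matrix of `-log10(P)` restricted to
#' terms passing in at least one list — the data behind a multi-list
#' enrichment heatmap.
#'
#' @param gene_lists named list of character vectors.
#' @inheritParams enrich
#' @return list with `results` (one [enrich()] table per list) and
#'   `heatmap` (numeric matrix, terms x lists).
#' @export
enrich_lists <- function(gene_lists, term_collection, background,
                         thresholds = enrichment_thresholds()) {
  results <- lapply(gene_lists, enrich, term_collection = term_collection,
                    background = background, thresholds = thresholds)
  terms <- sort(unique(unlist(lapply(results, function(r)
    r$term_id[r$passes]))))
  hm <- matrix(0, length(terms), length(results),
               dimnames = list(terms, names(results)))
  for (nm in names(results)) {
    r <- results[[nm]]
    hm[, nm] <- -log10(pmax(r$p_value[match(terms, r$term_id)],
                            .Machine$double.xmin))
  }
  list(results = results, heatmap = hm)
}
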