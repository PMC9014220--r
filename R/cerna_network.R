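#' Thresholds for triplet validity
#'
#' A scored triplet is kept when the circRNA-mRNA Pearson correlation
#' reaches `cor` and the sensitivity correlation reaches `s`. Both are
#' effect-size thresholds: with six samples per comparison, correlation
#' P values carry almost no information, so none are computed.
#'
#' @param cor minimum circRNA-mRNA Pearson correlation (default 0.7).
#' @param s minimum sensitivity correlation (default 0.3).
#' @export
triplet_thresholds <- function(cor = 0.7, s = 0.3) {
  stopifnot(cor >= -1, cor <= 1)
  list(cor = cor, s = s)
}

#' Candidate circRNA-miRNA and miRNA-mRNA pairs
#'
#' A pair exists when both members pass the DE filter and at least one seed
#' site links them; the evidence count is the number of distinct site starts.
#' Optionally, pairs whose members are DE in the same direction can be
#' dropped (`direction_constraint`); this is off by default — sponge logic
#' expects opposite directions, but published networks routinely keep
#' same-direction pairs, so the constraint is opt-in.
#'
#' @param de_circ,de_mir,de_mrna DE tables from [call_de()].
#' @param sites_circ site table of miRNAs on circRNAs
#'   ([find_sites()] with `circular = TRUE`).
#' @param sites_mrna site table of miRNAs on mRNA 3'UTRs.
#' @param direction_constraint require the miRNA's DE direction to be
#'   opposite its partner's?
#' @return list with data.frames `circ_mir` (`circ_id`, `mir_id`,
#'   `n_sites`) and `mir_mrna` (`mir_id`, `mrna_id`, `n_sites`).
#' @export
candidate_pairs <- function(de_circ, de_mir, de_mrna, sites_circ, sites_mrna,
                            direction_constraint = FALSE) {
  keep <- function(de) de[de$passes_filter, , drop = FALSE]
  dc <- keep(de_circ); dm <- keep(de_mir); dg <- keep(de_mrna)
  if (!nrow(dc) || !nrow(dm) || !nrow(dg))
    warning("empty DE set: no candidate pairs")

  pair_up <- function(sites, target_de, partner_col) {
    s <- sites[sites$target_id %in% target_de$feature_id &
                 sites$mir_id %in% dm$feature_id, , drop = FALSE]
    if (!nrow(s)) {
      out <- data.frame(target_id = character(0), mir_id = character(0),
                        n_sites = integer(0), stringsAsFactors = FALSE)
    } else {
      agg <- stats::aggregate(start ~ target_id + mir_id, data = s,
                              FUN = function(x) length(unique(x)))
      out <- data.frame(target_id = agg$target_id, mir_id = agg$mir_id,
                        n_sites = as.integer(agg$start),
                        stringsAsFactors = FALSE)
    }
    if (direction_constraint && nrow(out)) {
      dir_t <- target_de$direction[match(out$target_id, target_de$feature_id)]
      dir_m <- dm$direction[match(out$mir_id, dm$feature_id)]
      out <- out[dir_t != dir_m, , drop = FALSE]
    }
    names(out)[1] <- partner_col
    out[order(out[[1]], out$mir_id), , drop = FALSE]
  }

  cm <- pair_up(sites_circ, dc, "circ_id")
  gm <- pair_up(sites_mrna, dg, "mrna_id")
  list(circ_mir = cm[, c("circ_id", "mir_id", "n_sites")],
       mir_mrna = gm[, c("mir_id", "mrna_id", "n_sites")])
}

#' miRNAs shared by both pair kinds
#'
#' The intersection step: miRNAs that appear in at least one circRNA-miRNA
#' pair and at least one miRNA-mRNA pair can mediate a triplet.
#'
#' @param pairs list from [candidate_pairs()].
#' @return sorted character vector of miRNA ids.
#' @export
shared_mirnas <- function(pairs) {
  sort(intersect(unique(pairs$circ_mir$mir_id),
                 unique(pairs$mir_mrna$mir_id)))
}

#' Sensitivity correlation S
#'
#' `S = cor_xy - pcor(x, y | m)` where `pcor` is the first-order partial
#' correlation of circRNA and mRNA given the shared miRNA:
#' `pcor = (cor_xy - cor_cm * cor_tm) / sqrt((1 - cor_cm^2) (1 - cor_tm^2))`.
#' S measures how much of the circRNA-mRNA co-expression vanishes once the
#' miRNA is conditioned out: large S indicates miRNA-mediated coupling, the
#' ceRNA signature. With no miRNA involvement (`cor_cm = cor_tm = 0`),
#' S is exactly 0.
#'
#' @param cor_xy circRNA-mRNA Pearson correlation.
#' @param cor_cm circRNA-miRNA correlation (|value| < 1).
#' @param cor_tm mRNA-miRNA correlation (|value| < 1).
#' @export
relationship_S <- function(cor_xy, cor_cm, cor_tm) {
  if (any(abs(c(cor_xy, cor_cm, cor_tm)) > 1))
    stop("correlations must lie in [-1, 1]")
  if (any(abs(cor_cm) >= 1) || any(abs(cor_tm) >= 1))
    stop("partial correlation undefined at |cor| = 1")
  pcor <- (cor_xy - cor_cm * cor_tm) /
    sqrt((1 - cor_cm^2) * (1 - cor_tm^2))
  cor_xy - pcor
}

#' Score candidate triplets
#'
#' For every shared miRNA, every (circRNA partner, mRNA partner) combination
#' is scored: Pearson correlations are computed on `log2(x + 1)`-transformed
#' class-unit expression across the comparison's samples (the log tames the
#' skew of NB counts), then the sensitivity correlation S. Triplets with a
#' zero-variance member are dropped with a message. `valid` flags triplets
#' meeting both [triplet_thresholds()].
#'
#' @param pairs list from [candidate_pairs()].
#' @param expr named list of [expression_matrix()] (`circ`, `mir`, `mrna`).
#' @param sample_ids samples of the comparison (both groups).
#' @param thresholds a [triplet_thresholds()] list.
#' @param log_transform apply `log2(x + 1)` before correlating (default).
#' @return data.frame with one row per triplet: ids, `cor_xy`, `cor_cm`,
#'   `cor_tm`, `S`, `n_sites_circ`, `n_sites_mrna`, `valid`.
#' @export
score_triplets <- function(pairs, expr, sample_ids,
                           thresholds = triplet_thresholds(),
                           log_transform = TRUE) {
  mirs <- shared_mirnas(pairs)
  empty <- data.frame(circ_id = character(0), mir_id = character(0),
                      mrna_id = character(0), cor_xy = numeric(0),
                      cor_cm = numeric(0), cor_tm = numeric(0),
                      S = numeric(0), n_sites_circ = integer(0),
                      n_sites_mrna = integer(0), valid = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(mirs)) return(empty)

  vec <- function(class, id) {
    v <- expr[[class]]$values[id, sample_ids]
    if (log_transform) log2(v + 1) else v
  }
  rows <- list()
  dropped <- 0L
  for (m in mirs) {
    vm <- vec("mir", m)
    cpart <- pairs$circ_mir[pairs$circ_mir$mir_id == m, , drop = FALSE]
    gpart <- pairs$mir_mrna[pairs$mir_mrna$mir_id == m, , drop = FALSE]
    for (i in seq_len(nrow(cpart))) {
      vc <- vec("circ", cpart$circ_id[i])
      for (j in seq_len(nrow(gpart))) {
        vg <- vec("mrna", gpart$mrna_id[j])
        if (stats::sd(vc) == 0 || stats::sd(vg) == 0 || stats::sd(vm) == 0) {
          dropped <- dropped + 1L
          next
        }
        cxy <- stats::cor(vc, vg)
        ccm <- stats::cor(vc, vm)
        ctm <- stats::cor(vg, vm)
        s <- if (abs(ccm) >= 1 || abs(ctm) >= 1) NA_real_
             else relationship_S(cxy, ccm, ctm)
        if (is.na(s)) { dropped <- dropped + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = cpart$circ_id[i], mir_id = m,
          mrna_id = gpart$mrna_id[j],
          cor_xy = cxy, cor_cm = ccm, cor_tm = ctm, S = s,
          n_sites_circ = cpart$n_sites[i], n_sites_mrna = gpart$n_sites[j],
          valid = cxy >= thresholds$cor & s >= thresholds$s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped) message(dropped, " triplet(s) dropped (zero variance or ",
                       "degenerate correlation)")
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$circ_id, out$mir_id, out$mrna_id), , drop = FALSE]
}

#' Assemble the ceRNA network from valid triplets
#'
#' Nodes are the circRNAs, miRNAs and mRNAs of valid triplets; edges are the
#' circRNA-miRNA and miRNA-mRNA interactions, each carrying its seed-site
#' count and owning triplet ids. The graph is bipartite between miRNAs and
#' the other two classes by construction. Node and edge order is
#' deterministic (class, then id).
#'
#' @param triplets scored table from [score_triplets()].
#' @param de optional named list of DE tables used to annotate nodes with
#'   direction and log2 fold change.
#' @return a `CeRNANetwork`: list with `nodes`, `edges` and `triplets`
#'   (the valid rows).
#' @export
assemble_network <- function(triplets, de = NULL) {
  tr <- triplets[triplets$valid, , drop = FALSE]
  stopifnot(all(tr$n_sites_circ >= 1), all(tr$n_sites_mrna >= 1))
  tr$triplet_id <- if (nrow(tr))
    sprintf("%s|%s|%s", tr$circ_id, tr$mir_id, tr$mrna_id) else character(0)

  node_tab <- function(ids, class) {
    ids <- sort(unique(ids))
    data.frame(id = ids, class = rep(class, length(ids)),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(node_tab(tr$circ_id, "circRNA"),
                 node_tab(tr$mir_id, "miRNA"),
                 node_tab(tr$mrna_id, "mRNA"))
  nodes$direction <- rep(NA_character_, nrow(nodes))
  nodes$log2_fold_change <- rep(NA_real_, nrow(nodes))
  if (!is.null(de) && nrow(nodes)) {
    lut <- rbind(
      data.frame(id = de$circ$feature_id, dir = de$circ$direction,
                 l2fc = de$circ$log2_fold_change),
      data.frame(id = de$mir$feature_id, dir = de$mir$direction,
                 l2fc = de$mir$log2_fold_change),
      data.frame(id = de$mrna$feature_id, dir = de$mrna$direction,
                 l2fc = de$mrna$log2_fold_change))
    hit <- match(nodes$id, lut$id)
    nodes$direction <- lut$dir[hit]
    nodes$log2_fold_change <- lut$l2fc[hit]
  }

  edge_tab <- function(src, dst, type, n_sites, tid) {
    if (!length(src)) {
      return(data.frame(source = character(0), target = character(0),
                        edge_type = character(0), n_sites = integer(0),
                        triplet_ids = character(0), stringsAsFactors = FALSE))
    }
    d <- data.frame(source = src, target = dst, edge_type = type,
                    n_sites = n_sites, tid = tid, stringsAsFactors = FALSE)
    agg <- stats::aggregate(tid ~ source + target + edge_type + n_sites,
                            data = d, FUN = function(x)
                              paste(sort(unique(x)), collapse = ","))
    data.frame(source = agg$source, target = agg$target,
               edge_type = agg$edge_type, n_sites = agg$n_sites,
               triplet_ids = agg$tid, stringsAsFactors = FALSE)
  }
  edges <- rbind(
    edge_tab(tr$circ_id, tr$mir_id, "circRNA-miRNA", tr$n_sites_circ,
             tr$triplet_id),
    edge_tab(tr$mir_id, tr$mrna_id, "miRNA-mRNA", tr$n_sites_mrna,
             tr$triplet_id))
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, triplets = tr),
            class = "CeRNANetwork")
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  tab <- table(factor(x$nodes$class, c("circRNA", "miRNA", "mRNA")))
  cat(sprintf(
    "CeRNANetwork: %d circRNA, %d miRNA, %d mRNA nodes; %d edges; %d triplets\n",
    tab["circRNA"], tab["miRNA"], tab["mRNA"], nrow(x$edges),
    nrow(x$triplets)))
  invisible(x)
}

#' Convert a ceRNA network to igraph / GraphML
#'
#' Node attributes `class`, `direction` and `log2_fold_change` and edge
#' attributes `edge_type`, `n_sites`, `triplet_ids` are carried over, ready
#' for Cytoscape-style rendering.
#'
#' @param net a `CeRNANetwork`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "CeRNANetwork"))
  nodes <- net$nodes
  nodes$direction[is.na(nodes$direction)] <- ""
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  g
}

#' @rdname as_igraph
#' @param path output GraphML path.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  # GraphML cannot carry NA numeric attributes
  l2fc <- igraph::vertex_attr(g, "log2_fold_change")
  l2fc[is.na(l2fc)] <- 0
  g <- igraph::set_vertex_attr(g, "log2_fold_change", value = l2fc)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write network tables as TSV
#' @param net a `CeRNANetwork`.
#' @param edge_path,triplet_path output paths (either may be `NULL`).
#' @export
write_network_tables <- function(net, edge_path = NULL, triplet_path = NULL) {
  if (!is.null(edge_path))
    utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(triplet_path))
    utils::write.table(net$triplets, triplet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(net)
}
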