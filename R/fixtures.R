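.fixture_md5 <- c(
  network_circ_table_control.tsv = "41aaac57c9ac0a8b677cd90228c70e29",
  network_circ_table_surgery.tsv = "1e898d1acec371fc3ec1c49f0c6f5be7")

#' Packaged circRNA-miRNA network tables
#'
#' The published circRNA rows of the two ceRNA networks (control and
#' surgery condition), as printed: per circRNA its log2 fold change (aging
#' over young), raw P, regulation direction and the comma-separated miRNAs
#' predicted to bind it by seed matching. The miRNA column is split into a
#' list-column of miRNA id sets (tolerant of the irregular separators in the
#' printed table). File integrity is checked against a stored checksum.
#'
#' @return list with data.frames `control` and `surgery`, each with columns
#'   `circ_id`, `log2_fold_change`, `p_value`, `direction` and the
#'   list-column `mirnas`.
#' @export
load_table_fixtures <- function() {
  load_one <- function(fname) {
    path <- system.file("extdata", fname, package = "ceRNAnet",
                        mustWork = TRUE)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.fixture_md5[[fname]])))
      stop("checksum mismatch for packaged fixture ", fname)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    mirnas <- lapply(strsplit(tab$circRNA_miRNA, "[,[:space:]]+"),
                     function(x) sort(unique(x[nzchar(x)])))
    data.frame(circ_id = tab$circRNA,
               log2_fold_change = tab$log2_fold_change,
               p_value = tab$p_value,
               direction = tolower(tab$regulation),
               mirnas = I(mirnas),
               stringsAsFactors = FALSE)
  }
  list(control = load_one("network_circ_table_control.tsv"),
       surgery = load_one("network_circ_table_surgery.tsv"))
}

#' circRNA-miRNA pair list from a fixture table
#'
#' Expands the list-column into one row per (circRNA, miRNA) pair — the
#' printed network's circRNA-miRNA edge set.
#'
#' @param fixture one element of [load_table_fixtures()].
#' @return data.frame with `circ_id`, `mir_id`.
#' @export
fixture_pairs <- function(fixture) {
  out <- data.frame(
    circ_id = rep(fixture$circ_id, lengths(fixture$mirnas)),
    mir_id = unlist(fixture$mirnas, use.names = FALSE),
    stringsAsFactors = FALSE)
  out[order(out$circ_id, out$mir_id), , drop = FALSE]
}

#' Node composition of a printed network fixture
#'
#' Applies the DE filter to the printed fold changes and P values
#' (all printed rows pass the |log2FC| >= 1, P <= 0.05 criteria) and counts
#' the circRNA and unique miRNA nodes of the circRNA-miRNA layer.
#'
#' @param fixture one element of [load_table_fixtures()].
#' @param thresholds a [de_thresholds()] list.
#' @return list with `n_circ`, `n_mir`, and the filtered `pairs`.
#' @export
fixture_network_composition <- function(fixture,
                                        thresholds = de_thresholds()) {
  pass <- abs(fixture$log2_fold_change) >= log2(thresholds$fold_change) &
    fixture$p_value <= thresholds$p
  kept <- fixture[pass, , drop = FALSE]
  pairs <- fixture_pairs(kept)
  list(n_circ = length(unique(pairs$circ_id)),
       n_mir = length(unique(pairs$mir_id)),
       pairs = pairs)
}
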