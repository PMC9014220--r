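#' Thresholds for differential-expression calls
#'
#' The selection rule is `|log2 fold change| >= log2(fold_change)` and raw
#' Fisher `P <= p`. Filtering is on the raw P (the criterion the selection
#' rule states); the BH-adjusted P is always reported alongside.
#'
#' @param fold_change minimum fold change (default 2).
#' @param p maximum raw P (default 0.05).
#' @param pseudocount added to both group means before the log-ratio so that
#'   zero-count features keep a finite, large-magnitude fold change
#'   (default 0.1).
#' @export
de_thresholds <- function(fold_change = 2, p = 0.05, pseudocount = 0.1) {
  stopifnot(fold_change >= 1, p >= 0, p <= 1, pseudocount > 0)
  list(fold_change = fold_change, p = p, pseudocount = pseudocount)
}

#' Fisher exact test on pooled per-group counts
#'
#' Replicates are pooled within each group and the feature is tested on the
#' 2x2 table `[[count_a, lib_a - count_a], [count_b, lib_b - count_b]]`.
#' The two-sided P is the sum of the probabilities of all tables (with the
#' observed margins) no more likely than the observed one. Pooling means
#' only counting noise is modelled: between-replicate biological
#' overdispersion is not absorbed, a documented limitation of this test
#' family (an exact NB test would be the dispersion-aware alternative).
#'
#' @param count_a,count_b pooled feature counts in each group (vectorised).
#' @param lib_a,lib_b pooled library sizes (total mapped reads) per group.
#' @return vector of two-sided P values.
#' @export
fisher_feature_test <- function(count_a, count_b, lib_a, lib_b) {
  n <- length(count_a)
  stopifnot(length(count_b) == n)
  lib_a <- rep_len(lib_a, n)
  lib_b <- rep_len(lib_b, n)
  if (any(count_a > lib_a) || any(count_b > lib_b))
    stop("count exceeds library size")
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(count_a[i], lib_a[i] - count_a[i],
                    count_b[i], lib_b[i] - count_b[i]),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`: the change of
#' group b over group a in the class's expression unit.
#'
#' @param mean_a,mean_b non-negative group means.
#' @param pseudocount positive stabiliser (default 0.1).
#' @export
log2fc <- function(mean_a, mean_b, pseudocount = 0.1) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop("negative means")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values raw P values in `[0, 1]`.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed features between two groups
#'
#' Group means are taken from the class-unit expression matrices; P values
#' come from [fisher_feature_test()] on replicate-pooled raw counts against
#' pooled library sizes. One record per feature, sorted by (p_value,
#' feature_id).
#'
#' @param expr_a,expr_b [expression_matrix()] slices for the two groups
#'   (same features, same unit).
#' @param counts_a,counts_b [count_matrix()] slices for the two groups.
#' @param thresholds a [de_thresholds()] list.
#' @return data.frame of DE records: `feature_id`, `mean_expr_a`,
#'   `mean_expr_b`, `log2_fold_change` (b over a), `p_value`, `p_adjusted`,
#'   `direction` (`up` iff the fold change is positive), `passes_filter`.
#' @export
call_de <- function(expr_a, expr_b, counts_a, counts_b,
                    thresholds = de_thresholds()) {
  stopifnot(inherits(expr_a, "ExpressionMatrix"),
            inherits(expr_b, "ExpressionMatrix"),
            inherits(counts_a, "CountMatrix"),
            inherits(counts_b, "CountMatrix"))
  ids <- rownames(expr_a$values)
  if (!identical(ids, rownames(expr_b$values)) ||
      !identical(ids, rownames(counts_a$counts)) ||
      !identical(ids, rownames(counts_b$counts)))
    stop("feature axes differ between inputs")
  if (!identical(expr_a$unit, expr_b$unit))
    stop("expression units differ between groups")

  mean_a <- rowMeans(expr_a$values)
  mean_b <- rowMeans(expr_b$values)
  l2fc <- log2fc(mean_a, mean_b, thresholds$pseudocount)
  p <- fisher_feature_test(rowSums(counts_a$counts),
                           rowSums(counts_b$counts),
                           sum(counts_a$library_size),
                           sum(counts_b$library_size))
  padj <- bh_adjust(p)
  rec <- data.frame(
    feature_id = ids,
    mean_expr_a = mean_a, mean_expr_b = mean_b,
    log2_fold_change = l2fc,
    p_value = p, p_adjusted = padj,
    direction = ifelse(l2fc > 0, "up", "down"),
    passes_filter = abs(l2fc) >= log2(thresholds$fold_change) &
      p <= thresholds$p,
    stringsAsFactors = FALSE, row.names = NULL)
  rec[order(rec$p_value, rec$feature_id), , drop = FALSE]
}

#' Slice a design into one two-group comparison
#'
#' Returns the sample ids of the two age groups within one condition, the
#' pipeline's unit of comparison (aging over young).
#'
#' @param design a [study_design()].
#' @param condition `"control"` or `"surgery"`.
#' @return list with `a` (young sample ids, the reference) and `b` (aging).
#' @export
comparison_samples <- function(design, condition = c("control", "surgery")) {
  condition <- match.arg(condition)
  d <- design[design$condition == condition, ]
  list(a = d$sample_id[d$age == "young"], b = d$sample_id[d$age == "aging"])
}

#' Subset containers by sample
#'
#' Column subsetting that keeps the `CountMatrix` / `ExpressionMatrix`
#' classes (and their invariants) intact.
#'
#' @param cm a [count_matrix()].
#' @param sample_ids columns to keep.
#' @export
subset_counts <- function(cm, sample_ids) {
  count_matrix(cm$counts[, sample_ids, drop = FALSE],
               library_size = cm$library_size[sample_ids],
               feature_length = cm$feature_length)
}

#' @rdname subset_counts
#' @param em an [expression_matrix()].
#' @export
subset_expression <- function(em, sample_ids) {
  expression_matrix(em$values[, sample_ids, drop = FALSE], unit = em$unit)
}

#' Write DE records as TSV
#' @param de data.frame from [call_de()].
#' @param path output path.
#' @export
write_de <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
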