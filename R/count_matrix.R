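#' Raw count matrix for one RNA class
#'
#' A `CountMatrix` bundles an integer feature-by-sample count matrix with
#' per-sample library sizes (total mapped reads, used as the normalisation
#' denominator) and, for length-normalised units, per-feature lengths in bp.
#' Library sizes may exceed the per-class column sums: a class (e.g. circRNA
#' back-splice junction reads) typically captures only a fraction of all
#' mapped reads.
#'
#' @param counts integer matrix, features x samples, with rownames and
#'   colnames set. Negative or non-integer values are rejected.
#' @param library_size per-sample positive totals, named by sample or in
#'   column order. Defaults to the column sums of `counts`, which is the
#'   right denominator for self-contained synthetic runs.
#' @param feature_length optional per-feature length in bp (needed for FPKM),
#'   named by feature or in row order.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, library_size = NULL, feature_length = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"  # keeps >2^31 library arithmetic exact enough

  if (is.null(library_size)) library_size <- colSums(counts)
  library_size <- .align_named(library_size, colnames(counts), "library_size")
  if (any(library_size <= 0)) stop("library sizes must be positive")
  if (any(library_size < colSums(counts)))
    stop("library_size smaller than the column sum of counts")

  if (!is.null(feature_length)) {
    feature_length <- .align_named(feature_length, rownames(counts),
                                   "feature_length")
    if (any(feature_length <= 0)) stop("feature lengths must be positive")
  }

  structure(list(counts = counts, library_size = library_size,
                 feature_length = feature_length),
            class = "CountMatrix")
}

# align a possibly-named vector to `ids`, recycling nothing
.align_named <- function(x, ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stop(sprintf("%s missing entries for: %s", what,
                   paste(utils::head(missing, 5), collapse = ", ")))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop(sprintf("%s must have one entry per id", what))
  } else {
    names(x) <- ids
  }
  x
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(" library sizes:", paste(format(x$library_size, big.mark = ","),
                               collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Normalised expression matrix
#'
#' Same axes as the originating [count_matrix()], real-valued, with the unit
#' (`SRPBM`, `TPM` or `FPKM`) recorded so downstream consumers know what they
#' are correlating.
#'
#' @param values numeric matrix with dimnames.
#' @param unit one of `"SRPBM"`, `"TPM"`, `"FPKM"`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, unit = c("SRPBM", "TPM", "FPKM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have dimnames")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  structure(list(values = values, unit = unit), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              x$unit, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read / write count matrices as TSV
#'
#' The on-disk format is a tab-separated table whose first column is the
#' feature id and whose remaining columns are integer counts, one per sample.
#' Optional side tables supply total-mapped-read library sizes
#' (`sample_id<TAB>library_size`) and feature lengths
#' (`feature_id<TAB>length_bp`); without a library table, library sizes
#' default to the per-class column sums.
#'
#' @param path TSV file of counts.
#' @param library_path optional two-column TSV of per-sample mapping totals.
#' @param length_path optional two-column TSV of feature lengths in bp.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, library_path = NULL, length_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  lib <- NULL
  if (!is.null(library_path)) {
    lt <- utils::read.delim(library_path, header = FALSE,
                            stringsAsFactors = FALSE)
    lib <- stats::setNames(as.numeric(lt[[2]]), lt[[1]])
  }
  len <- NULL
  if (!is.null(length_path)) len <- read_lengths(length_path)
  count_matrix(m, library_size = lib, feature_length = len)
}

#' @rdname read_counts
#' @param cm a [count_matrix()].
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_counts
#' @export
read_lengths <- function(path) {
  lt <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(lt[[2]]), lt[[1]])
}

#' Read / write expression matrices as TSV
#'
#' Expression tables carry their unit in a `# unit=` comment on the first
#' line so that values are never reinterpreted in the wrong unit system.
#'
#' @param em an [expression_matrix()].
#' @param path output TSV path.
#' @export
write_expression <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s", em$unit), con)
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- sub("^# unit=", "", first)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  expression_matrix(m, unit = unit)
}
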