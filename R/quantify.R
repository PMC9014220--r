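#' Class-specific normalisation units
#'
#' Each RNA class is normalised in its own unit system:
#'
#' * **SRPBM** (back-splice junction reads per billion mapped reads) for
#'   circRNAs: `count / library_size * 1e9`. Circles are quantified only by
#'   reads crossing the back-splice junction, so no length term applies.
#' * **TPM**, implemented for mature miRNAs as reads per million class-mapped
#'   reads: `count / column_sum * 1e6`. Mature miRNAs are all ~22 nt, so the
#'   length normalisation of transcript-level TPM degenerates to a constant
#'   and is omitted; each output column sums to exactly one million.
#' * **FPKM** (fragments per kilobase of exon model per million mapped
#'   fragments) for mRNAs:
#'   `count / (length_bp / 1e3) / (library_size / 1e6)`.
#'
#' @param cm a [count_matrix()] of the appropriate class.
#' @return an [expression_matrix()] with the unit recorded.
#' @examples
#' cm <- count_matrix(matrix(c(50, 0), 1, 2,
#'                           dimnames = list("circA", c("s1", "s2"))),
#'                    library_size = c(s1 = 2e8, s2 = 1e9))
#' srpbm(cm)$values  # 250 and 0
#' @export
srpbm <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (any(cm$library_size == 0)) stop("zero library size")
  v <- sweep(cm$counts, 2, cm$library_size, "/") * 1e9
  expression_matrix(v, unit = "SRPBM")
}

#' @rdname srpbm
#' @export
tpm_mirna <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  cs <- colSums(cm$counts)
  if (any(cs == 0)) stop("all-zero sample column: TPM undefined")
  v <- sweep(cm$counts, 2, cs, "/") * 1e6
  expression_matrix(v, unit = "TPM")
}

#' @rdname srpbm
#' @export
fpkm <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(cm$feature_length))
    stop("FPKM needs per-feature lengths (feature_length)")
  if (any(cm$library_size == 0)) stop("zero library size")
  v <- cm$counts / (cm$feature_length / 1e3)
  v <- sweep(v, 2, cm$library_size / 1e6, "/")
  expression_matrix(v, unit = "FPKM")
}

#' Normalise a count matrix in its class's unit
#'
#' Dispatch helper used by the pipeline: circRNA -> SRPBM, miRNA -> TPM,
#' mRNA -> FPKM.
#'
#' @param cm a [count_matrix()].
#' @param class_name one of `"circ"`, `"mir"`, `"mrna"`.
#' @export
normalize_class <- function(cm, class_name = c("circ", "mir", "mrna")) {
  switch(match.arg(class_name),
         circ = srpbm(cm),
         mir  = tpm_mirna(cm),
         mrna = fpkm(cm))
}
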