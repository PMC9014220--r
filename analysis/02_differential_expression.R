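#!/usr/bin/env Rscript
# Stage 2: class-specific normalisation and differential expression.
#
# Reads the count matrices from stage 1, normalises each RNA class in its
# own unit (circRNA -> SRPBM, miRNA -> TPM, mRNA -> FPKM) and calls
# aging-vs-young DE within each condition with the pooled-count Fisher
# exact test, BH correction and the fold-change >= 2, P <= 0.05 filter.
# Writes one DE table per class and comparison under results/de/.

suppressPackageStartupMessages(library(ceRNAnet))

indir <- "results/synthetic"
outdir <- "results/de"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

design <- study_design()
counts <- list(
  circ = read_counts(file.path(indir, "counts_circ.tsv")),
  mir = read_counts(file.path(indir, "counts_mir.tsv")),
  mrna = read_counts(file.path(indir, "counts_mrna.tsv")))
# synthetic mRNAs share a flat 2 kb exon model (no isoform structure)
counts$mrna$feature_length <- setNames(rep(2000, nrow(counts$mrna$counts)),
                                       rownames(counts$mrna$counts))
expr <- lapply(setNames(nm = names(counts)),
               function(cls) normalize_class(counts[[cls]], cls))
for (cls in names(expr))
  write_expression(expr[[cls]], file.path(outdir, sprintf("expr_%s.tsv", cls)))

for (cond in c("control", "surgery")) {
  cmp <- comparison_samples(design, cond)
  for (cls in names(counts)) {
    de <- call_de(subset_expression(expr[[cls]], cmp$a),
                  subset_expression(expr[[cls]], cmp$b),
                  subset_counts(counts[[cls]], cmp$a),
                  subset_counts(counts[[cls]], cmp$b))
    write_de(de, file.path(outdir, sprintf("de_%s_%s.tsv", cond, cls)))
    cat(sprintf("%s/%s: %d of %d features pass (%d up, %d down)\n",
                cond, cls, sum(de$passes_filter), nrow(de),
                sum(de$passes_filter & de$direction == "up"),
                sum(de$passes_filter & de$direction == "down")))
  }
}
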