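#!/usr/bin/env Rscript
# Stage 3: miRNA seed-site scanning.
#
# Scans the DE miRNAs of each comparison against the DE circRNAs (circular
# scan, junction-spanning sites included) and DE mRNA 3'UTRs (linear scan),
# using the strict 7mer-m8 rule with 8mer upgrades. Writes one BED-like
# site table per comparison under results/sites/.

suppressPackageStartupMessages(library(ceRNAnet))

outdir <- "results/sites"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

seqs <- list(circ = read_fasta("results/synthetic/circ.fa"),
             mir = read_fasta("results/synthetic/mir.fa"),
             mrna = read_fasta("results/synthetic/mrna_utr.fa"))

for (cond in c("control", "surgery")) {
  de <- lapply(setNames(nm = c("circ", "mir", "mrna")), function(cls)
    read.delim(sprintf("results/de/de_%s_%s.tsv", cond, cls)))
  ids <- function(cls) de[[cls]]$feature_id[de[[cls]]$passes_filter]
  sites_circ <- find_sites(seqs$circ[ids("circ")], seqs$mir[ids("mir")],
                           circular = TRUE)
  sites_mrna <- find_sites(seqs$mrna[ids("mrna")], seqs$mir[ids("mir")],
                           circular = FALSE)
  write_sites(sites_circ, file.path(outdir, sprintf("sites_circ_%s.tsv", cond)))
  write_sites(sites_mrna, file.path(outdir, sprintf("sites_mrna_%s.tsv", cond)))
  cat(sprintf(
    "%s: %d circRNA sites (%d junction-spanning), %d 3'UTR sites\n",
    cond, nrow(sites_circ), sum(sites_circ$spans_junction),
    nrow(sites_mrna)))
}
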