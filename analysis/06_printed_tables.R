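#!/usr/bin/env Rscript
# Stage 6: published-network composition from the packaged printed tables.
#
# Loads the packaged circRNA-miRNA tables of the two published networks,
# applies the fold-change/P filter and the pairing logic, and reports the
# node composition (circRNA and unique miRNA counts) plus per-circRNA
# degrees. Also demonstrates why the pipeline's opposite-direction
# constraint defaults to off: the published pairing retains a
# down-regulated circRNA bound to a down-regulated miRNA.

suppressPackageStartupMessages(library(ceRNAnet))

outdir <- "results/printed_tables"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fx <- load_table_fixtures()
for (cond in names(fx)) {
  comp <- fixture_network_composition(fx[[cond]])
  cat(sprintf("%s network: %d circRNA nodes, %d unique miRNA nodes, %d edges\n",
              cond, comp$n_circ, comp$n_mir, nrow(comp$pairs)))
  write.table(comp$pairs, file.path(outdir, sprintf("pairs_%s.tsv", cond)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  deg <- sort(table(comp$pairs$mir_id), decreasing = TRUE)
  cat("  top miRNA degrees:",
      paste(names(deg)[1:3], deg[1:3], sep = "=", collapse = ", "), "\n")
}

ctrl <- fx$control
down_circ <- ctrl$circ_id[ctrl$direction == "down"]
pairs <- fixture_pairs(ctrl)
odd <- pairs[pairs$circ_id %in% down_circ &
               pairs$mir_id == "mmu-miR-298-5p", ]
cat(sprintf(paste0("down-regulated circRNAs paired with down-regulated ",
                   "miR-298-5p: %d (opposite-direction filtering would ",
                   "remove published edges)\n"), nrow(odd)))
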