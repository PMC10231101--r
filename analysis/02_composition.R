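#!/usr/bin/env Rscript

# Step 2: descriptive genomics of the cohort.
#
# Whole-genome and per-class composition (A+T content, AT/GC skew), the
# junction table with overlap motifs, start/stop codon classification and
# codon usage (RSCU) under the invertebrate mitochondrial genetic code.
# Writes results/composition.tsv, results/junctions.tsv and
# results/codon_usage.tsv.

suppressPackageStartupMessages(library(mitocomp))

files <- list.files("results/genomes", pattern = "\\.gb$",
                    full.names = TRUE)
stopifnot(length(files) > 0)

comp_rows <- list(); junc_rows <- list(); codon_rows <- list()
for (f in files) {
  g <- read_genbank(f)
  st <- composition_stats(g$sequence)
  comp_rows[[g$id]] <- data.frame(
    genome = g$id, region = "whole", length = st$length,
    pct_AT = st$pct_AT_1dp, at_skew = st$at_skew_3dp,
    gc_skew = st$gc_skew_3dp)
  for (cls in names(strandwise_stats(g))) {
    cs <- strandwise_stats(g)[[cls]]
    comp_rows[[paste(g$id, cls)]] <- data.frame(
      genome = g$id, region = cls, length = cs$length,
      pct_AT = cs$pct_AT_1dp, at_skew = cs$at_skew_3dp,
      gc_skew = cs$gc_skew_3dp)
  }
  j <- gene_junctions(g)
  j$genome <- g$id
  junc_rows[[g$id]] <- j
  cu <- suppressWarnings(codon_usage(g))
  cd <- cu$codons
  cd$genome <- g$id
  codon_rows[[g$id]] <- cd

  ov <- j[j$gap_bp < 0, ]
  cat(sprintf("%-16s %6d bp  A+T %.1f%%  AT-skew %+.3f  GC-skew %+.3f  overlaps: %s\n",
              g$id, st$length, st$pct_AT, st$at_skew, st$gc_skew,
              paste(sprintf("%s/%s %dbp", ov$upstream, ov$downstream,
                            -ov$gap_bp), collapse = ", ")))
}

dir.create("results", showWarnings = FALSE)
write.table(do.call(rbind, comp_rows), "results/composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, junc_rows), "results/junctions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, codon_rows), "results/codon_usage.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# headline codon-usage finding across the cohort
all_cod <- do.call(rbind, codon_rows)
sense <- all_cod[all_cod$aa != "*", ]
agg <- aggregate(count ~ codon_rna + aa, sense, sum)
top <- agg[which.max(agg$count), ]
rscu_by <- aggregate(rscu ~ codon_rna, sense, mean)
cat(sprintf("most used codon: %s (%s); highest mean RSCU: %s\n",
            top$codon_rna, top$aa,
            rscu_by$codon_rna[which.max(rscu_by$rscu)]))
cat("wrote results/composition.tsv, junctions.tsv, codon_usage.tsv\n")
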