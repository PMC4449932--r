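#!/usr/bin/env Rscript
# Step 5 — evaluate the selected panel.
#
# Computes the panel's MAF spectrum on the inbred lines, parent/F1 pedigree
# consistency for the 22 triplets, pairwise differential-locus distributions
# among inbreds and among hybrids (5 % histogram bins), similar-line
# similarity, the genomic window distribution and genic-category breakdown,
# and a comparative table of the curated panel against the full universe.

suppressMessages(library(panelsnp))

sim <- "results/sim"
out <- "results/eval"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

loci <- read_locus_map(file.path(sim, "locus_map.tsv"))
meta <- read_sample_metadata(file.path(sim, "sample_metadata.tsv"))
calls <- read_genotype_matrix("results/calls/genotypes.tsv")
qc <- read.table("results/qc/locus_qc.tsv", sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
qc$flags[is.na(qc$flags)] <- ""
panel <- read_panel("results/panel/panel_loci.txt")
maf <- compute_maf(calls, sample_subset = inbred_lines(meta))

panel_calls <- calls[, panel, drop = FALSE]

## MAF spectrum of the panel
pm <- maf$maf[match(panel, maf$locus_id)]
cat(sprintf("panel MAF: min %.3f, mean %.3f; all > 0.20: %s\n",
            min(pm), mean(pm), all(pm >= 0.20)))

## pedigree consistency over the triplets
hyb <- meta[meta$role == "hybrid" & !is.na(meta$parent1_id) &
              is.na(meta$duplicate_of), ]
triplets <- data.frame(triplet_id = sprintf("T%02d", seq_len(nrow(hyb))),
                       parent1 = hyb$parent1_id, parent2 = hyb$parent2_id,
                       f1 = hyb$sample_id)
ped <- pedigree_consistency_all(panel_calls, triplets)
write.table(ped, file.path(out, "pedigree_consistency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("pedigree consistency over %d triplets: mean %.2f%%, min %.2f%%\n",
            nrow(ped), 100 * mean(ped$consistency),
            100 * min(ped$consistency)))

## pairwise differential-locus distributions
for (role in c("inbred", "hybrid")) {
  ids <- meta$sample_id[meta$role == role & is.na(meta$duplicate_of)]
  pw <- pairwise_differences(panel_calls, sample_set = ids)
  write.table(pw$pairs, file.path(out, sprintf("pairwise_%s.tsv", role)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pw$histogram,
              file.path(out, sprintf("pairwise_%s_hist.tsv", role)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s pairs: %d, differential rate mean %.1f%% (range %.1f-%.1f%%)\n",
              role, nrow(pw$pairs),
              100 * mean(pw$pairs$differential_rate, na.rm = TRUE),
              100 * min(pw$pairs$differential_rate, na.rm = TRUE),
              100 * max(pw$pairs$differential_rate, na.rm = TRUE)))
}

## similar-line similarity
series <- meta[!is.na(meta$series) & meta$series != "", ]
if (nrow(series)) {
  for (i in seq_len(nrow(series))) {
    others <- setdiff(inbred_lines(meta), series$sample_id[i])
    sims <- vapply(others, function(s)
      genetic_similarity(panel_calls, c(s, series$sample_id[i])), numeric(1))
    cat(sprintf("similar line %s (%s series): closest line similarity %.2f%%\n",
                series$sample_id[i], series$series[i], 100 * max(sims)))
  }
}

## genomic distribution
gd <- genomic_distribution(panel, loci)
write.table(gd$windows, file.path(out, "window_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("genic-category proportions of the panel:\n")
print(round(gd$category_proportions, 3))

## comparative table: curated panel vs the full universe
ev_panel <- evaluate_panel(panel, calls, qc, maf, meta)
ev_universe <- evaluate_panel(loci$locus_id, calls, qc, maf, meta)
comp <- comparative_report(ev_panel, ev_universe,
                           names = c("curated_panel", "universe"))
print(round(comp, 3))
write.table(cbind(panel = rownames(comp), comp),
            file.path(out, "comparative_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
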