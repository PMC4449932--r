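#!/usr/bin/env Rscript
# Step 3 — score locus quality and detect defect classes.
#
# Computes the clustering-quality composite (angle, dispersion, overlap,
# intensity), missing statistics, het-inbred and inconsistent-triplet
# counts, duplicate reproducibility, and defect flags for every locus, then
# cross-tabulates detected flags against the planted defect classes.

suppressMessages(library(panelsnp))

sim <- "results/sim"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ints <- read_intensities(file.path(sim, "intensities.tsv"))
cf <- read_cluster_file("results/calls/cluster_file.json")
calls <- read_genotype_matrix("results/calls/genotypes.tsv")
meta <- read_sample_metadata(file.path(sim, "sample_metadata.tsv"))
loci <- read_locus_map(file.path(sim, "locus_map.tsv"))

# triplets and duplicate pairs are recoverable from the metadata
hyb <- meta[meta$role == "hybrid" & !is.na(meta$parent1_id) &
              is.na(meta$duplicate_of), ]
triplets <- data.frame(parent1 = hyb$parent1_id, parent2 = hyb$parent2_id,
                       f1 = hyb$sample_id)
dups <- meta[!is.na(meta$duplicate_of), ]
duplicate_pairs <- data.frame(sample_a = dups$duplicate_of,
                              sample_b = dups$sample_id)

qc <- score_loci(ints, calls, cf, meta, triplets = triplets,
                 duplicate_pairs = duplicate_pairs)
write.table(qc, file.path(out, "locus_qc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("quality-score summary:\n")
print(summary(qc$quality_score))
cat("\nflags vs planted defect class (rows = detected, cols = planted):\n")
print(table(detected = qc$flags,
            planted = loci$defect_class[match(qc$locus_id, loci$locus_id)]))
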