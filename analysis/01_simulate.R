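#!/usr/bin/env Rscript
# Step 1 — simulate the evaluation experiment.
#
# Generates the synthetic study: a 5,000-locus universe on 10 chromosomes
# with planted defect classes, low-MAF and low-designability loci; an
# evaluation panel of inbred lines (six heterotic groups), hybrids including
# 22 parent/parent/F1 triplets, two similar-line series, and duplicate
# assays; and the two-channel intensities for every (sample, locus) pair.
# Writes the locus map, sample metadata, truth genotypes, and intensities.

suppressMessages(library(panelsnp))

seed <- 101
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(n_loci = 5000, seed = seed)
print(study$universe)
print(study$population)

write_locus_map(study$universe$loci, file.path(out, "locus_map.tsv"))
write_sample_metadata(study$population$samples,
                      file.path(out, "sample_metadata.tsv"))
write_genotype_matrix(study$population$truth$genotypes,
                      file.path(out, "truth_genotypes.tsv"))
write_intensities(study$intensities, file.path(out, "intensities.tsv"))
writeLines(study$population$truth$planted_good_loci,
           file.path(out, "planted_good_loci.txt"))
write_scenario_config(list(seed = seed, output_dir = out,
                           simdata = list(n_loci = 5000)),
                      file.path(out, "scenario.yaml"))

cat(sprintf("wrote %s/: %d loci, %d samples, %d intensity rows\n", out,
            nrow(study$universe$loci), nrow(study$population$samples),
            nrow(study$intensities)))
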