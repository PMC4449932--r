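# panelsnp

Design and evaluation of SNP fingerprinting panels from genotyping-array
intensities, for people who curate fixed marker sets for crop variety
identification (maize in particular) and for anyone who wants a fully
synthetic, ground-truthed testbed for array genotype-calling and
marker-selection workflows.

## What it does

A fingerprinting panel is assembled by screening a large source array
against an evaluation panel of inbred lines and hybrids. `panelsnp`
implements every stage of that workflow:

1. **Simulation** (`simulate_study()`, `generate_locus_universe()`,
   `generate_population()`, `generate_intensities()`) — synthetic
   two-channel array data with planted defect classes, heterotic-group
   allele-frequency structure (Balding–Nichols), parent/parent/F1 triplets,
   similar-line series, duplicates, and a planted-good truth set.
2. **Signal model and calling** (`to_theta_r()`, `build_cluster_file()`,
   `call_genotypes()`) — the normalized polar transform
   θ = (2/π)·arctan(y/x) ∈ [0, 1] (0 = pure A, 1 = pure B, 0.5 = equal
   signals), R = x + y, and per-locus three-genotype call regions built from
   a labeled panel ("cluster file"), with points below the signal floor or
   outside all regions called `NC`.
3. **Locus QC** (`score_loci()`, `detect_defects()`, `reproducibility()`) —
   a composite clustering-quality score from the four canonical cluster
   characteristics (angle, dispersion, overlap, intensity) plus detection of
   the five defect classes: weak signal, high missing, pedigree
   inconsistency (> 3 triplets), heterozygous inbreds (> 5), shifted
   clusters.
4. **Staged selection** (`run_pipeline()`) — quality ≥ 0.70 → data quality
   (missing ≤ 5 %, no defects, perfect duplicate reproducibility) →
   population gate (single-copy, inbred MAF ≥ 0.20, one locus per genic
   region by coding-region priority) → designability ≥ 0.40 with an
   evenness-preserving trim to the target panel size.
5. **Evaluation** (`compute_maf()`, `pedigree_consistency()`,
   `pairwise_differences()`, `genetic_similarity()`,
   `platform_concordance()`, `genomic_distribution()`,
   `comparative_report()`) — MAF spectra, Mendelian triplet consistency,
   pairwise differential-locus distributions, cross-platform concordance,
   1000-kb window distributions, and side-by-side panel comparisons.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running
it end to end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build_and_call.R
Rscript analysis/03_locus_qc.R
Rscript analysis/04_select_panel.R
Rscript analysis/05_evaluate_panel.R
```

prints, among other things:

```
locus_universe: 5000 loci on 10 chromosomes, 6 heterotic groups
snp_population: 96 samples (55 inbred, 41 hybrid), 5000 loci
22 triplets, 4 duplicate pairs, 1610 planted-good loci

missing rate: 4.70% with the curated cluster file vs 13.05% with default regions
call accuracy vs truth on planted-good loci: 99.937%

panel_report selection funnel:
  input     5000 loci
  stage1    4784 loci
  stage2    4016 loci
  stage3    2044 loci
  panel     1610 loci

planted-good recovery: 1610 selected, 1610 planted, 0 false positive, 0 false negative
minimum inbred MAF in the panel: 0.2308

panel MAF: min 0.231, mean 0.374; all > 0.20: TRUE
pedigree consistency over 40 triplets: mean 100.00%, min 100.00%
inbred pairs: 1326, differential rate mean 46.5% (range 0.0-52.0%)
hybrid pairs: 780, differential rate mean 59.5% (range 39.9-65.3%)
similar line SLb01_2 (backcross series): closest line similarity 98.13%
```

Reading this: the curated cluster file nearly triples the callable fraction
relative to uncurated canonical regions; the staged funnel removes each
planted violation class at the intended gate (the per-locus first-failure
breakdown is in `results/panel/panel_report.tsv`); the selection recovers
the planted-good truth set exactly; every retained locus clears the 0.20
MAF floor on the inbred lines; error-free triplets are 100 %
Mendelian-consistent; and the backcross similar-line series lands at ~98 %
similarity, exactly what its 2 % planted mutation fraction implies. Each
script writes its tables under `results/`.

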